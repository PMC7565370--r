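#include <Rcpp.h>
using namespace Rcpp;

// Walk outward from a core site, tracking identity-by-state haplotype groups.
//
// A is a sites x haplotypes 0/1 matrix whose first nf columns form the focal
// panel and the remaining columns the control panel (nf == ncol means a single
// panel). Grouping starts just beyond the core, so EHH at the core itself is 1.
// At each step the EHH of the combined panel and of the two sub-panels is the
// probability that two random chromosomes of that panel are identical from the
// core through the current site. The walk stops after the first step where the
// combined-panel EHH drops below `cutoff` (that step is kept); `edge` is true
// when the chromosome end was reached first.
//
// Returns a list: idx (1-based site indices walked), ehh (steps x 3 matrix:
// combined, focal, control; control column is NA for a single panel), edge.
// [[Rcpp::export(name = ".ehh_walk_cpp")]]
List ehh_walk_cpp(const IntegerMatrix& A, int core, int dir, double cutoff, int nf) {
  const int m = A.nrow(), n = A.ncol();
  const int from = core - 1;  // 0-based
  const int nsteps_max = dir > 0 ? (m - 1 - from) : from;
  std::vector<int> grp(n, 0);
  std::vector<int> relabel;
  IntegerVector idx(nsteps_max);
  NumericMatrix ehh(nsteps_max, 3);
  const double den_all = n * (n - 1) / 2.0;
  const double den_f = nf * (nf - 1) / 2.0;
  const int nc = n - nf;
  const double den_c = nc * (nc - 1) / 2.0;
  int used = 0;
  bool edge = true;
  int ngroups = 1;
  std::vector<double> cnt_all, cnt_f, cnt_c;
  for (int st = 0; st < nsteps_max; ++st) {
    const int site = from + dir * (st + 1);
    // refine groups by the allele at this site
    relabel.assign(2 * ngroups + 2, -1);
    int next_id = 0;
    for (int j = 0; j < n; ++j) {
      const int key = 2 * grp[j] + A(site, j);
      if (relabel[key] < 0) relabel[key] = next_id++;
      grp[j] = relabel[key];
    }
    ngroups = next_id;
    cnt_all.assign(ngroups, 0.0);
    cnt_f.assign(ngroups, 0.0);
    cnt_c.assign(ngroups, 0.0);
    for (int j = 0; j < n; ++j) {
      cnt_all[grp[j]] += 1.0;
      if (j < nf) cnt_f[grp[j]] += 1.0; else cnt_c[grp[j]] += 1.0;
    }
    double h_all = 0.0, h_f = 0.0, h_c = 0.0;
    for (int g = 0; g < ngroups; ++g) {
      h_all += cnt_all[g] * (cnt_all[g] - 1.0) / 2.0;
      h_f += cnt_f[g] * (cnt_f[g] - 1.0) / 2.0;
      h_c += cnt_c[g] * (cnt_c[g] - 1.0) / 2.0;
    }
    idx[st] = site + 1;  // back to 1-based
    ehh(st, 0) = den_all > 0 ? h_all / den_all : NA_REAL;
    ehh(st, 1) = den_f > 0 ? h_f / den_f : NA_REAL;
    ehh(st, 2) = den_c > 0 ? h_c / den_c : NA_REAL;
    used = st + 1;
    if (ehh(st, 0) < cutoff) { edge = false; break; }
  }
  if (used == 0) {
    return List::create(_["idx"] = IntegerVector(0),
                        _["ehh"] = NumericMatrix(0, 3),
                        _["used"] = 0, _["edge"] = edge);
  }
  return List::create(_["idx"] = head(idx, used),
                      _["ehh"] = ehh(Range(0, used - 1), _),
                      _["used"] = used,
                      _["edge"] = edge);
}
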