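---
title: "Detecting selective sweeps from two-population resequencing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps from two-population resequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A population that has adapted to a stressful environment — here the motivating
case is an arid-adapted deer population contrasted with a related elk
population — carries the marks of recent positive selection in its genome:
loci where a beneficial allele rose quickly to fixation drag their linked
neighbourhood along, locally depressing nucleotide diversity, inflating
allele-frequency differentiation against the unselected population, and
leaving unusually long, unusually homogeneous haplotypes. `sweepscan`
implements the standard three-pronged scan for such selective sweeps:

1. **Windowed differentiation**: per-site Weir–Cockerham Fst variance
   components, combined per sliding window by the weighted ratio of sums, then
   Z-transformed as `Z(Fst) = (Fst - mean) / sd`.
2. **Windowed diversity contrast**: nucleotide diversity π per window in each
   population and the log2 ratio `log2(π_control / π_focal)`, which grows where
   the focal population lost diversity.
3. **Haplotype extension**: cross-population extended haplotype homozygosity
   (XP-EHH), `ln(iHH_focal / iHH_control)` at each core SNP, standardized
   genome-wide.

Windows in the top 5% of both `Z(Fst)` and the log2 diversity ratio
simultaneously are joint outliers; XP-EHH outlier windows are the top 5% by
window score. Outlier windows are merged into candidate regions, genes are
mapped by 1-bp overlap, the two candidate gene sets are intersected, and each
set is tested for term over-representation with a one-sided hypergeometric
test.

## Quality control upstream of the scan

The read-pair filter drops a pair when either mate has more than 10%
ambiguous bases, more than 50% bases below Phred quality 5, or an ungapped
adapter alignment longer than 10 nt with at most 10% mismatches. The SNP
filters act in a fixed order — site depth, RMS mapping quality, missingness,
minor allele frequency, proximity — with defaults (mean depth ≥ 3, MQ ≥ 20,
missing ratio ≤ 0.2, MAF ≥ 0.01, spacing < 5 bp) matching common practice for
medium-coverage population resequencing. Two choices are deliberately
documented because the conventional phrasing leaves them open:

* the per-site depth statistic is the **mean** per-sample depth (a per-sample
  minimum mode is available);
* the "< 5 bp apart, both removed" rule is extended to chains: in any run of
  sites in which every member has a neighbour closer than the spacing, all
  members are removed. A distance exactly equal to the spacing is kept.
* a genotype with any missing allele counts as missing; MAF is computed over
  the remaining alleles only.

Positional annotation assigns each SNP exactly one category with precedence
`splice_site > exon > intron > upstream/downstream > intergenic` (upstream
wins ties against downstream). Splice sites are positions within 2 bp of an
intron boundary; flanks extend 1 kb from the gene span, strand-aware. Exonic
SNPs are classified synonymous or nonsynonymous by codon translation under
the standard genetic code, reverse-complemented for minus-strand genes; stop
gain or loss counts as nonsynonymous.

## The statistics in detail

**Per-site π** is `(n/(n-1)) · 2p(1-p)` over the population's non-missing
alleles — the unbiased per-site mean pairwise difference. Windowed π divides
the sum over variant sites by the full window width, treating unobserved
sites as monomorphic; this is the conventional definition and makes values
comparable across windows regardless of SNP count.

**Weir–Cockerham components.** For two populations the among-population
component `a` and the total `a + b + c` are accumulated separately so that a
window's Fst is `Σa / Σ(a+b+c)` (the "weighted" estimator). Negative values
are retained; clamping would bias the genome-wide mean used by the
Z-transformation. Sites where either population has no called genotype, or
where the average sample size is a single diploid, yield no components.

**Z-transformation** uses the population (divide-by-N) standard deviation, so
the transformed vector has exactly mean 0 and sd 1; it errors on degenerate
input rather than producing NaN.

**Top-5% rule.** The outlier threshold is the k-th largest usable value with
`k = ceiling(0.05 · N)`; every window at or above it is flagged, so ties at
the cut enter together and with 100 distinct windows exactly five are
flagged. Cutoffs are always derived from the data being scanned and reported
in the run manifest — printed cutoff values from any particular dataset are
percentiles of that dataset, not portable constants.

**EHH and XP-EHH.** EHH at extension distance x is the probability that two
chromosomes drawn from the panel are identical at all SNPs from just beyond
the core out to x; the curve starts at 1 at the core and is non-increasing.
The grouping deliberately excludes the core site itself and is not
partitioned by core allele: the cross-population statistic compares whole
populations, and the polarity comes from the ratio of integrals. iHH is the
trapezoidal integral of EHH over genetic distance (cM), both directions
summed, each direction truncated at the first site where the EHH of the
**combined** two-population panel falls below 0.05 (the trapezoid into that
site is included). Cores whose walk reaches a chromosome end before the
cutoff are kept and flagged rather than dropped — on short test chromosomes a
strict drop would empty the scan; a strict mode is available. Normalization
is genome-wide and unbinned; the window score is the maximum (not mean) over
member cores, preserving peaks. A burn-in-based z-scoring scheme used by one
legacy implementation is not reproduced; its definition is not documented
anywhere we could verify.

**LD decay** computes r² — the squared correlation of allele indicators
across phased haplotypes, algebraically identical to `D²/(p_A q_A p_B q_B)` —
for all within-chromosome pairs up to 500 kb apart after MAF ≥ 0.05 and
missingness ≤ 0.1 screens, averages it in 1-kb distance bins, and reports the
half-decay distance: the smallest bin midpoint whose mean r² is at or below
half the curve maximum (ties resolve to the smaller distance; binned means,
not a fitted curve). Unphased genotype input is rejected rather than
approximated by a genotype-composite estimator.

**Enrichment** is the plain one-sided hypergeometric over-representation
test, one test per term with at least one candidate gene, default
significance at raw p < 0.05 and optional Bonferroni correction. Gene-length
bias correction is out of scope; the background defaults to all annotated
genes and is configurable.

## The simulator and what it emulates

`simulate_cohort()` is a forward Wright–Fisher engine: discrete generations,
binomial resampling, infinite-sites mutation, single-crossover recombination
(one crossover with probability `1 - exp(-rL)` per meiosis), an ancestral
burn-in (default 8N generations) followed by a split into focal and control
populations with piecewise-constant sizes, optional gamete migration, and an
injectable sweep under genic selection (fitnesses 1, 1+s/2, 1+s).

Forward simulation at the real parameters of a large mammal is not feasible,
so the preset is **rescaled**: population sizes and times are divided and
per-generation rates multiplied by a common factor, preserving the
population-scaled products 4Nμ (diversity), 4Nr (LD scale, via the
2.53 cM/Mb map and μ = 1.5 × 10⁻⁸, r/μ ≈ 1.69), and t/2N (drift depth). The
preset keeps the focal population's observed genome-wide diversity
(π ≈ 0.56 × 10⁻³), a split depth of ≈ 0.22 coalescent units with a
control/focal size ratio of 1.7 at the split and a recent halving of the
focal size — the demographic shape diffusion-approximation analyses infer for this
kind of population pair — and unequal cohort sizes (13 focal, 4 control
diploids) on a 500-kb
chromosome with roughly a thousand SNPs. Generation time (6.3 years) only
labels outputs.

Hard sweeps are injected as a **single derived copy** at the configured onset;
because most single copies are lost by drift, the sweep phase is replayed
from the onset (still within one seeded random stream, so runs remain
deterministic) until the allele escapes loss and reaches a minimum final
frequency (default 0.5). A standing-variation mode instead converts a
configurable fraction of haplotypes at the onset, without replay. The truth
ledger records the realized interval `position ± s/(r·ln 2Ns)` — the
classical hitchhiking scale — plus loss/fixation flags and the replay count.

What the simulator does **not** emulate: sequencing errors and genotyping
uncertainty (depth and mapping quality in the VCF are synthetic Poisson/
constant fields so the filters can be exercised, optionally corrupted),
multi-chromosome genomes (concatenate runs with distinct names), varying
recombination maps, gene conversion, overlapping or sex-linked genes.
Passing tests on this generator therefore validate the statistical machinery
and its contracts, not robustness to real-data artefacts.

## Numerical and design choices

* Windows tile from position 1 with the standard schemes (40 kb / 20 kb for
  Fst and π; 10 kb / 5 kb for XP-EHH); terminal windows are clipped. Windows
  with no usable sites, or zero π in either population, are excluded from
  ranking rather than imputed.
* Internally coordinates are 1-based inclusive; BED output is 0-based
  half-open.
* Candidate regions merge overlapping **and book-ended** outlier windows.
* All randomness flows from a single integer seed; `run_scan()` writes a
  byte-identical bundle for identical configuration, and the manifest records
  the derived cutoffs so any stage can be re-run from its inputs.
* The EHH walk is implemented in C++ (Rcpp), as is usual for haplotype
  scanners; all statistics are cross-checked in the test suite against
  brute-force R oracles at 1e-12.

## Problem sizes used by the test suite

The replicated property checks run on deliberately small instances chosen to
keep the whole suite in the minutes range while leaving the assertions sharp:
neutral calibration uses 200 replicates of a 20-diploid, 50-kb, θ = 2 panel
against Watterson's expectation; the Fst–split-time monotonicity check uses a
5-point split grid with 20 replicates per point on 50-kb chromosomes; sweep
recovery uses 20 replicates of the preset demography (s = 1 hard sweep
injected at the split, 500-kb chromosome) with a gene-dense toy annotation
(120 genes) so that candidate regions contain enough genes for gene-level
intersection statistics to be meaningful at this scale; enrichment
calibration uses 200 random candidate draws against an 800-gene background.

## Known limitations

* With only 4 control diploids (a realistic constraint for rare or
  hard-to-sample control populations), per-window control diversity
  and iHH are noisy; the diversity-ratio flag is accordingly the least stable
  of the three signals, which is faithful to the underlying design.
* On a 500-kb test chromosome a strong sweep's haplotype footprint spans a
  sizable fraction of the genome; XP-EHH integration frequently reaches the
  chromosome edge (flagged), and genome-wide normalization partially absorbs
  the sweep itself. Real applications with many chromosomes do not share
  this small-genome artefact.
* The hypergeometric enrichment test ignores gene length bias; a
  length-aware sampler can rank terms differently on real annotations.
* The simulator's single-crossover recombination underestimates multi-
  crossover events on megabase scales; at the preset's map length
  (≈ 1.3 cM per 500 kb) the error is negligible.
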