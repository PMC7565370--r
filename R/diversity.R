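#' Sliding-window scheme
#'
#' Windows tile from position 1 of each chromosome; the terminal window is
#' clipped at the chromosome end. The default is the 40 kb / 20 kb scheme used
#' for the Fst and diversity-ratio scans; the haplotype scan uses 10 kb / 5 kb.
#'
#' @param width,step window width and step in bp (`0 < step <= width`)
#' @return list of class `window_scheme`
#' @export
window_scheme <- function(width = 40000L, step = 20000L) {
  if (width <= 0 || step <= 0 || step > width) {
    stop_input("need width > 0 and 0 < step <= width")
  }
  structure(list(width = as.integer(width), step = as.integer(step)),
            class = "window_scheme")
}

## chromosome lengths used for windowing: header contigs, else last SNP
chrom_lengths_of <- function(tab) {
  chroms <- unique(tab$chrom)
  vapply(chroms, function(cc) {
    cl <- tab$contig_lengths
    if (!is.null(cl) && cc %in% names(cl) && is.finite(cl[[cc]])) {
      as.numeric(cl[[cc]])
    } else as.numeric(max(tab$pos[tab$chrom == cc]))
  }, numeric(1))
}

## per-site pi (expected heterozygosity with the n/(n-1) small-sample factor)
## for one population; returns NA where fewer than 2 alleles are called
site_pi <- function(tab, population) {
  cols <- which(unname(tab$populations) == population)
  if (length(cols) == 0L) stop_input("unknown population label '%s'", population)
  a1 <- tab$a1[, cols, drop = FALSE]; a2 <- tab$a2[, cols, drop = FALSE]
  n <- rowSums(!is.na(a1)) + rowSums(!is.na(a2))
  cnt <- rowSums(a1, na.rm = TRUE) + rowSums(a2, na.rm = TRUE)
  p <- ifelse(n > 0, cnt / n, NA_real_)
  ifelse(n >= 2, n / (n - 1) * 2 * p * (1 - p), NA_real_)
}

#' Windowed nucleotide diversity
#'
#' Per-site diversity `(n/(n-1)) * 2*p*(1-p)` over the population's non-missing
#' alleles, summed over the variant sites inside each window and divided by the
#' window width in bp (invariant sites contribute zero). A site contributes to
#' every window containing it; windows without SNPs report 0 with `n_snps = 0`.
#'
#' @param table a filtered [variant_table()]
#' @param population population label
#' @param scheme a [window_scheme()], default 40 kb / 20 kb
#' @return data.frame: chrom, start, end (1-based inclusive), n_snps, pi (per bp)
#' @export
windowed_pi <- function(table, population, scheme = window_scheme()) {
  sp <- site_pi(table, population)
  lens <- chrom_lengths_of(table)
  res <- lapply(names(lens), function(cc) {
    win <- build_windows(lens[[cc]], scheme$width, scheme$step)
    on_c <- tab_sites_on(table, cc)
    agg <- window_accumulate(table$pos[on_c], cbind(pi = sp[on_c]), win)
    data.frame(chrom = cc, start = win$start, end = win$end,
               n_snps = agg$n, pi = ifelse(is.na(agg$sums[, "pi"]), 0,
                                           agg$sums[, "pi"]) / (win$end - win$start + 1))
  })
  do.call(rbind, res)
}

tab_sites_on <- function(tab, chrom) which(tab$chrom == chrom)

## sum site values over sliding windows; values is a matrix with one column per
## statistic; NA values are skipped per column but counted in n (site count)
window_accumulate <- function(pos, values, windows) {
  nw <- nrow(windows)
  sums <- matrix(0, nw, ncol(values), dimnames = list(NULL, colnames(values)))
  n <- integer(nw)
  width <- windows$end[1] - windows$start[1] + 1L
  step <- if (nw > 1L) windows$start[2] - windows$start[1] else width
  for (i in seq_along(pos)) {
    p <- pos[i]
    last <- min(nw, (p - 1L) %/% step + 1L)
    first <- max(1L, last - (ceiling(width / step) - 1L))
    for (w in first:last) {
      if (p >= windows$start[w] && p <= windows$end[w]) {
        n[w] <- n[w] + 1L
        v <- values[i, ]
        ok <- !is.na(v)
        sums[w, ok] <- sums[w, ok] + v[ok]
      }
    }
  }
  sums[n == 0L, ] <- NA_real_
  list(sums = sums, n = n)
}

#' LD computation settings
#'
#' Defaults mirror common practice for decay curves from resequencing panels:
#' pairs up to 500 kb apart, sites screened at minor allele frequency >= 0.05
#' and missing-haplotype fraction <= 0.1, distances binned at 1 kb.
#'
#' @param max_dist maximum pair distance in bp
#' @param min_maf,max_miss site screens
#' @param bin_width distance bin width in bp
#' @param max_sites optional cap on the number of sites used (evenly thinned)
#' @return list of class `ld_config`
#' @export
ld_config <- function(max_dist = 500000L, min_maf = 0.05, max_miss = 0.1,
                      bin_width = 1000L, max_sites = Inf) {
  if (max_dist <= 0 || bin_width <= 0) stop_input("distances must be positive")
  if (min_maf < 0 || min_maf > 0.5) stop_input("min_maf must be in [0,0.5]")
  structure(list(max_dist = as.integer(max_dist), min_maf = min_maf,
                 max_miss = max_miss, bin_width = as.integer(bin_width),
                 max_sites = max_sites), class = "ld_config")
}

#' Squared allele-frequency correlation between two sites
#'
#' `r^2 = D^2 / (pA(1-pA) pB(1-pB))` with `D = pAB - pA pB`, computed from
#' phased haplotype alleles; haplotypes missing at either site are excluded
#' pairwise. Returns NA when either site is monomorphic after exclusion.
#'
#' @param x,y 0/1 allele vectors over the same haplotypes (NA = missing)
#' @return r-squared in `[0, 1]`, or NA
#' @export
pairwise_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  pa <- mean(x); pb <- mean(y)
  if (length(x) == 0L || pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  d <- mean(x * y) - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Linkage-disequilibrium decay curve
#'
#' Computes r-squared for every within-chromosome site pair up to `max_dist`
#' apart (after the MAF and missingness screens) and averages it in distance
#' bins. r-squared is the squared Pearson correlation of haplotype alleles
#' with pairwise-complete exclusion, identical to the two-locus
#' haplotype-frequency formula.
#'
#' @param cohort a `phased_cohort` (or a phased [variant_table()])
#' @param config an [ld_config()]
#' @param population optional population label to subset haplotypes
#' @return data.frame of class `ld_curve`: bin_mid, mean_r2, n_pairs
#' @export
ld_decay <- function(cohort, config = ld_config(), population = NULL) {
  if (inherits(cohort, "variant_table")) {
    if (!isTRUE(cohort$phased)) stop_input("ld_decay needs phased haplotypes")
    cohort <- cohort_from_table(cohort)
  }
  A <- cohort$alleles
  pos <- cohort$positions
  if (!is.null(population)) A <- A[, cohort_hap_cols(cohort, population), drop = FALSE]
  miss <- rowMeans(is.na(A))
  p <- rowMeans(A, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  keep <- which(miss <= config$max_miss & !is.na(maf) & maf >= config$min_maf)
  if (length(keep) > config$max_sites) {
    keep <- keep[unique(round(seq(1, length(keep), length.out = config$max_sites)))]
  }
  A <- A[keep, , drop = FALSE]; pos <- pos[keep]
  bins <- seq(config$bin_width, config$max_dist, by = config$bin_width)
  sums <- numeric(length(bins)); counts <- integer(length(bins))
  if (length(pos) >= 2L) {
    r2m <- suppressWarnings(stats::cor(t(A), use = "pairwise.complete.obs"))^2
    dm <- abs(outer(pos, pos, "-"))
    up <- upper.tri(dm)
    d <- dm[up]; r2 <- r2m[up]
    ok <- d <= config$max_dist & !is.na(r2)
    d <- d[ok]; r2 <- r2[ok]
    bi <- pmin(length(bins), (d - 1L) %/% config$bin_width + 1L)
    if (length(bi)) {
      sums <- as.numeric(tapply(r2, factor(bi, levels = seq_along(bins)), sum, default = 0))
      counts <- as.integer(tapply(r2, factor(bi, levels = seq_along(bins)), length, default = 0L))
    }
  } else {
    warning("no eligible site pairs; empty LD curve")
  }
  out <- data.frame(bin_mid = bins - config$bin_width / 2,
                    mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
                    n_pairs = counts)
  class(out) <- c("ld_curve", class(out))
  out
}

## variant_table -> phased cohort view (requires phased genotypes)
cohort_from_table <- function(tab) {
  n <- length(tab$samples)
  A <- matrix(NA_integer_, n_sites(tab), 2L * n)
  A[, seq(1L, 2L * n, 2L)] <- tab$a1
  A[, seq(2L, 2L * n, 2L)] <- tab$a2
  lens <- chrom_lengths_of(tab)
  structure(list(chrom = tab$chrom[1], sequence_length = unname(lens[1]),
                 positions = tab$pos, cm = NULL, alleles = A,
                 sample_ids = tab$samples,
                 populations = tab$populations,
                 hap_sample = rep(seq_len(n), each = 2L),
                 config = NULL), class = "phased_cohort")
}

#' Half-maximum LD decay distance
#'
#' The smallest distance-bin midpoint at which the mean r-squared has dropped
#' to half of the curve maximum or below; ties at the threshold resolve to the
#' smaller distance by construction.
#'
#' @param curve an `ld_curve` from [ld_decay()]
#' @return list with `distance_bp` (NA when never reached), `half_value`
#'   (the r-squared threshold) and `reached`
#' @export
half_decay_distance <- function(curve) {
  ok <- !is.na(curve$mean_r2)
  if (!any(ok)) stop_input("empty LD curve")
  mx <- max(curve$mean_r2[ok])
  thr <- mx / 2
  idx <- which(ok & curve$mean_r2 <= thr)
  if (length(idx) == 0L) {
    return(list(distance_bp = NA_real_, half_value = thr, reached = FALSE))
  }
  list(distance_bp = curve$bin_mid[min(idx)], half_value = thr, reached = TRUE)
}
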