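#' Read a genetic map TSV
#'
#' Expects columns chrom, bp, cM (header optional ignored by name matching);
#' cM must be non-decreasing in bp within each chromosome.
#'
#' @param path TSV path
#' @return data.frame of class `genetic_map`
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  names(df) <- tolower(names(df))
  names(df)[names(df) == "cm"] <- "cM"
  if (!all(c("chrom", "bp", "cM") %in% names(df))) {
    stop_input("genetic map needs columns chrom, bp, cM")
  }
  for (cc in unique(df$chrom)) {
    sub <- df[df$chrom == cc, ]
    if (is.unsorted(sub$bp) || is.unsorted(sub$cM)) {
      stop_input("genetic map must be non-decreasing in bp and cM (%s)", cc)
    }
  }
  class(df) <- c("genetic_map", class(df))
  df
}

#' Constant-rate genetic map
#'
#' @param chrom chromosome name
#' @param length_bp chromosome length
#' @param cm_per_mb constant rate, default 2.53 cM/Mb
#' @return data.frame of class `genetic_map`
#' @export
constant_genetic_map <- function(chrom, length_bp, cm_per_mb = 2.53) {
  df <- data.frame(chrom = chrom, bp = c(1, length_bp),
                   cM = c(1, length_bp) * cm_per_mb / 1e6)
  class(df) <- c("genetic_map", class(df))
  df
}

#' Interpolate genetic positions
#'
#' Linear interpolation of cM at bp positions; positions outside the mapped
#' range are an input error.
#'
#' @param map a `genetic_map`
#' @param chrom chromosome
#' @param pos bp positions
#' @return cM positions
#' @export
map_cm <- function(map, chrom, pos) {
  sub <- map[map$chrom == chrom, ]
  if (nrow(sub) < 2L) stop_input("genetic map does not cover chromosome %s", chrom)
  if (any(pos < min(sub$bp) | pos > max(sub$bp))) {
    stop_input("positions outside the genetic map range on %s", chrom)
  }
  stats::approx(sub$bp, sub$cM, xout = pos, ties = "ordered")$y
}

## check a haplotype matrix is phased and complete
check_phased <- function(A) {
  if (anyNA(A)) stop_input("unphased or missing haplotype alleles are not supported")
  invisible(TRUE)
}

## EHH walk outward from `core` in `dir` (+1 right, -1 left), backed by the
## compiled kernel. `A` holds the combined panel; its first `nf` columns are
## the focal sub-panel. Haplotype grouping starts beyond the core site (EHH at
## the core itself is 1). Stops after the first step where the combined panel
## drops below `cutoff` (that site included); `edge` is TRUE when the
## chromosome end was reached first. The returned `ehh` matrix has columns
## combined, focal, control.
walk_ehh <- function(A, core, dir, cutoff = 0, nf = ncol(A)) {
  storage.mode(A) <- "integer"
  .ehh_walk_cpp(A, as.integer(core), as.integer(dir), cutoff, as.integer(nf))
}

#' Extended haplotype homozygosity curve from a core site
#'
#' EHH at extension distance x is the probability that two randomly drawn
#' chromosomes of the panel are identical over all sites from just beyond the
#' core out to x: `sum over groups of C(c,2) / C(n,2)`. The curve starts at 1
#' at the core and is non-increasing with distance.
#'
#' @param haplotypes sites x haplotypes 0/1 matrix (phased, no missing data)
#' @param core core site row index (must be polymorphic)
#' @param direction "left" or "right"
#' @param positions optional bp positions per site (for bp distances)
#' @param cm optional cM positions per site (for genetic distances)
#' @return data.frame: site, bp_dist, cm_dist, ehh — first row is the core
#'   with distance 0 and EHH 1
#' @export
ehh_curve <- function(haplotypes, core, direction = c("right", "left"),
                      positions = NULL, cm = NULL) {
  direction <- match.arg(direction)
  check_phased(haplotypes)
  if (ncol(haplotypes) < 2L) stop_input("need at least 2 haplotypes")
  p <- mean(haplotypes[core, ])
  if (p %in% c(0, 1)) stop_input("core site must be polymorphic")
  w <- walk_ehh(haplotypes, core, if (direction == "right") 1L else -1L)
  site <- c(core, w$idx)
  data.frame(site = site,
             bp_dist = if (is.null(positions)) NA_real_ else abs(positions[site] - positions[core]),
             cm_dist = if (is.null(cm)) NA_real_ else abs(cm[site] - cm[core]),
             ehh = c(1, w$ehh[, 1]))
}

## trapezoidal integral of an EHH curve over cM distance, starting at
## (0, 1) for the core
trapz_ehh <- function(cm_dist, ehh) {
  d <- c(0, cm_dist); e <- c(1, ehh)
  sum((e[-1] + e[-length(e)]) / 2 * diff(d))
}

#' Integrated EHH at a core site
#'
#' Trapezoidal integral of the EHH curve over genetic distance (cM), summed
#' over both directions. Each direction is truncated at the first site where
#' the stopping panel's EHH drops below `cutoff` (the trapezoid into that site
#' is included). By default the stopping rule is evaluated on the panel itself;
#' the cross-population scan passes the combined two-population panel via
#' `stop_haplotypes`. If a chromosome edge is reached before the cutoff, the
#' truncation flag is set.
#'
#' @param haplotypes sites x haplotypes 0/1 matrix (phased)
#' @param core core site row index
#' @param cm per-site genetic positions in cM (same row order)
#' @param cutoff EHH stopping threshold, default 0.05
#' @param stop_haplotypes optional wider panel whose EHH drives the stopping
#'   rule; `haplotypes` must form its first columns
#' @return list: ihh, left, right, truncated (TRUE when an edge was hit first),
#'   undefined (TRUE when the integration support has zero length)
#' @export
ihh <- function(haplotypes, core, cm, cutoff = 0.05, stop_haplotypes = NULL) {
  check_phased(haplotypes)
  nf <- ncol(haplotypes)
  A <- if (is.null(stop_haplotypes)) haplotypes else stop_haplotypes
  if (!is.null(stop_haplotypes)) {
    check_phased(stop_haplotypes)
    if (!identical(unname(stop_haplotypes[, seq_len(nf), drop = FALSE]),
                   unname(haplotypes))) {
      stop_input("haplotypes must form the first columns of stop_haplotypes")
    }
  }
  res <- lapply(c(1L, -1L), function(dir) walk_ehh(A, core, dir, cutoff, nf))
  vals <- vapply(res, function(w) {
    if (length(w$idx) == 0L) return(0)
    trapz_ehh(abs(cm[w$idx] - cm[core]), w$ehh[, 2])
  }, numeric(1))
  truncated <- res[[1]]$edge || res[[2]]$edge
  total <- sum(vals)
  list(ihh = total, right = vals[1], left = vals[2], truncated = truncated,
       undefined = total == 0)
}

#' Raw cross-population EHH score at one core site
#'
#' `ln(iHH_focal / iHH_control)`, with both integrals truncated where the EHH
#' of the combined two-population panel falls below `cutoff`. A positive score
#' means longer haplotypes (slower EHH decay) in the focal population. Cores
#' where either iHH is zero or undefined are reported with an NA score and a
#' reason.
#'
#' @param focal_h,control_h sites x haplotypes matrices over the same site rows
#' @param core core site row index (polymorphic in the combined panel)
#' @param cm per-site genetic positions in cM
#' @param cutoff combined-panel EHH stopping threshold, default 0.05
#' @return list: raw, ihh_focal, ihh_control, truncated, reason (NA when usable)
#' @export
xpehh_raw <- function(focal_h, control_h, core, cm, cutoff = 0.05) {
  check_phased(focal_h); check_phased(control_h)
  combined <- cbind(focal_h, control_h)
  p <- mean(combined[core, ])
  if (p %in% c(0, 1)) stop_input("core site must be polymorphic in the combined panel")
  res <- lapply(c(1L, -1L), function(dir) {
    walk_ehh(combined, core, dir, cutoff, nf = ncol(focal_h))
  })
  integrate_panel <- function(col) {
    sum(vapply(res, function(w) {
      if (length(w$idx) == 0L) return(0)
      trapz_ehh(abs(cm[w$idx] - cm[core]), w$ehh[, col])
    }, numeric(1)))
  }
  ihh_f <- integrate_panel(2L)
  ihh_c <- integrate_panel(3L)
  truncated <- res[[1]]$edge || res[[2]]$edge
  reason <- NA_character_
  raw <- NA_real_
  if (ihh_f <= 0 || ihh_c <= 0) {
    reason <- "zero_ihh"
  } else {
    raw <- log(ihh_f / ihh_c)
  }
  list(raw = raw, ihh_focal = ihh_f, ihh_control = ihh_c,
       truncated = truncated, reason = reason)
}

#' Cross-population EHH scan over all core sites
#'
#' Computes [xpehh_raw()] at every site polymorphic in the combined panel
#' (optionally a subset), on genetic positions from `map` (default: the
#' cohort's own cM coordinates).
#'
#' @param cohort a `phased_cohort` with two populations
#' @param focal,control population labels
#' @param map optional `genetic_map`; default uses `cohort$cm`
#' @param cutoff combined-panel EHH stopping threshold, default 0.05
#' @param cores optional integer site indices to use as cores
#' @param drop_truncated drop cores whose EHH never reached the cutoff before
#'   a chromosome edge (strict mode); default FALSE, keep with a flag
#' @return data.frame of class `xpehh_records`: chrom, pos, ihh_focal,
#'   ihh_control, raw, truncated, reason
#' @export
xpehh_scan <- function(cohort, focal, control, map = NULL, cutoff = 0.05,
                       cores = NULL, drop_truncated = FALSE) {
  fc <- cohort_hap_cols(cohort, focal)
  cc <- cohort_hap_cols(cohort, control)
  A <- cohort$alleles
  check_phased(A)
  cm <- if (is.null(map)) cohort$cm else map_cm(map, cohort$chrom, cohort$positions)
  if (is.null(cm)) stop_input("no genetic positions available; supply a map")
  if (is.null(cores)) cores <- seq_len(nrow(A))
  Af <- A[, fc, drop = FALSE]; Ac <- A[, cc, drop = FALSE]
  p_all <- rowMeans(A[, c(fc, cc), drop = FALSE])
  cores <- cores[!(p_all[cores] %in% c(0, 1))]
  nk <- length(cores)
  ihh_f <- ihh_c <- raw <- rep(NA_real_, nk)
  trunc <- logical(nk)
  reason <- rep(NA_character_, nk)
  for (i in seq_len(nk)) {
    r <- xpehh_raw(Af, Ac, cores[i], cm, cutoff)
    ihh_f[i] <- r$ihh_focal; ihh_c[i] <- r$ihh_control
    raw[i] <- r$raw; trunc[i] <- r$truncated; reason[i] <- r$reason
  }
  res <- data.frame(chrom = rep(cohort$chrom, nk), pos = cohort$positions[cores],
                    ihh_focal = ihh_f, ihh_control = ihh_c, raw = raw,
                    truncated = trunc, reason = reason)
  if (drop_truncated) res <- res[!res$truncated, , drop = FALSE]
  class(res) <- c("xpehh_records", class(res))
  res
}

#' Genome-wide normalization of raw XP-EHH scores
#'
#' Standardizes the usable raw scores by their genome-wide mean and population
#' standard deviation (unbinned), adding a `normalized` column with mean 0 and
#' sd 1 over usable cores.
#'
#' @param records an `xpehh_records` data.frame from [xpehh_scan()]
#' @return `records` with a `normalized` column
#' @export
normalize_xpehh <- function(records) {
  records$normalized <- z_transform(records$raw)
  records
}

#' Windowed XP-EHH outliers
#'
#' Window score is the maximum normalized score over in-window cores (peaks
#' are preserved); windows without cores are excluded. Outliers are windows at
#' or above the tie-inclusive top-`1 - quantile` threshold; genes are mapped
#' onto merged outlier regions as in [merge_and_map()].
#'
#' @param records normalized `xpehh_records` (see [normalize_xpehh()])
#' @param scheme a [window_scheme()], default 10 kb / 5 kb
#' @param quantile outlier quantile, default 0.95
#' @param genes optional `gene_models` for candidate-gene mapping
#' @param chrom_lengths optional named chromosome lengths
#' @return data.frame of windows (chrom, start, end, n_cores, score, outlier)
#'   with attributes `cutoff`, `regions` and `genes`
#' @export
xpehh_windows <- function(records, scheme = window_scheme(10000L, 5000L),
                          quantile = 0.95, genes = NULL, chrom_lengths = NULL) {
  if (!"normalized" %in% names(records)) stop_input("normalize records first")
  use <- records[is.finite(records$normalized), , drop = FALSE]
  chroms <- unique(use$chrom)
  res <- lapply(chroms, function(cc) {
    sel <- use$chrom == cc
    len <- if (!is.null(chrom_lengths) && cc %in% names(chrom_lengths)) {
      chrom_lengths[[cc]]
    } else max(use$pos[sel])
    win <- build_windows(len, scheme$width, scheme$step)
    score <- rep(NA_real_, nrow(win))
    n_cores <- integer(nrow(win))
    pos <- use$pos[sel]; val <- use$normalized[sel]
    for (w in seq_len(nrow(win))) {
      inw <- pos >= win$start[w] & pos <= win$end[w]
      n_cores[w] <- sum(inw)
      if (n_cores[w] > 0L) score[w] <- max(val[inw])
    }
    data.frame(chrom = cc, start = win$start, end = win$end,
               n_cores = n_cores, score = score)
  })
  win <- do.call(rbind, res)
  win <- win[win$n_cores > 0L, , drop = FALSE]
  thr <- top_fraction_threshold(win$score, quantile)
  win$outlier <- win$score >= thr
  attr(win, "cutoff") <- thr
  if (!is.null(genes)) {
    reg <- merge_and_map(win[win$outlier, , drop = FALSE], genes)
    attr(win, "regions") <- reg
    attr(win, "genes") <- attr(reg, "genes")
  }
  win
}
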