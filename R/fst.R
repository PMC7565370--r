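#' Per-site Weir-Cockerham variance components for two populations
#'
#' Computes the Weir-Cockerham (1984) moment-estimator components from diploid
#' genotypes: `a` (among-population variance, the numerator) and `a + b + c`
#' (the denominator). Sites where either population has fewer than two
#' non-missing allele copies, or where the estimator is undefined (average
#' sample size of one diploid), get NA components.
#'
#' @param table a [variant_table()] with exactly two population labels
#' @return data.frame: chrom, pos, num (a), den (a + b + c)
#' @export
per_site_fst_components <- function(table) {
  pops <- unique(unname(table$populations))
  if (length(pops) != 2L) stop_input("exactly two populations required, got %d", length(pops))
  r <- 2
  stats_pop <- lapply(pops, function(pp) {
    cols <- which(unname(table$populations) == pp)
    a1 <- table$a1[, cols, drop = FALSE]; a2 <- table$a2[, cols, drop = FALSE]
    called <- !is.na(a1)
    n <- rowSums(called)                       # diploids with a genotype
    p <- ifelse(n > 0, (rowSums(a1, na.rm = TRUE) + rowSums(a2, na.rm = TRUE)) / (2 * n), NA_real_)
    h <- ifelse(n > 0, rowSums(a1 != a2, na.rm = TRUE) / n, NA_real_)
    list(n = n, p = p, h = h)
  })
  n1 <- stats_pop[[1]]$n; n2 <- stats_pop[[2]]$n
  p1 <- stats_pop[[1]]$p; p2 <- stats_pop[[2]]$p
  h1 <- stats_pop[[1]]$h; h2 <- stats_pop[[2]]$h
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  num <- a
  den <- a + b + cc
  bad <- n1 < 1 | n2 < 1 | nbar <= 1 | !is.finite(num) | !is.finite(den)
  num[bad] <- NA_real_; den[bad] <- NA_real_
  data.frame(chrom = table$chrom, pos = table$pos, num = num, den = den)
}

#' Windowed Fst by the weighted ratio of sums
#'
#' Window Fst is the sum of the per-site Weir-Cockerham numerators divided by
#' the sum of denominators over in-window sites (the "weighted" estimator).
#' Negative window values are retained as computed; windows without usable
#' sites get NA and are excluded from downstream ranking. A mean-of-ratios
#' variant is available for comparison.
#'
#' @param components output of [per_site_fst_components()]
#' @param scheme a [window_scheme()]
#' @param chrom_lengths named chromosome lengths (defaults to the last site)
#' @param mode "ratio_of_sums" (default) or "mean_of_ratios"
#' @return data.frame: chrom, start, end, n_snps, fst
#' @export
windowed_fst <- function(components, scheme = window_scheme(), chrom_lengths = NULL,
                         mode = c("ratio_of_sums", "mean_of_ratios")) {
  mode <- match.arg(mode)
  chroms <- unique(components$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(cc) {
      as.numeric(max(components$pos[components$chrom == cc]))
    }, numeric(1))
  }
  res <- lapply(chroms, function(cc) {
    sel <- components$chrom == cc & !is.na(components$num) & !is.na(components$den)
    win <- build_windows(chrom_lengths[[cc]], scheme$width, scheme$step)
    vals <- if (mode == "ratio_of_sums") {
      cbind(num = components$num[sel], den = components$den[sel])
    } else {
      cbind(ratio = ifelse(components$den[sel] != 0,
                           components$num[sel] / components$den[sel], NA_real_))
    }
    agg <- window_accumulate(components$pos[sel], vals, win)
    fst <- if (mode == "ratio_of_sums") {
      ifelse(agg$n > 0 & agg$sums[, "den"] != 0, agg$sums[, "num"] / agg$sums[, "den"], NA_real_)
    } else {
      ifelse(agg$n > 0, agg$sums[, "ratio"] / agg$n, NA_real_)
    }
    data.frame(chrom = cc, start = win$start, end = win$end, n_snps = agg$n, fst = fst)
  })
  do.call(rbind, res)
}

#' Log2 diversity ratio per window
#'
#' `log2(pi_control / pi_focal)` for aligned window sets; a sweep in the focal
#' population depresses its diversity and drives the ratio up. Windows where
#' either diversity is zero (or missing) are flagged unusable (NA).
#'
#' @param pi_control,pi_focal per-window diversity vectors, same window order
#' @return numeric vector, NA where unusable
#' @export
log2_pi_ratio <- function(pi_control, pi_focal) {
  if (length(pi_control) != length(pi_focal)) stop_input("misaligned window sets")
  ok <- !is.na(pi_control) & !is.na(pi_focal) & pi_control > 0 & pi_focal > 0
  out <- rep(NA_real_, length(pi_focal))
  out[ok] <- log2(pi_control[ok] / pi_focal[ok])
  out
}

#' Joint Fst / diversity-ratio outlier windows
#'
#' Flags windows in the top `1 - quantile` tail of Z(Fst) (`fst_top`) and of
#' the log2 diversity ratio (`ratio_top`), with the tie-inclusive threshold of
#' [top_fraction_threshold()] computed over usable windows only; `joint` marks
#' windows flagged by both. Z(Fst) is computed here over usable windows via
#' [z_transform()].
#'
#' @param windows data.frame with `fst` and `log2_ratio` columns (one row per
#'   window), e.g. from [fst_pi_scan()]
#' @param quantile outlier quantile, default 0.95
#' @return `windows` with added columns z_fst, fst_top, ratio_top, joint
#' @export
joint_outliers <- function(windows, quantile = 0.95) {
  usable <- is.finite(windows$fst) & is.finite(windows$log2_ratio)
  if (sum(usable) < 20L) {
    warning(sprintf("only %d usable windows; outlier quantiles are unstable", sum(usable)))
  }
  z <- rep(NA_real_, nrow(windows))
  z[is.finite(windows$fst)] <- z_transform(windows$fst[is.finite(windows$fst)])
  windows$z_fst <- z
  thr_f <- top_fraction_threshold(windows$z_fst[usable], quantile)
  thr_r <- top_fraction_threshold(windows$log2_ratio[usable], quantile)
  windows$fst_top <- usable & windows$z_fst >= thr_f
  windows$ratio_top <- usable & windows$log2_ratio >= thr_r
  windows$joint <- windows$fst_top & windows$ratio_top
  attr(windows, "cutoffs") <- c(z_fst = thr_f, log2_ratio = thr_r)
  windows
}

#' Combined Fst and diversity-ratio window scan
#'
#' Runs [per_site_fst_components()], [windowed_fst()], [windowed_pi()] for both
#' populations and [log2_pi_ratio()] on one window scheme, then calls
#' [joint_outliers()].
#'
#' @param table a filtered [variant_table()] with two populations
#' @param focal,control population labels; the ratio is control over focal
#' @param scheme a [window_scheme()], default 40 kb / 20 kb
#' @param quantile outlier quantile, default 0.95
#' @return window data.frame with fst, pi_focal, pi_control, log2_ratio,
#'   z_fst and outlier flags; cutoffs in the `cutoffs` attribute
#' @export
fst_pi_scan <- function(table, focal, control, scheme = window_scheme(),
                        quantile = 0.95) {
  comp <- per_site_fst_components(table)
  lens <- chrom_lengths_of(table)
  wfst <- windowed_fst(comp, scheme, lens)
  pf <- windowed_pi(table, focal, scheme)
  pc <- windowed_pi(table, control, scheme)
  stopifnot(nrow(wfst) == nrow(pf), nrow(wfst) == nrow(pc))
  wfst$pi_focal <- pf$pi
  wfst$pi_control <- pc$pi
  wfst$log2_ratio <- log2_pi_ratio(pc$pi, pf$pi)
  joint_outliers(wfst, quantile)
}

#' Merge outlier windows into candidate regions and map genes
#'
#' Overlapping or book-ended outlier windows are merged into maximal regions;
#' a gene is assigned to a region when their spans overlap by at least 1 bp.
#'
#' @param outliers data.frame of outlier windows (chrom, start, end)
#' @param genes a `gene_models` object, or a data.frame with gene_id, chrom,
#'   start, end
#' @return data.frame: chrom, start, end, n_windows, genes (comma-separated);
#'   the full gene list is in the `genes` attribute
#' @export
merge_and_map <- function(outliers, genes) {
  gdf <- if (inherits(genes, "gene_models")) genes$genes else genes
  if (nrow(outliers) == 0L) {
    out <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      n_windows = integer(0), genes = character(0))
    attr(out, "genes") <- character(0)
    return(out)
  }
  win_gr <- GenomicRanges::GRanges(outliers$chrom,
                                   IRanges::IRanges(outliers$start, outliers$end))
  reg_gr <- GenomicRanges::reduce(win_gr)   # merges overlapping and book-ended
  n_win <- GenomicRanges::countOverlaps(reg_gr, win_gr)
  gene_str <- rep("", length(reg_gr))
  all_genes <- character(0)
  if (nrow(gdf) > 0L) {
    gene_gr <- GenomicRanges::GRanges(gdf$chrom, IRanges::IRanges(gdf$start, gdf$end))
    hits <- GenomicRanges::findOverlaps(reg_gr, gene_gr, minoverlap = 1L)
    by_reg <- split(gdf$gene_id[S4Vectors::subjectHits(hits)], S4Vectors::queryHits(hits))
    for (k in names(by_reg)) gene_str[as.integer(k)] <- paste(sort(unique(by_reg[[k]])), collapse = ",")
    all_genes <- sort(unique(gdf$gene_id[S4Vectors::subjectHits(hits)]))
  }
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(reg_gr)),
                    start = GenomicRanges::start(reg_gr),
                    end = GenomicRanges::end(reg_gr),
                    n_windows = n_win, genes = gene_str)
  attr(out, "genes") <- all_genes
  out
}
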