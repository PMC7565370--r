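#' @keywords internal
#' @useDynLib sweepscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

## input-validation helper used across modules
stop_input <- function(...) stop(sprintf(...), call. = FALSE)

#' Threshold for the top fraction of a vector, ties included
#'
#' Returns the k-th largest finite value with `k = ceiling((1 - quantile) * N)`,
#' where N is the number of finite values. Values greater than or equal to the
#' threshold form the top `(1 - quantile)` tail; ties at the threshold are all
#' included. With 100 distinct values and `quantile = 0.95` exactly the top 5
#' exceed-or-equal the threshold.
#'
#' @param x numeric vector (non-finite entries ignored)
#' @param quantile lower-tail fraction excluded, default 0.95
#' @return the threshold value
#' @export
top_fraction_threshold <- function(x, quantile = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) stop_input("no finite values to rank")
  ## guard the ceiling against floating-point noise in (1 - quantile) * n
  k <- max(1L, as.integer(ceiling((1 - quantile) * n - 1e-9)))
  sort(x, decreasing = TRUE)[k]
}

## population (divide-by-N) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Z-transform a vector by its mean and population standard deviation
#'
#' Standardizes as `(x - mean) / sd` with the population (divide-by-N) standard
#' deviation, so the output has mean 0 and population sd 1. Non-finite entries
#' are ignored for the moments and returned as NA.
#'
#' @param values numeric vector with at least two finite values and nonzero spread
#' @return standardized vector, same length as the input
#' @export
z_transform <- function(values) {
  ok <- is.finite(values)
  x <- values[ok]
  if (length(x) < 2L) stop_input("z_transform needs at least 2 finite values")
  s <- pop_sd(x)
  if (s == 0) stop_input("z_transform undefined for zero spread")
  out <- rep(NA_real_, length(values))
  out[ok] <- (x - mean(x)) / s
  out
}

## strict integer-ish check
is_count <- function(x, min = 0) length(x) == 1L && is.finite(x) && x >= min && x == floor(x)

## reverse complement for plain ACGT character strings
revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca", vapply(s, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

complement_base <- function(b) chartr("ACGTacgt", "TGCAtgca", b)

## sliding windows tiling from position 1; ends clipped at chrom_length
build_windows <- function(chrom_length, width, step) {
  stopifnot(width > 0, step > 0, step <= width)
  starts <- seq.int(1L, max(1L, as.integer(chrom_length)), by = as.integer(step))
  ends <- pmin.int(starts + as.integer(width) - 1L, as.integer(chrom_length))
  keep <- starts <= chrom_length
  data.frame(start = starts[keep], end = ends[keep])
}

#' Three-way partition of two gene sets
#'
#' Splits two candidate-gene sets into exclusive and shared parts, as drawn in a
#' two-set Venn diagram.
#'
#' @param set_a,set_b character vectors of gene identifiers (duplicates ignored)
#' @return list with `a_only`, `shared`, `b_only` (sorted) and `counts`
#' @export
intersect_gene_sets <- function(set_a, set_b) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  shared <- sort(intersect(a, b))
  a_only <- sort(setdiff(a, b))
  b_only <- sort(setdiff(b, a))
  list(a_only = a_only, shared = shared, b_only = b_only,
       counts = c(a_only = length(a_only), shared = length(shared), b_only = length(b_only)))
}
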