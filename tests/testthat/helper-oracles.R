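# Independent brute-force oracles. These re-derive each statistic from first
# principles by a route different from the package implementation, so that
# agreement is evidence of correctness rather than shared code.

## mean pairwise difference at one site: loop over all haplotype pairs
oracle_site_pi <- function(alleles) {
  alleles <- alleles[!is.na(alleles)]
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) tot <- tot + (alleles[i] != alleles[j])
  tot / choose(n, 2)
}

## windowed pi oracle: sum of per-site pairwise differences over window width
oracle_windowed_pi <- function(pos, hap, start, end) {
  inw <- which(pos >= start & pos <= end)
  if (length(inw) == 0) return(0)
  sum(vapply(inw, function(i) oracle_site_pi(hap[i, ]), numeric(1))) / (end - start + 1)
}

## literal transcription of the Weir & Cockerham (1984) two-population
## estimator, computed per site from per-population genotype vectors (each a
## matrix of two allele columns, NA for missing)
oracle_wc_components <- function(g1a, g1b, g2a, g2b) {
  r <- 2
  pop_stats <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    n <- sum(ok)
    list(n = n,
         p = if (n > 0) sum(a[ok] + b[ok]) / (2 * n) else NA,
         h = if (n > 0) mean(a[ok] != b[ok]) else NA)
  }
  s1 <- pop_stats(g1a, g1b); s2 <- pop_stats(g2a, g2b)
  if (s1$n < 1 || s2$n < 1) return(c(num = NA, den = NA))
  n_bar <- (s1$n + s2$n) / r
  if (n_bar <= 1) return(c(num = NA, den = NA))
  n_c <- (r * n_bar - (s1$n^2 + s2$n^2) / (r * n_bar)) / (r - 1)
  p_bar <- (s1$n * s1$p + s2$n * s2$p) / (r * n_bar)
  s2v <- (s1$n * (s1$p - p_bar)^2 + s2$n * (s2$p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (s1$n * s1$h + s2$n * s2$h) / (r * n_bar)
  a <- n_bar / n_c *
    (s2v - 1 / (n_bar - 1) * (p_bar * (1 - p_bar) - (r - 1) / r * s2v - h_bar / 4))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2v - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  if (!is.finite(a) || !is.finite(a + b + cc)) return(c(num = NA, den = NA))
  c(num = a, den = a + b + cc)
}

## r^2 from the 2x2 haplotype count table
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  pAB <- sum(x == 1 & y == 1) / n
  pA <- mean(x); pB <- mean(y)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

## EHH by exhaustive haplotype-string grouping from just beyond the core
## through site j (inclusive)
oracle_ehh <- function(hap, core, j) {
  n <- ncol(hap)
  rng <- if (j > core) (core + 1):j else j:(core - 1)
  keys <- apply(hap[rng, , drop = FALSE], 2, paste, collapse = "")
  tab <- table(keys)
  sum(choose(tab, 2)) / choose(n, 2)
}

## iHH oracle: walk site by site with oracle_ehh, truncate at the first site
## where the stop panel drops below the cutoff, manual trapezoid over cM
oracle_ihh <- function(hap, core, cm, cutoff = 0.05, stop_hap = hap) {
  m <- nrow(hap)
  one_dir <- function(sites) {
    d_prev <- 0; e_prev <- 1; acc <- 0
    for (j in sites) {
      e_stop <- oracle_ehh(stop_hap, core, j)
      e <- oracle_ehh(hap, core, j)
      d <- abs(cm[j] - cm[core])
      acc <- acc + (e_prev + e) / 2 * (d - d_prev)
      d_prev <- d; e_prev <- e
      if (e_stop < cutoff) break
    }
    acc
  }
  right <- if (core < m) one_dir((core + 1):m) else 0
  left <- if (core > 1) one_dir((core - 1):1) else 0
  c(total = left + right, left = left, right = right)
}

## hypergeometric upper tail by direct enumeration of the probability mass
oracle_hyper_tail <- function(k, n, K, N) {
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

## straight-line re-implementation of the SNP filters, one rule at a time
oracle_filters <- function(df, min_depth = 3, min_mq = 20, max_miss = 0.2,
                           min_maf = 0.01, min_space = 5) {
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (is.finite(df$mean_dp[i]) && df$mean_dp[i] < min_depth) keep[i] <- FALSE
  }
  for (i in seq_len(nrow(df))) {
    if (keep[i] && is.finite(df$mq[i]) && df$mq[i] < min_mq) keep[i] <- FALSE
  }
  for (i in seq_len(nrow(df))) {
    if (keep[i] && df$miss[i] > max_miss) keep[i] <- FALSE
  }
  for (i in seq_len(nrow(df))) {
    if (keep[i] && (is.na(df$maf[i]) || df$maf[i] < min_maf)) keep[i] <- FALSE
  }
  surv <- which(keep)
  drop <- rep(FALSE, length(surv))
  for (a in seq_along(surv)) {
    for (b in seq_along(surv)) {
      if (a != b && abs(df$pos[surv[a]] - df$pos[surv[b]]) < min_space) drop[a] <- TRUE
    }
  }
  surv[!drop]
}

## random small phased panel (no missing data)
random_panel <- function(m, n, seed) {
  set.seed(seed)
  A <- matrix(sample(0:1, m * n, replace = TRUE), m, n)
  ## ensure every site is polymorphic so cores are usable
  for (i in seq_len(m)) {
    if (all(A[i, ] == A[i, 1])) A[i, sample(n, 1)] <- 1L - A[i, 1]
  }
  A
}
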