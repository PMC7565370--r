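test_that("windowed diversity matches the average pairwise-difference definition", {
  ## one site at frequency 2/4 in a 1000-bp window: 4 of 6 pairs differ
  tab <- make_table(500L, a1 = matrix(c(0L, 1L), 1), a2 = matrix(c(0L, 1L), 1),
                    pops = c("pA", "pA"), contig_len = 1000)
  res <- windowed_pi(tab, "pA", window_scheme(1000L, 1000L))
  expect_equal(res$pi, (4 / 6) / 1000, tolerance = 1e-12)
  expect_equal(res$n_snps, 1L)
  ## a population monomorphic at every site has zero diversity
  tabm <- make_table(c(10L, 20L), matrix(0L, 2, 2), matrix(0L, 2, 2),
                     pops = c("pA", "pA"), contig_len = 1000)
  expect_equal(windowed_pi(tabm, "pA", window_scheme(1000L, 1000L))$pi, 0)
  expect_error(windowed_pi(tab, "nope"), "population")
})

test_that("windowed diversity equals the O(n^2) pairwise-Hamming oracle", {
  set.seed(8)
  for (rep in 1:6) {
    n <- 5L                     # diploids
    m <- 20L
    pos <- sort(sample.int(2000L, m))
    hap <- matrix(sample(0:1, m * 2 * n, TRUE), m, 2 * n)
    a1 <- hap[, seq(1, 2 * n, 2)]; a2 <- hap[, seq(2, 2 * n, 2)]
    tab <- make_table(pos, a1, a2, pops = rep("pA", n), contig_len = 2000)
    res <- windowed_pi(tab, "pA", window_scheme(1000L, 500L))
    for (w in seq_len(nrow(res))) {
      expect_equal(res$pi[w], oracle_windowed_pi(pos, hap, res$start[w], res$end[w]),
                   tolerance = 1e-12)
    }
  }
})

test_that("diversity is invariant to sample relabeling and allele recoding", {
  set.seed(9)
  m <- 30L; n <- 6L
  a1 <- matrix(sample(0:1, m * n, TRUE), m, n)
  a2 <- matrix(sample(0:1, m * n, TRUE), m, n)
  pos <- sort(sample.int(5e4, m))
  tab <- make_table(pos, a1, a2, pops = rep("pA", n), contig_len = 5e4)
  base <- windowed_pi(tab, "pA")
  perm <- sample(n)
  tab_perm <- make_table(pos, a1[, perm], a2[, perm], pops = rep("pA", n),
                         contig_len = 5e4)
  expect_equal(windowed_pi(tab_perm, "pA")$pi, base$pi, tolerance = 1e-12)
  tab_swap <- make_table(pos, 1L - a1, 1L - a2, pops = rep("pA", n),
                         contig_len = 5e4)
  expect_equal(windowed_pi(tab_swap, "pA")$pi, base$pi, tolerance = 1e-12)
})

test_that("r2 reproduces the textbook haplotype-frequency cases", {
  expect_equal(pairwise_r2(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)       # coupling
  expect_equal(pairwise_r2(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)       # independence
  ## counts AB=3, Ab=1, aB=1, ab=3: D = 3/8 - 1/4 = 1/8, r2 = (1/64)/(1/16)
  x <- c(rep(1, 4), rep(0, 4)); y <- c(1, 1, 1, 0, 1, 0, 0, 0)
  expect_equal(pairwise_r2(x, y), 0.25, tolerance = 1e-12)
  expect_equal(pairwise_r2(x, y), pairwise_r2(y, x))
  ## monomorphic after pairwise missing exclusion: undefined
  expect_true(is.na(pairwise_r2(c(1, NA, 0), c(1, 1, NA))))
  set.seed(10)
  for (rep in 1:20) {
    x <- sample(0:1, 14, TRUE); y <- sample(0:1, 14, TRUE)
    r <- pairwise_r2(x, y)
    o <- oracle_r2(x, y)
    if (is.na(o)) expect_true(is.na(r)) else {
      expect_equal(r, o, tolerance = 1e-12)
      expect_gte(r, 0); expect_lte(r, 1)
    }
  }
})

test_that("LD decay curves accumulate exactly the eligible pairs", {
  set.seed(12)
  m <- 30L; nh <- 20L
  A <- random_panel(m, nh, 13)
  pos <- sort(sample.int(3e4, m))
  cohort <- structure(list(chrom = "c", sequence_length = 3e4, positions = pos,
                           cm = pos * 2.53e-6, alleles = A,
                           sample_ids = sprintf("s%d", 1:(nh / 2)),
                           populations = stats::setNames(rep("pA", nh / 2),
                                                         sprintf("s%d", 1:(nh / 2))),
                           hap_sample = rep(1:(nh / 2), each = 2), config = NULL),
                      class = "phased_cohort")
  cfg <- ld_config(max_dist = 3e4, min_maf = 0.05, bin_width = 1000L)
  curve <- ld_decay(cohort, cfg)
  ## brute force over all eligible pairs
  maf <- pmin(rowMeans(A), 1 - rowMeans(A))
  keep <- which(maf >= 0.05)
  sums <- numeric(30); cnt <- integer(30)
  for (a in keep) for (b in keep) {
    if (a < b && pos[b] - pos[a] <= 3e4) {
      r2 <- oracle_r2(A[a, ], A[b, ])
      if (!is.na(r2)) {
        bin <- (pos[b] - pos[a] - 1) %/% 1000 + 1
        sums[bin] <- sums[bin] + r2; cnt[bin] <- cnt[bin] + 1L
      }
    }
  }
  expect_equal(curve$n_pairs, cnt)
  nz <- cnt > 0
  expect_equal(curve$mean_r2[nz], sums[nz] / cnt[nz], tolerance = 1e-12)
  expect_equal(sum(curve$n_pairs), sum(cnt))   # conservation
  ## a site below the MAF screen joins no pair
  A2 <- A; A2[1, ] <- c(1L, rep(0L, nh - 1))   # MAF 0.05 > 1/20... exactly 0.05 kept
  A2[2, ] <- 0L; A2[2, 1] <- 1L
  cohort$alleles <- A2
  curve2 <- ld_decay(cohort, ld_config(max_dist = 3e4, min_maf = 0.2, bin_width = 1000L))
  expect_true(sum(curve2$n_pairs) <= sum(curve$n_pairs))
})

test_that("half-decay distance scans binned means from the left", {
  curve <- data.frame(bin_mid = c(1000, 5000, 13000, 50000),
                      mean_r2 = c(0.6, 0.5, 0.29, 0.2), n_pairs = 5L)
  class(curve) <- c("ld_curve", class(curve))
  h <- half_decay_distance(curve)
  expect_equal(h$distance_bp, 13000)
  expect_true(h$reached)
  ## flat curve never reaches half its maximum
  flat <- curve; flat$mean_r2 <- 0.4
  hf <- half_decay_distance(flat)
  expect_false(hf$reached); expect_true(is.na(hf$distance_bp))
  ## first bin already at or below half the maximum
  early <- curve; early$mean_r2 <- c(0.2, 0.6, 0.5, 0.4)
  expect_equal(half_decay_distance(early)$distance_bp, 1000)
  expect_error(half_decay_distance(data.frame(bin_mid = 1, mean_r2 = NA,
                                              n_pairs = 0L)), "empty")
})
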