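two_pop_table <- function(a1_1, a2_1, a1_2, a2_2, pos = NULL) {
  n1 <- ncol(a1_1); n2 <- ncol(a1_2)
  m <- nrow(a1_1)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  make_table(pos, cbind(a1_1, a1_2), cbind(a2_1, a2_2),
             pops = rep(c("p1", "p2"), c(n1, n2)), contig_len = max(pos) + 100)
}

test_that("fixed differences give per-site Fst of one", {
  m1 <- matrix(1L, 1, 10); m0 <- matrix(0L, 1, 10)
  tab <- two_pop_table(m1, m1, m0, m0)
  comp <- per_site_fst_components(tab)
  expect_equal(comp$num / comp$den, 1)
  ## identical allele counts: no between-population variance, numerator <= 0
  same <- matrix(rep(c(0L, 1L), 5), 1)
  tab2 <- two_pop_table(same, same, same, same)
  comp2 <- per_site_fst_components(tab2)
  expect_lte(comp2$num, 0)
  expect_error(per_site_fst_components(make_table(100L, matrix(0L, 1, 2),
                                                  matrix(1L, 1, 2),
                                                  pops = c("p1", "p1"))),
               "two populations")
})

test_that("components match a literal Weir-Cockerham transcription on random sites", {
  set.seed(21)
  for (rep in 1:4) {
    m <- 100L; n1 <- 8L; n2 <- 5L
    gen <- function(n) {
      a <- matrix(sample(c(0L, 1L, NA), m * n, TRUE, prob = c(.45, .45, .1)), m, n)
      b <- matrix(sample(c(0L, 1L, NA), m * n, TRUE, prob = c(.45, .45, .1)), m, n)
      miss <- is.na(a) | is.na(b); a[miss] <- NA; b[miss] <- NA
      list(a = a, b = b)
    }
    g1 <- gen(n1); g2 <- gen(n2)
    tab <- two_pop_table(g1$a, g1$b, g2$a, g2$b)
    comp <- per_site_fst_components(tab)
    for (i in seq_len(m)) {
      o <- oracle_wc_components(g1$a[i, ], g1$b[i, ], g2$a[i, ], g2$b[i, ])
      if (is.na(o["num"])) {
        expect_true(is.na(comp$num[i]))
      } else {
        expect_equal(comp$num[i], unname(o["num"]), tolerance = 1e-12)
        expect_equal(comp$den[i], unname(o["den"]), tolerance = 1e-12)
      }
    }
  }
})

test_that("window Fst is the ratio of summed components", {
  comp <- data.frame(chrom = "c", pos = c(100L, 900L, 1500L, 2500L),
                     num = c(0.2, -0.05, 0.4, 0.1), den = c(0.5, 0.3, 0.8, 0.4))
  w <- windowed_fst(comp, window_scheme(1000L, 1000L), c(c = 3000))
  expect_equal(w$fst[1], (0.2 - 0.05) / (0.5 + 0.3), tolerance = 1e-12)
  expect_equal(w$fst[2], 0.4 / 0.8)
  expect_equal(w$fst[3], 0.25)
  ## single-site window equals that site's ratio; negative values retained
  compn <- data.frame(chrom = "c", pos = 500L, num = -0.1, den = 0.5)
  wn <- windowed_fst(compn, window_scheme(1000L, 1000L), c(c = 1000))
  expect_equal(wn$fst, -0.2)
  ## brute-force re-summation on random component sets
  set.seed(31)
  pos <- sort(sample.int(10000L, 200L))
  comp <- data.frame(chrom = "c", pos = pos, num = rnorm(200), den = runif(200, .1, 1))
  w <- windowed_fst(comp, window_scheme(2000L, 1000L), c(c = 10000))
  for (k in seq_len(nrow(w))) {
    inw <- pos >= w$start[k] & pos <= w$end[k]
    if (any(inw)) {
      expect_equal(w$fst[k], sum(comp$num[inw]) / sum(comp$den[inw]),
                   tolerance = 1e-12)
    } else expect_true(is.na(w$fst[k]))
  }
})

test_that("z-transformation standardizes by the population moments", {
  expect_equal(z_transform(c(0, 1)), c(-1, 1))
  expect_error(z_transform(rep(2, 5)), "spread")
  expect_error(z_transform(1), "2 finite")
  set.seed(41)
  x <- rnorm(50, 3, 2)
  z <- z_transform(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_equal(z, (x - mean(x)) / sqrt(mean((x - mean(x))^2)), tolerance = 1e-12)
  ## affine invariance
  expect_equal(z_transform(5 * x - 2), z, tolerance = 1e-10)
})

test_that("log2 diversity ratio flags unusable windows", {
  expect_equal(log2_pi_ratio(0.002, 0.001), 1)
  expect_equal(log2_pi_ratio(0.5, 0.5), 0)
  expect_true(is.na(log2_pi_ratio(0.002, 0)))
  expect_true(is.na(log2_pi_ratio(0, 0.001)))
  expect_error(log2_pi_ratio(1:3, 1:2), "misaligned")
})

test_that("joint outliers implement the tie-inclusive top-5% rule", {
  ## identical rank order: exactly the common top 5 of 100 are joint
  set.seed(51)
  fst <- sort(runif(100))
  win <- data.frame(fst = fst, log2_ratio = fst * 2 + 1)
  out <- joint_outliers(win)
  expect_equal(sum(out$fst_top), 5L)
  expect_equal(sum(out$ratio_top), 5L)
  expect_equal(which(out$joint), 96:100)
  ## reversed ranks: disjoint top tails, no joint outliers
  win2 <- data.frame(fst = fst, log2_ratio = rev(fst))
  out2 <- joint_outliers(win2)
  expect_equal(sum(out2$joint), 0L)
  ## all tied on both statistics: z-transform degenerates, which is an error;
  ## tie inclusion is exercised on the ratio side instead
  win3 <- data.frame(fst = fst, log2_ratio = rep(1, 100))
  out3 <- joint_outliers(win3)
  expect_true(all(out3$ratio_top))
  expect_equal(sum(out3$joint), 5L)
})

test_that("top_fraction_threshold includes ties at the cut", {
  ## ten windows tied exactly at the 5% cut all enter together
  x <- c(100, 99, 98, rep(97, 10), 1:87)
  thr <- top_fraction_threshold(x, 0.95)
  expect_equal(thr, 97)
  expect_equal(sum(x >= thr), 13L)
  expect_equal(top_fraction_threshold(1:100, 0.95), 96)
})

test_that("outlier windows merge into regions and collect overlapping genes", {
  win <- data.frame(chrom = "c", start = c(100000L, 120000L, 300000L),
                    end = c(140000L, 160000L, 340000L))
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "c",
                      start = c(160000L, 200000L, 339999L),
                      end = c(170000L, 210000L, 350000L))
  reg <- merge_and_map(win, genes)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$start[1], 100000L); expect_equal(reg$end[1], 160000L)
  ## gA overlaps region 1 by exactly 1 bp; gC overlaps region 2 by 2 bp
  expect_equal(attr(reg, "genes"), c("gA", "gC"))
  ## random windows and genes against an all-pairs overlap oracle
  set.seed(61)
  for (rep in 1:5) {
    ws <- sort(sample.int(1e5, 12)) ; win <- data.frame(chrom = "c", start = ws,
                                                        end = ws + 5000L)
    gs <- sort(sample.int(1e5, 15))
    genes <- data.frame(gene_id = sprintf("g%02d", 1:15), chrom = "c",
                        start = gs, end = gs + 800L)
    reg <- merge_and_map(win, genes)
    manual <- character(0)
    for (i in 1:15) {
      if (any(genes$start[i] <= win$end & genes$end[i] >= win$start)) {
        manual <- c(manual, genes$gene_id[i])
      }
    }
    expect_setequal(attr(reg, "genes"), manual)
    ## windows are covered by exactly their merged regions
    for (k in seq_len(nrow(win))) {
      expect_true(any(reg$start <= win$start[k] & reg$end >= win$end[k]))
    }
  }
})

test_that("gene-set intersection partitions both sets", {
  v <- intersect_gene_sets(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(v$shared, c("B", "C"))
  expect_equal(v$a_only, "A"); expect_equal(v$b_only, "D")
  v2 <- intersect_gene_sets(c("A", "B"), c("C", "D"))
  expect_equal(length(v2$shared), 0L)
  set.seed(71)
  a <- sample(sprintf("g%04d", 1:2000), 300)
  b <- sample(sprintf("g%04d", 1:2000), 900)
  v3 <- intersect_gene_sets(a, b)
  expect_equal(sum(v3$counts), length(union(a, b)))
  expect_equal(length(v3$shared), length(intersect(a, b)))
})
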