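test_that("read-pair filter applies the ambiguity, quality and adapter rules", {
  mk <- function(seq, qual) list(seq = seq, qual = qual)
  good <- mk(strrep("ACGT", 25), strrep("I", 100))          # Q40 clean read
  ## 16 N in a 100-nt mate: ambiguous-base rule fires
  n16 <- mk(paste0(strrep("N", 16), strrep("A", 84)), strrep("I", 100))
  r <- filter_read_pair(n16, good)
  expect_false(r$keep); expect_equal(r$reason, "ambiguous_bases")
  ## 60 of 100 bases below Q5 ("&" is Phred 5, "!" is 0)
  lowq <- mk(strrep("A", 100), paste0(strrep("!", 60), strrep("I", 40)))
  r <- filter_read_pair(good, lowq)                         # symmetric in mates
  expect_false(r$keep); expect_equal(r$reason, "low_quality")
  ## exactly 10% N is kept (strict inequality)
  n10 <- mk(paste0(strrep("N", 10), strrep("A", 90)), strrep("I", 100))
  expect_true(filter_read_pair(n10, good)$keep)
  ## clean pair with no adapter hit
  expect_true(filter_read_pair(good, good, adapter = "GGGGGGGGGGGG")$keep)
  ## an 11-nt exact adapter match drops the pair; a 9-nt fragment leaves every
  ## >10-nt alignment with more than 10% mismatches and is kept
  adapter <- "CTGTCTCTTAT"
  withad <- mk(paste0(strrep("A", 50), adapter, strrep("C", 39)), strrep("I", 100))
  expect_false(filter_read_pair(withad, good, adapter = adapter)$keep)
  short <- mk(paste0(strrep("A", 50), substr(adapter, 1, 9), strrep("C", 41)),
              strrep("I", 100))
  expect_true(filter_read_pair(short, good, adapter = adapter)$keep)
  ## sequence/quality length mismatch is an input error
  expect_error(filter_read_pair(mk("ACGT", "III"), good), "length")
})

test_that("VCF reading loads biallelic SNPs and skips the rest", {
  dir <- tempdir()
  samples <- c("sampA", "sampB")
  vcf <- write_test_vcf(
    file.path(dir, "t.vcf"), "chr9",
    pos = c(101L, 205L, 330L, 400L),
    ref = c("A", "C", "G", "T"),
    alt = c("G", "T", "A,T", "C"),          # third record is multiallelic
    gt = rbind(c("0|1", "1|1"), c("0|0", "0|1"), c("0|1", "0|0"), c("./.", "1|1")),
    dp = rbind(c(7, 9), c(3, 4), c(8, 8), c(10, 2)),
    mq = c(55, 31.5, 40, NA),
    samples = samples)
  pm <- write_test_popmap(file.path(dir, "t.pop"), samples, c("p1", "p2"))
  tab <- read_vcf(vcf, pm)
  expect_equal(n_sites(tab), 3L)
  expect_equal(attr(tab, "skipped"), 1L)
  expect_equal(tab$pos, c(101L, 205L, 400L))
  expect_equal(tab$ref, c("A", "C", "T"))
  expect_equal(unname(tab$a1[, 1]), c(0L, 0L, NA))
  expect_equal(unname(tab$a2[, 2]), c(1L, 1L, 1L))
  expect_equal(unname(tab$dp[1, ]), c(7, 9))
  expect_equal(tab$mq, c(55, 31.5, NA))
  expect_equal(unname(tab$contig_lengths["chr9"]), 1e6)
  ## header-only VCF gives an empty table
  writeLines(readLines(vcf)[1:6], file.path(dir, "empty.vcf"))
  etab <- read_vcf(file.path(dir, "empty.vcf"), pm)
  expect_equal(n_sites(etab), 0L)
  ## sample missing from the popmap is an input error
  pm2 <- write_test_popmap(file.path(dir, "bad.pop"), "sampA", "p1")
  expect_error(read_vcf(vcf, pm2), "popmap")
})

test_that("proximal-SNP removal drops both members and whole chains", {
  expect_equal(remove_proximal(c(100L, 104L), 5), integer(0))
  expect_equal(remove_proximal(c(100L, 105L), 5), c(1L, 2L))  # 5 bp is kept
  expect_equal(remove_proximal(c(100L, 104L, 108L, 200L), 5), 4L)
  expect_error(remove_proximal(c(5L, 3L), 5), "sorted")
  ## property: surviving sites are pairwise >= min_spacing apart
  set.seed(42)
  for (rep in 1:25) {
    pos <- sort(sample.int(300L, 40L))
    keep <- remove_proximal(pos, 7)
    if (length(keep) > 1) expect_true(all(diff(pos[keep]) >= 7))
    ## oracle: a site survives iff no other site is within the spacing
    manual <- which(vapply(seq_along(pos), function(i) {
      all(abs(pos[-i] - pos[i]) >= 7)
    }, logical(1)))
    expect_equal(keep, manual)
  }
})

test_that("SNP filters reproduce the per-rule thresholds", {
  ## site 2: RMS MQ 19 -> removed; site 3: 3 of 13 genotypes missing -> removed
  n <- 13L
  a1 <- matrix(0L, 4, n); a2 <- matrix(1L, 4, n)      # all het, MAF 0.5
  a1[3, 1:3] <- NA; a2[3, 1:3] <- NA
  tab <- make_table(pos = c(100L, 2000L, 4000L, 6000L), a1, a2,
                    pops = rep(c("p1", "p2"), c(7, 6)),
                    mq = c(40, 19, 40, 40))
  out <- apply_snp_filters(tab, filter_thresholds())
  expect_equal(out$table$pos, c(100L, 6000L))
  rep <- out$report
  expect_equal(rep$removed[rep$rule == "rms_mq"], 1L)
  expect_equal(rep$removed[rep$rule == "miss_ratio"], 1L)
  ## filtering is idempotent
  out2 <- apply_snp_filters(out$table, filter_thresholds())
  expect_equal(out2$table$pos, out$table$pos)
  expect_true(all(out2$report$removed == 0L))
})

test_that("filters on a randomized table match a rule-by-rule oracle", {
  set.seed(7)
  for (rep in 1:5) {
    m <- 50L; n <- 10L
    pos <- sort(sample.int(2000L, m))
    a1 <- matrix(sample(c(0L, 1L, NA), m * n, TRUE, prob = c(.45, .45, .1)), m, n)
    a2 <- matrix(sample(c(0L, 1L, NA), m * n, TRUE, prob = c(.45, .45, .1)), m, n)
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA; a2[miss] <- NA
    dp <- matrix(rpois(m * n, 4), m, n)
    mq <- round(runif(m, 10, 60), 1)
    tab <- make_table(pos, a1, a2, pops = rep(c("p1", "p2"), each = 5),
                      dp = dp, mq = mq)
    out <- apply_snp_filters(tab, filter_thresholds())
    p <- ifelse(rowSums(!miss) > 0,
                (rowSums(a1, na.rm = TRUE) + rowSums(a2, na.rm = TRUE)) /
                  (2 * rowSums(!miss)), NA)
    oracle_keep <- oracle_filters(data.frame(
      pos = pos, mean_dp = rowMeans(dp), mq = mq,
      miss = rowMeans(miss), maf = pmin(p, 1 - p)))
    expect_equal(out$table$pos, pos[oracle_keep])
  }
})

test_that("ts/tv classification matches a per-site oracle", {
  tab <- make_table(pos = c(10L, 20L, 30L),
                    a1 = matrix(0L, 3, 2), a2 = matrix(1L, 3, 2),
                    pops = c("p1", "p1"),
                    ref = c("A", "C", "A"), alt = c("G", "T", "C"))
  r <- tstv(tab)
  expect_equal(r$ratio, 2)
  ## all transitions: undefined, not an error
  tab2 <- make_table(pos = c(10L, 20L), a1 = matrix(0L, 2, 2),
                     a2 = matrix(1L, 2, 2), pops = c("p1", "p1"),
                     ref = c("A", "T"), alt = c("G", "C"))
  r2 <- tstv(tab2)
  expect_true(r2$undefined); expect_true(is.na(r2$ratio))
  expect_error(tstv(make_table(integer(0), matrix(0L, 0, 1), matrix(0L, 0, 1),
                               "p1", contig_len = 1)), "site")
  ## 200 random substitutions against direct classification
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 200, TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  tab3 <- make_table(sort(sample.int(1e6, 200)), matrix(0L, 200, 2),
                     matrix(1L, 200, 2), c("p1", "p1"), ref = ref, alt = alt)
  is_ts <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
           (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  expect_equal(tstv(tab3)$ratio, sum(is_ts) / sum(!is_ts))
})

test_that("heterozygote counts exclude missing genotypes", {
  a1 <- rbind(c(0L, NA), c(0L, NA), c(1L, NA))
  a2 <- rbind(c(1L, NA), c(1L, NA), c(1L, NA))
  tab <- make_table(c(1L, 5L, 9L) * 10L, a1, a2, pops = c("p1", "p1"))
  expect_equal(unname(het_counts(tab)), c(2L, 0L))
  ## random table versus an element-wise scan
  set.seed(3)
  m <- 100L; n <- 6L
  a1 <- matrix(sample(c(0L, 1L, NA), m * n, TRUE), m, n)
  a2 <- matrix(sample(c(0L, 1L, NA), m * n, TRUE), m, n)
  keep <- !(is.na(a1) | is.na(a2))
  a1[!keep] <- NA; a2[!keep] <- NA
  tab <- make_table(sort(sample.int(1e5, m)), a1, a2, pops = rep("p1", n))
  manual <- integer(n)
  for (j in seq_len(n)) for (i in seq_len(m)) {
    if (!is.na(a1[i, j]) && !is.na(a2[i, j]) && a1[i, j] != a2[i, j]) {
      manual[j] <- manual[j] + 1L
    }
  }
  expect_equal(unname(het_counts(tab)), manual)
})
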