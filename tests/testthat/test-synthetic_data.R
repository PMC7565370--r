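test_that("no mutation means no variation", {
  cfg <- sim_config(seed = 1, mutation_rate = 0, sequence_length = 1e4,
                    ancestral_size = 10L, burn_in = 30L, split_generation = 5L,
                    epochs_focal = data.frame(start = 5L, size = 10L),
                    epochs_control = data.frame(start = 5L, size = 10L),
                    sample_sizes = c(5L, 3L))
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$cohort$alleles), 0L)
  expect_equal(sim$truth$n_segregating, 0L)
})

test_that("identical config and seed give identical cohorts and files", {
  cfg <- small_sim(11, L = 5e4)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort$alleles, s2$cohort$alleles)
  expect_identical(s1$cohort$positions, s2$cohort$positions)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_cohort(s1$cohort, s1$truth, d1)
  write_cohort(s2$cohort, s2$truth, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("cohort structure is internally consistent", {
  sim <- simulate_cohort(small_sim(5, L = 1e5))
  ch <- sim$cohort
  expect_true(all(diff(ch$positions) > 0))
  expect_true(all(ch$alleles %in% 0:1))
  expect_equal(ncol(ch$alleles), 2L * length(ch$sample_ids))
  expect_true(all(diff(ch$cm) > 0))
  rs <- rowSums(ch$alleles)
  expect_true(all(rs > 0 & rs < ncol(ch$alleles)))  # segregating in the sample
})

test_that("invalid epoch ordering is a configuration error", {
  expect_error(sim_config(epochs_focal = data.frame(start = c(44L, 50L),
                                                    size = c(50L, 60L))),
               "decreasing")
  expect_error(sim_config(split_generation = 44L,
                          epochs_focal = data.frame(start = 10L, size = 50L)),
               "split")
  expect_error(sim_config(sweep = list(position = 6e5, s = 0.1, onset = 10)),
               "position")
})

test_that("a planted hard sweep raises the derived frequency in the target population", {
  cfg <- small_sim(21, L = 1e5,
                   sweep = list(position = 5e4, s = 1.0, onset = 20,
                                population = "focal", min_final_freq = 0.9))
  sim <- simulate_cohort(cfg)
  tw <- sim$truth$sweep
  expect_false(tw$lost)
  expect_gte(tw$freq_focal_sample, 0.5)
  idx <- match(as.integer(5e4), sim$cohort$positions)
  if (!is.na(idx)) {
    pops <- rep(unname(sim$cohort$populations), each = 2)
    f_focal <- mean(sim$cohort$alleles[idx, pops == "focal"])
    f_ctrl <- mean(sim$cohort$alleles[idx, pops == "control"])
    expect_gt(f_focal, f_ctrl)
  }
  expect_true(tw$interval[1] >= 0 && tw$interval[2] <= cfg$sequence_length)
})

test_that("written cohort round-trips through the VCF reader", {
  sim <- simulate_cohort(small_sim(3, L = 5e4))
  dir <- file.path(tempdir(), "roundtrip")
  files <- write_cohort(sim$cohort, sim$truth, dir)
  tab <- read_vcf(files$vcf, files$popmap)
  expect_identical(tab$pos, sim$cohort$positions)
  n <- length(sim$cohort$sample_ids)
  a1 <- sim$cohort$alleles[, seq(1, 2 * n, 2)]
  a2 <- sim$cohort$alleles[, seq(2, 2 * n, 2)]
  expect_identical(unname(tab$a1), unname(a1))
  expect_identical(unname(tab$a2), unname(a2))
  expect_true(tab$phased)
  ## popmap has one line per diploid; VCF holds every segregating site
  expect_equal(length(readLines(files$popmap)), n)
  expect_equal(n_sites(tab), sim$truth$n_segregating)
  ## genetic map is readable and non-decreasing
  gm <- read_genetic_map(files$genetic_map)
  expect_true(all(diff(gm$cM) >= 0))
})

test_that("toy annotation respects frame, placement and term coverage", {
  ann <- make_annotation_and_terms(2e5, n_genes = 25L, n_terms = 15L, seed = 2)
  g <- ann$genes$genes
  cds <- ann$genes$cds
  cds_len <- tapply(cds$end - cds$start + 1L, cds$gene_id, sum)
  expect_true(all(cds_len %% 3L == 0L))
  o <- g[order(g$start), ]
  expect_true(all(o$start[-1] > o$end[-nrow(o)]))      # non-overlapping
  expect_true(all(g$gene_id %in% ann$term_map$gene))   # every gene has a term
  expect_true(all(cds$start >= g$start[match(cds$gene_id, g$gene_id)]))
  empty <- make_annotation_and_terms(1e4, n_genes = 0L, n_terms = 0L, seed = 1)
  expect_equal(nrow(empty$genes$genes), 0L)
  expect_equal(nrow(empty$term_map), 0L)
})

test_that("annotation files round-trip through rtracklayer", {
  dir <- file.path(tempdir(), "annio")
  ann <- make_annotation_and_terms(1e5, n_genes = 10L, n_terms = 5L, seed = 4,
                                   output_dir = dir)
  back <- read_gff_genes(ann$files$gff3, ann$files$fasta)
  expect_setequal(back$genes$gene_id, ann$genes$genes$gene_id)
  ord <- match(ann$genes$genes$gene_id, back$genes$gene_id)
  expect_equal(back$genes$start[ord], ann$genes$genes$start)
  expect_equal(back$genes$end[ord], ann$genes$genes$end)
  expect_equal(back$genes$strand[ord], ann$genes$genes$strand)
  expect_equal(toupper(back$sequence), ann$genes$sequence)
  expect_equal(nrow(back$cds), nrow(ann$genes$cds))
})

test_that("planted term genes drive downstream enrichment below 0.05", {
  ann <- make_annotation_and_terms(2e5, n_genes = 25L, n_terms = 10L, seed = 9,
                                   planted_term = list(term = "TERM_SWEEP",
                                                       genes = 1:5))
  planted_genes <- ann$genes$genes$gene_id[1:5]
  res <- enrich(planted_genes, ann$genes$genes$gene_id, ann$term_map)
  row <- res[res$term == "TERM_SWEEP", ]
  expect_equal(row$k, 5L)
  expect_lt(row$p_raw, 0.05)
  expect_equal(res$term[1], "TERM_SWEEP")  # smallest p
})
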