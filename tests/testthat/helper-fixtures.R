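# Fixtures built in code: small simulation presets and a handwritten VCF.

## downscaled two-population demography used across tests: same coalescent-unit
## split depth and size ratios as the package preset, at half the population
## size (and so half the generations); mu and r doubled to preserve N*mu, N*r
small_sim <- function(seed, L = 2e5, sweep = NULL, sample_sizes = c(13L, 4L)) {
  sim_config(seed = seed, sequence_length = L,
             mutation_rate = 2.34e-6, recombination_rate = 3.94e-6,
             ancestral_size = 60L, burn_in = 480L, split_generation = 22L,
             epochs_focal = data.frame(start = c(22L, 11L), size = c(50L, 22L)),
             epochs_control = data.frame(start = 22L, size = 85L),
             sample_sizes = sample_sizes, sweep = sweep)
}

## single-population neutral configuration at a chosen theta = 4*N*mu*L
neutral_sim <- function(seed, theta = 2, N = 20L, L = 5e4, n_sample = 10L) {
  sim_config(seed = seed, sequence_length = L, mutation_rate = theta / (4 * N * L),
             recombination_rate = 1e-6, ancestral_size = N, burn_in = 10L * N,
             split_generation = 0L, sample_sizes = c(n_sample, 0L))
}

## write a small VCF by hand; gt is a sites x samples character matrix of
## genotype strings, dp same shape integer, mq per site (NA drops the field)
write_test_vcf <- function(path, chrom, pos, ref, alt, gt, dp, mq,
                           samples, contig_len = 1e6) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", chrom, contig_len),
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS MQ\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", samples), collapse = "\t"))
  rows <- vapply(seq_along(pos), function(i) {
    info <- if (is.na(mq[i])) "." else sprintf("MQ=%.2f", mq[i])
    cells <- paste0(gt[i, ], ":", dp[i, ])
    paste(c(chrom, pos[i], ".", ref[i], alt[i], "50", "PASS", info, "GT:DP", cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

write_test_popmap <- function(path, samples, pops) {
  writeLines(paste(samples, pops, sep = "\t"), path)
  path
}

## variant table built directly from allele matrices (dosage-style shortcut)
make_table <- function(pos, a1, a2, pops, dp = NULL, mq = NULL, chrom = "chr1",
                       ref = NULL, alt = NULL, contig_len = max(pos)) {
  m <- length(pos); n <- ncol(a1)
  samples <- sprintf("s%02d", seq_len(n))
  if (is.null(dp)) dp <- matrix(10, m, n)
  if (is.null(mq)) mq <- rep(40, m)
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  variant_table(chrom, pos, ref, alt, a1, a2, dp, mq, samples,
                stats::setNames(pops, samples), phased = TRUE,
                contig_lengths = stats::setNames(contig_len, chrom))
}
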