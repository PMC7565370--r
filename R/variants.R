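#' Construct a variant table
#'
#' Internal-format container for biallelic SNP sites: per-site chrom, 1-based
#' position, REF/ALT alleles, RMS mapping quality, and per-sample allele
#' matrices (`a1`, `a2`, NA = missing) plus per-sample depth. Positions must be
#' strictly increasing within each chromosome.
#'
#' @param chrom,pos,ref,alt per-site vectors
#' @param a1,a2 sites x samples integer allele matrices (0 = REF, 1 = ALT, NA)
#' @param dp sites x samples numeric depth matrix (NA allowed)
#' @param mq per-site RMS mapping quality (NA allowed)
#' @param samples sample identifiers (column order of the matrices)
#' @param populations named character vector mapping sample to population
#' @param phased logical, whether `a1`/`a2` are phased haplotype alleles
#' @param contig_lengths optional named vector of chromosome lengths
#' @return object of class `variant_table`
#' @export
variant_table <- function(chrom, pos, ref, alt, a1, a2, dp, mq, samples,
                          populations, phased = FALSE, contig_lengths = NULL) {
  m <- length(pos)
  k <- length(samples)
  stopifnot(length(a1) == m * k, length(a2) == m * k, length(dp) == m * k,
            length(chrom) %in% c(1L, m), length(mq) == m)
  a1 <- matrix(as.integer(a1), m, k); a2 <- matrix(as.integer(a2), m, k)
  dp <- matrix(as.numeric(dp), m, k)
  if (length(chrom) == 1L) chrom <- rep(chrom, m)
  for (cc in unique(chrom)) {
    p <- pos[chrom == cc]
    if (any(diff(p) <= 0)) stop_input("positions must be strictly increasing within %s", cc)
  }
  if (!all(samples %in% names(populations))) {
    stop_input("samples missing from the population map: %s",
               paste(setdiff(samples, names(populations)), collapse = ", "))
  }
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 a1 = a1, a2 = a2, dp = dp, mq = as.numeric(mq),
                 samples = samples, populations = populations[samples],
                 phased = phased, contig_lengths = contig_lengths),
            class = "variant_table")
}

#' @method print variant_table
#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites, %d samples, populations: %s\n",
              length(x$pos), length(x$samples),
              paste(names(table(x$populations)), table(x$populations),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Number of sites in a variant table
#' @param tab a [variant_table()]
#' @return integer site count
#' @export
n_sites <- function(tab) length(tab$pos)

## subset a variant table by site index
subset_sites <- function(tab, idx) {
  tab$chrom <- tab$chrom[idx]; tab$pos <- tab$pos[idx]
  tab$ref <- tab$ref[idx]; tab$alt <- tab$alt[idx]; tab$mq <- tab$mq[idx]
  tab$a1 <- tab$a1[idx, , drop = FALSE]; tab$a2 <- tab$a2[idx, , drop = FALSE]
  tab$dp <- tab$dp[idx, , drop = FALSE]
  tab
}

#' Read biallelic SNPs from a VCF into a variant table
#'
#' Loads genotypes, per-sample DP and site INFO MQ via the vcfR parser.
#' Multiallelic records, indels and non-ACGT alleles are skipped; the skip
#' count is stored in the `skipped` attribute. Sites without DP or MQ are
#' retained with the metric missing.
#'
#' @param vcf path to a VCF file
#' @param popmap path to a two-column TSV (sample, population) covering every
#'   VCF sample
#' @return a [variant_table()]
#' @export
read_vcf <- function(vcf, popmap) {
  pm <- utils::read.table(popmap, sep = "\t", header = FALSE,
                          col.names = c("sample", "population"),
                          colClasses = "character")
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(v@gt)[-1]
  if (length(samples) && !all(samples %in% pm$sample)) {
    stop_input("VCF samples absent from popmap: %s",
               paste(setdiff(samples, pm$sample), collapse = ", "))
  }
  populations <- stats::setNames(pm$population, pm$sample)
  contig <- vcfR::queryMETA(v, element = "contig")
  contig_lengths <- NULL
  if (length(contig)) {
    ids <- vapply(contig, function(x) sub("^contig=<?ID=", "", x[grep("ID=", x)][1]),
                  character(1))
    lens <- vapply(contig, function(x) {
      lf <- x[grep("^length=", x)]
      if (length(lf)) as.numeric(sub("length=", "", lf[1])) else NA_real_
    }, numeric(1))
    contig_lengths <- stats::setNames(lens, ids)
  }
  if (nrow(fix) == 0L) {
    tab <- variant_table(character(0), integer(0), character(0), character(0),
                         matrix(NA_integer_, 0, length(samples)),
                         matrix(NA_integer_, 0, length(samples)),
                         matrix(NA_real_, 0, length(samples)),
                         numeric(0), samples, populations,
                         contig_lengths = contig_lengths)
    attr(tab, "skipped") <- 0L
    return(tab)
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  skipped <- sum(!snp)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "MQ")))
  if (length(mq) == 0L) mq <- rep(NA_real_, nrow(fix))
  gt <- matrix(gt[snp, ], sum(snp), length(samples))
  dp <- matrix(dp[snp, ], sum(snp), length(samples))
  phased <- any(grepl("|", gt, fixed = TRUE), na.rm = TRUE)
  gt[is.na(gt)] <- "./."
  a1 <- suppressWarnings(matrix(as.integer(substr(gt, 1, 1)), nrow(gt), ncol(gt)))
  a2 <- suppressWarnings(matrix(as.integer(substr(gt, 3, 3)), nrow(gt), ncol(gt)))
  half <- is.na(a1) | is.na(a2)   # any half-called genotype counts as missing
  a1[half] <- NA_integer_; a2[half] <- NA_integer_
  tab <- variant_table(fix[snp, "CHROM"], as.integer(fix[snp, "POS"]),
                       ref[snp], alt[snp], a1, a2, dp, mq[snp],
                       samples, populations, phased = phased,
                       contig_lengths = contig_lengths)
  attr(tab, "skipped") <- skipped
  tab
}

#' Convert a simulated cohort to a variant table
#'
#' In-memory shortcut around the VCF round trip: haplotype pairs become phased
#' genotypes, REF/ALT are set to the placeholder bases A/G, depth to the
#' configured Poisson mean and MQ to the configured constant.
#'
#' @param cohort a `phased_cohort`
#' @return a phased [variant_table()]
#' @export
as_variant_table <- function(cohort) {
  n <- length(cohort$sample_ids)
  m <- nrow(cohort$alleles)
  a1 <- cohort$alleles[, seq(1L, 2L * n, 2L), drop = FALSE]
  a2 <- cohort$alleles[, seq(2L, 2L * n, 2L), drop = FALSE]
  cfg <- cohort$config
  variant_table(cohort$chrom, cohort$positions,
                rep("A", m), rep("G", m), a1, a2,
                matrix(if (is.null(cfg)) NA_real_ else cfg$depth_mean, m, n),
                rep(if (is.null(cfg)) NA_real_ else cfg$mq_value, m),
                cohort$sample_ids, cohort$populations, phased = TRUE,
                contig_lengths = stats::setNames(cohort$sequence_length, cohort$chrom))
}

#' SNP quality-filter thresholds
#'
#' Defaults follow standard population-resequencing practice: mean per-sample
#' depth at the site of at least 3, RMS mapping quality of at least 20, at most
#' 20 percent missing genotypes, minor allele frequency of at least 0.01
#' (computed over non-missing alleles), and removal of every member of any run
#' of SNPs spaced less than 5 bp apart.
#'
#' @param min_depth,min_rms_mq,max_miss_ratio,min_maf,min_spacing_bp thresholds
#' @param depth_mode "mean" (mean per-sample DP at the site) or "per_sample_min"
#' @return list of class `filter_thresholds`
#' @export
filter_thresholds <- function(min_depth = 3, min_rms_mq = 20,
                              max_miss_ratio = 0.2, min_maf = 0.01,
                              min_spacing_bp = 5, depth_mode = c("mean", "per_sample_min")) {
  if (min_depth < 0 || min_rms_mq < 0 || min_spacing_bp < 0) {
    stop_input("thresholds must be non-negative")
  }
  if (max_miss_ratio < 0 || max_miss_ratio > 1) stop_input("max_miss_ratio must be in [0,1]")
  if (min_maf < 0 || min_maf > 0.5) stop_input("min_maf must be in [0,0.5]")
  structure(list(min_depth = min_depth, min_rms_mq = min_rms_mq,
                 max_miss_ratio = max_miss_ratio, min_maf = min_maf,
                 min_spacing_bp = min_spacing_bp,
                 depth_mode = match.arg(depth_mode)),
            class = "filter_thresholds")
}

#' Remove SNPs closer than a minimum spacing
#'
#' Any site with a neighbour at an absolute distance below `min_spacing` is
#' removed, so both members of a close pair go, and a chain of closely spaced
#' sites is removed entirely. Distance exactly equal to `min_spacing` is kept.
#'
#' @param positions sorted (non-decreasing) bp positions
#' @param min_spacing minimum allowed distance in bp
#' @return integer indices of the retained sites
#' @export
remove_proximal <- function(positions, min_spacing) {
  if (is.unsorted(positions)) stop_input("positions must be sorted")
  m <- length(positions)
  if (m <= 1L) return(seq_len(m))
  d <- diff(positions)
  close_left <- c(FALSE, d < min_spacing)
  close_right <- c(d < min_spacing, FALSE)
  which(!(close_left | close_right))
}

## per-site missing-genotype ratio, ALT frequency and MAF over non-missing alleles
site_stats <- function(tab) {
  miss <- is.na(tab$a1)                     # a1/a2 NA in lockstep
  n_called <- rowSums(!miss)
  alt_n <- rowSums(tab$a1, na.rm = TRUE) + rowSums(tab$a2, na.rm = TRUE)
  p <- ifelse(n_called > 0, alt_n / (2 * n_called), NA_real_)
  list(miss_ratio = rowMeans(miss), p_alt = p, maf = pmin(p, 1 - p),
       n_alleles = 2L * n_called)
}

#' Apply the SNP quality filters
#'
#' Applies, in order: site depth (mean per-sample DP, or per-sample minimum
#' when configured), RMS mapping quality, missing-genotype ratio, minor allele
#' frequency over non-missing alleles, and proximal-SNP removal
#' ([remove_proximal()], applied per chromosome). Sites with a missing depth or
#' MQ metric are retained by that rule and counted in the report's `flagged`
#' column. The report counts removals per rule in application order.
#'
#' @param table a [variant_table()]
#' @param thresholds a [filter_thresholds()]
#' @return list with `table` (the filtered variant table) and `report`
#'   (data.frame: rule, removed, flagged)
#' @export
apply_snp_filters <- function(table, thresholds = filter_thresholds()) {
  thr <- thresholds
  report <- data.frame(rule = character(0), removed = integer(0), flagged = integer(0))
  add <- function(rule, removed, flagged = 0L) {
    rbind(report, data.frame(rule = rule, removed = removed, flagged = flagged))
  }
  ## depth
  depth_stat <- if (thr$depth_mode == "mean") {
    rowMeans(table$dp, na.rm = TRUE)
  } else {
    apply(table$dp, 1L, function(x) if (all(is.na(x))) NaN else min(x, na.rm = TRUE))
  }
  no_metric <- !is.finite(depth_stat)
  keep <- no_metric | depth_stat >= thr$min_depth
  report <- add("depth", sum(!keep), sum(no_metric))
  table <- subset_sites(table, which(keep))
  ## RMS mapping quality
  no_metric <- !is.finite(table$mq)
  keep <- no_metric | table$mq >= thr$min_rms_mq
  report <- add("rms_mq", sum(!keep), sum(no_metric))
  table <- subset_sites(table, which(keep))
  ## missingness
  st <- site_stats(table)
  keep <- st$miss_ratio <= thr$max_miss_ratio
  report <- add("miss_ratio", sum(!keep))
  table <- subset_sites(table, which(keep))
  ## minor allele frequency
  st <- site_stats(table)
  keep <- !is.na(st$maf) & st$maf >= thr$min_maf
  report <- add("maf", sum(!keep))
  table <- subset_sites(table, which(keep))
  ## proximity, per chromosome
  keep_idx <- unlist(lapply(unique(table$chrom), function(cc) {
    i <- which(table$chrom == cc)
    i[remove_proximal(table$pos[i], thr$min_spacing_bp)]
  }), use.names = FALSE)
  keep_idx <- sort(keep_idx)
  report <- add("spacing", n_sites(table) - length(keep_idx))
  table <- subset_sites(table, keep_idx)
  list(table = table, report = report)
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T substitutions; all other REF/ALT pairs are
#' transversions. The ratio is undefined when no transversions are present.
#'
#' @param table a [variant_table()] with at least one site
#' @return list with `ratio` (NA when undefined), `n_transitions`,
#'   `n_transversions` and `undefined`
#' @export
tstv <- function(table) {
  if (n_sites(table) == 0L) stop_input("tstv needs at least one site")
  pair <- paste0(table$ref, table$alt)
  ts <- pair %in% c("AG", "GA", "CT", "TC")
  n_ts <- sum(ts); n_tv <- sum(!ts)
  list(ratio = if (n_tv == 0L) NA_real_ else n_ts / n_tv,
       n_transitions = n_ts, n_transversions = n_tv, undefined = n_tv == 0L)
}

#' Per-sample heterozygous genotype counts
#'
#' Counts genotypes with two different alleles per sample; missing genotypes
#' are excluded.
#'
#' @param table a [variant_table()]
#' @return named integer vector, one count per sample
#' @export
het_counts <- function(table) {
  het <- table$a1 != table$a2
  stats::setNames(as.integer(colSums(het, na.rm = TRUE)), table$samples)
}

#' Quality filter for a read pair
#'
#' Drops the pair when either mate has more than 10 percent ambiguous (N)
#' bases, more than 50 percent low-quality bases (Phred quality below 5), or an
#' ungapped adapter alignment longer than 10 nt with at most 10 percent
#' mismatches. The decision is symmetric in the two mates.
#'
#' @param read1,read2 lists with `seq` and `qual` (Phred+33) strings of equal length
#' @param adapter adapter sequence
#' @param max_n_frac,max_lowq_frac,q_low,adapter_min_len,adapter_max_mismatch_frac
#'   rule settings; defaults are the standard resequencing values
#' @return list with `keep` (logical) and `reason` (NA when kept)
#' @export
filter_read_pair <- function(read1, read2, adapter = NULL,
                             max_n_frac = 0.10, max_lowq_frac = 0.50, q_low = 5,
                             adapter_min_len = 11L, adapter_max_mismatch_frac = 0.10) {
  check_mate <- function(mate) {
    s <- toupper(mate$seq); q <- mate$qual
    if (nchar(s) != nchar(q)) stop_input("sequence and quality lengths differ")
    len <- nchar(s)
    sv <- strsplit(s, "")[[1]]
    if (mean(sv == "N") > max_n_frac) return("ambiguous_bases")
    phred <- utf8ToInt(q) - 33L
    if (mean(phred < q_low) > max_lowq_frac) return("low_quality")
    if (!is.null(adapter) && adapter_hit(sv, strsplit(toupper(adapter), "")[[1]],
                                         adapter_min_len, adapter_max_mismatch_frac)) {
      return("adapter")
    }
    NA_character_
  }
  for (mate in list(read1, read2)) {
    reason <- check_mate(mate)
    if (!is.na(reason)) return(list(keep = FALSE, reason = reason))
  }
  list(keep = TRUE, reason = NA_character_)
}

## ungapped adapter alignment: any offset with overlap >= min_len and
## mismatch fraction <= max_mm
adapter_hit <- function(read, adapter, min_len, max_mm) {
  lr <- length(read); la <- length(adapter)
  for (shift in seq(-la + 1L, lr - 1L)) {
    r_from <- max(1L, shift + 1L)
    a_from <- max(1L, 1L - shift)
    ov <- min(lr - r_from, la - a_from) + 1L
    if (ov < min_len) next
    r_idx <- r_from:(r_from + ov - 1L)
    a_idx <- a_from:(a_from + ov - 1L)
    mm <- sum(read[r_idx] != adapter[a_idx])
    if (mm <= max_mm * ov) return(TRUE)
  }
  FALSE
}

#' Write the filtered records of a VCF, byte-preserved
#'
#' Copies header lines and exactly those data lines whose (chrom, pos) survive
#' in `table`, leaving record bytes untouched.
#'
#' @param vcf input VCF path
#' @param table the filtered [variant_table()]
#' @param out output path
#' @return invisibly, the number of records written
#' @export
write_filtered_vcf <- function(vcf, table, out) {
  lines <- readLines(vcf)
  hdr <- grepl("^#", lines)
  body <- lines[!hdr]
  key <- sub("^([^\t]+)\t([^\t]+)\t.*$", "\\1:\\2", body)
  keep <- key %in% paste(table$chrom, table$pos, sep = ":")
  writeLines(c(lines[hdr], body[keep]), out)
  invisible(sum(keep))
}
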