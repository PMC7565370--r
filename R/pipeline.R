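#' Configuration for an end-to-end sweep scan
#'
#' Exactly one of `simulation` (a [sim_config()]) or `inputs` (paths to VCF,
#' popmap, and optionally GFF3, FASTA, genetic map and term map) must be given.
#' Defaults mirror the standard scan parameters: 40 kb / 20 kb windows for the
#' Fst and diversity-ratio scan, 10 kb / 5 kb for XP-EHH, top-5% outliers, and
#' enrichment at raw p < 0.05.
#'
#' @param output_dir directory for the report bundle
#' @param simulation a [sim_config()] (simulated-cohort mode)
#' @param inputs list with `vcf`, `popmap` and optional `gff3`, `fasta`,
#'   `genetic_map`, `term_map` paths (file mode)
#' @param thresholds a [filter_thresholds()]
#' @param scan_scheme,xpehh_scheme [window_scheme()]s
#' @param quantile outlier quantile, default 0.95
#' @param alpha,correction enrichment settings (see [enrich()])
#' @param n_genes,n_terms toy-annotation sizes in simulated mode
#' @param focal,control population labels; default: first and second label in
#'   the population map
#' @param seed integer seed governing all randomness of the run
#' @param include_ld also compute per-population LD decay curves (slower)
#' @param ld an [ld_config()]
#' @return list of class `run_config`
#' @export
run_config <- function(output_dir,
                       simulation = NULL, inputs = NULL,
                       thresholds = filter_thresholds(),
                       scan_scheme = window_scheme(40000L, 20000L),
                       xpehh_scheme = window_scheme(10000L, 5000L),
                       quantile = 0.95, alpha = 0.05, correction = "none",
                       n_genes = 30L, n_terms = 20L,
                       focal = NULL, control = NULL, seed = 1L,
                       include_ld = FALSE, ld = ld_config()) {
  if (is.null(simulation) == is.null(inputs)) {
    stop_input("exactly one of 'simulation' or 'inputs' must be given")
  }
  if (!is.null(inputs) && !all(c("vcf", "popmap") %in% names(inputs))) {
    stop_input("inputs need at least 'vcf' and 'popmap'")
  }
  structure(list(output_dir = output_dir, simulation = simulation, inputs = inputs,
                 thresholds = thresholds, scan_scheme = scan_scheme,
                 xpehh_scheme = xpehh_scheme, quantile = quantile,
                 alpha = alpha, correction = correction,
                 n_genes = n_genes, n_terms = n_terms,
                 focal = focal, control = control, seed = as.integer(seed),
                 include_ld = include_ld, ld = ld), class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

## BED is 0-based half-open
write_bed <- function(regions, path) {
  df <- data.frame(chrom = regions$chrom, start = regions$start - 1L, end = regions$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Run the full selective-sweep scan
#'
#' Orchestrates simulate (or load) -> SNP filters -> positional annotation ->
#' Fst / diversity-ratio scan -> XP-EHH scan -> candidate-region merging and
#' gene mapping -> candidate-set intersection -> term enrichment, writing a
#' report bundle (TSV/BED/JSON) into the configured output directory. The
#' bundle is a pure function of the configuration: identical config and seed
#' give byte-identical files.
#'
#' @param config a [run_config()]
#' @return object of class `sweep_scan_run` with the main tables, candidate
#'   gene sets, derived cutoffs and file paths
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logc <- file(log_path, open = "wt")
  on.exit(close(logc), add = TRUE)
  log_msg <- function(...) {
    line <- sprintf(...)
    writeLines(line, logc)
    message(line)
  }

  genes <- NULL; term_map <- NULL; gmap <- NULL; truth <- NULL
  if (!is.null(config$simulation)) {
    log_msg("stage simulate: seed %d", config$seed)
    simc <- config$simulation
    simc$seed <- config$seed
    in_dir <- file.path(out_dir, "inputs")
    ann <- make_annotation_and_terms(simc$sequence_length, config$n_genes,
                                     config$n_terms, seed = config$seed + 7L,
                                     chrom = simc$chrom, output_dir = in_dir)
    genes <- ann$genes
    term_map <- ann$term_map
    sim <- simulate_cohort(simc)
    truth <- sim$truth
    files <- write_cohort(sim$cohort, sim$truth, in_dir, ref_seq = genes$sequence)
    vcf_path <- files$vcf; popmap_path <- files$popmap
    gmap <- read_genetic_map(files$genetic_map)
    log_msg("simulated %d segregating sites", sim$truth$n_segregating)
  } else {
    vcf_path <- config$inputs$vcf; popmap_path <- config$inputs$popmap
    if (!is.null(config$inputs$gff3)) {
      genes <- read_gff_genes(config$inputs$gff3, config$inputs$fasta)
    }
    if (!is.null(config$inputs$term_map)) {
      term_map <- utils::read.table(config$inputs$term_map, sep = "\t",
                                    col.names = c("term", "gene"),
                                    colClasses = "character")
    }
    if (!is.null(config$inputs$genetic_map)) {
      gmap <- read_genetic_map(config$inputs$genetic_map)
    }
  }

  log_msg("stage filter")
  tab <- read_vcf(vcf_path, popmap_path)
  filt <- apply_snp_filters(tab, config$thresholds)
  write_tsv(filt$report, file.path(out_dir, "filter_report.tsv"))
  write_filtered_vcf(vcf_path, filt$table, file.path(out_dir, "filtered.vcf"))
  log_msg("filtered %d -> %d sites", n_sites(tab), n_sites(filt$table))
  ftab <- filt$table

  pops <- unique(unname(ftab$populations[ftab$samples]))
  focal <- if (is.null(config$focal)) pops[1] else config$focal
  control <- if (is.null(config$control)) setdiff(pops, focal)[1] else config$control

  if (!is.null(genes)) {
    log_msg("stage annotate")
    ann_df <- annotate_sites(ftab, genes)
    write_tsv(ann_df, file.path(out_dir, "annotation.tsv"))
  } else ann_df <- NULL

  log_msg("stage fst-pi scan (%d kb / %d kb windows)",
          config$scan_scheme$width %/% 1000L, config$scan_scheme$step %/% 1000L)
  scan <- fst_pi_scan(ftab, focal, control, config$scan_scheme, config$quantile)
  write_tsv(scan, file.path(out_dir, "fst_pi_scan.tsv"))
  joint_regions <- merge_and_map(scan[scan$joint, , drop = FALSE],
                                 if (!is.null(genes)) genes else
                                   data.frame(gene_id = character(0), chrom = character(0),
                                              start = integer(0), end = integer(0)))
  write_bed(joint_regions, file.path(out_dir, "fst_pi_regions.bed"))
  fst_pi_genes <- attr(joint_regions, "genes")
  write_tsv(data.frame(gene = fst_pi_genes), file.path(out_dir, "fst_pi_genes.tsv"))

  log_msg("stage xpehh")
  lens <- chrom_lengths_of(ftab)
  if (is.null(gmap)) {
    gmap <- do.call(rbind, lapply(names(lens), function(cc) {
      constant_genetic_map(cc, lens[[cc]])
    }))
    class(gmap) <- c("genetic_map", class(gmap))
  }
  recs <- do.call(rbind, lapply(unique(ftab$chrom), function(cc) {
    sub <- subset_sites(ftab, which(ftab$chrom == cc))
    xpehh_scan(cohort_from_table(sub), focal, control, map = gmap)
  }))
  recs <- normalize_xpehh(recs)
  write_tsv(recs, file.path(out_dir, "xpehh.tsv"))
  xwin <- xpehh_windows(recs, config$xpehh_scheme, config$quantile,
                        genes = genes, chrom_lengths = lens)
  write_tsv(xwin, file.path(out_dir, "xpehh_windows.tsv"))
  xpehh_genes <- character(0)
  if (!is.null(genes)) {
    xreg <- attr(xwin, "regions")
    write_bed(xreg, file.path(out_dir, "xpehh_regions.bed"))
    xpehh_genes <- attr(xwin, "genes")
    write_tsv(data.frame(gene = xpehh_genes), file.path(out_dir, "xpehh_genes.tsv"))
  } else xreg <- NULL

  venn <- intersect_gene_sets(fst_pi_genes, xpehh_genes)
  write_tsv(data.frame(set = c("fst_pi_only", "shared", "xpehh_only"),
                       count = unname(venn$counts)),
            file.path(out_dir, "venn_counts.tsv"))

  enr_fst <- NULL; enr_xp <- NULL
  if (!is.null(term_map) && !is.null(genes) && nrow(genes$genes) > 0L) {
    log_msg("stage enrich")
    background <- genes$genes$gene_id
    enr_fst <- enrich(fst_pi_genes, background, term_map,
                      alpha = config$alpha, correction = config$correction)
    enr_xp <- enrich(xpehh_genes, background, term_map,
                     alpha = config$alpha, correction = config$correction)
    write_tsv(enr_fst, file.path(out_dir, "enrichment_fst_pi.tsv"))
    write_tsv(enr_xp, file.path(out_dir, "enrichment_xpehh.tsv"))
  }

  ld_out <- NULL
  if (config$include_ld) {
    log_msg("stage ld")
    ld_out <- lapply(stats::setNames(c(focal, control), c(focal, control)), function(pp) {
      curve <- ld_decay(ftab, config$ld, population = pp)
      write_tsv(curve, file.path(out_dir, sprintf("ld_decay_%s.tsv", pp)))
      list(curve = curve, half = half_decay_distance(curve))
    })
  }

  cutoffs <- c(attr(scan, "cutoffs"), xpehh = unname(attr(xwin, "cutoff")))
  manifest <- list(
    seed = config$seed,
    focal = focal, control = control,
    parameters = list(
      scan_window_bp = config$scan_scheme$width, scan_step_bp = config$scan_scheme$step,
      xpehh_window_bp = config$xpehh_scheme$width, xpehh_step_bp = config$xpehh_scheme$step,
      quantile = config$quantile, alpha = config$alpha,
      thresholds = unclass(config$thresholds)),
    cutoffs = as.list(cutoffs),
    counts = list(
      sites_raw = n_sites(tab), sites_filtered = n_sites(ftab),
      windows_scan = nrow(scan), windows_usable = sum(is.finite(scan$z_fst) &
                                                      is.finite(scan$log2_ratio)),
      joint_outlier_windows = sum(scan$joint, na.rm = TRUE),
      candidate_regions = nrow(joint_regions),
      genes_fst_pi = length(fst_pi_genes), genes_xpehh = length(xpehh_genes),
      genes_shared = length(venn$shared)))
  if (!is.null(truth)) {
    manifest$truth <- list(n_segregating = truth$n_segregating,
                           split_generation = truth$split_generation,
                           sweep = truth$sweep)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  log_msg("done: %d candidate regions, %d shared genes",
          nrow(joint_regions), length(venn$shared))

  structure(list(config = config, focal = focal, control = control,
                 table_raw_sites = n_sites(tab), table = ftab,
                 filter_report = filt$report, annotation = ann_df,
                 scan = scan, regions = joint_regions,
                 xpehh = recs, xpehh_win = xwin, xpehh_regions = xreg,
                 genes_fst_pi = fst_pi_genes, genes_xpehh = xpehh_genes,
                 venn = venn, enrichment_fst_pi = enr_fst, enrichment_xpehh = enr_xp,
                 ld = ld_out, cutoffs = cutoffs, truth = truth,
                 manifest = manifest, output_dir = out_dir),
            class = "sweep_scan_run")
}

#' @method print sweep_scan_run
#' @export
print.sweep_scan_run <- function(x, ...) {
  cat("Selective-sweep scan\n")
  cat(sprintf("  populations: focal=%s control=%s\n", x$focal, x$control))
  cat(sprintf("  sites: %d raw, %d after filters\n", x$table_raw_sites, n_sites(x$table)))
  cat(sprintf("  windows: %d (usable %d), joint outliers %d\n",
              nrow(x$scan), x$manifest$counts$windows_usable,
              x$manifest$counts$joint_outlier_windows))
  cat(sprintf("  cutoffs: Z(Fst) %.4f, log2 ratio %.4f, XP-EHH %.4f\n",
              x$cutoffs[["z_fst"]], x$cutoffs[["log2_ratio"]], x$cutoffs[["xpehh"]]))
  cat(sprintf("  candidate regions: %d; genes: %d (Fst-pi), %d (XP-EHH), %d shared\n",
              nrow(x$regions), length(x$genes_fst_pi), length(x$genes_xpehh),
              length(x$venn$shared)))
  invisible(x)
}

#' @method summary sweep_scan_run
#' @export
summary.sweep_scan_run <- function(object, ...) {
  print(object)
  cat("\nFilter report:\n")
  print(object$filter_report, row.names = FALSE)
  if (!is.null(object$enrichment_fst_pi) && nrow(object$enrichment_fst_pi)) {
    cat("\nTop enriched terms (Fst-pi candidates):\n")
    print(utils::head(object$enrichment_fst_pi, 5), row.names = FALSE)
  }
  invisible(object)
}
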