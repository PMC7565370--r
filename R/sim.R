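#' Configuration for the two-population Wright-Fisher simulator
#'
#' Builds a validated configuration for [simulate_cohort()]. The defaults are a
#' desk-scale preset for a focal arid-adapted deer population contrasted with a
#' smaller-sample control elk population: an ancestral population splits into a
#' focal lineage (declining through a recent bottleneck) and a control lineage.
#' The preset keeps the split depth in coalescent units (t / 2N of roughly 0.22),
#' the relative population sizes (control about 1.7x the focal size at the
#' split, focal present size about 0.44x its size at the split), the per-base
#' nucleotide diversity (4 N mu of about 5.6e-4, the genome-wide average for the
#' focal population), and the recombination-to-mutation ratio implied by a
#' 2.53 cM/Mb map and mu = 1.5e-8 per base per generation (r/mu about 1.69).
#' Population sizes, times, and per-generation rates are jointly rescaled so the
#' products N*mu, N*r and t/N are preserved at desk scale.
#'
#' @param seed integer seed; the same config and seed give byte-identical output
#' @param sequence_length chromosome length in bp
#' @param mutation_rate per-bp per-generation mutation probability (rescaled)
#' @param recombination_rate per-bp per-generation crossover probability (rescaled)
#' @param generation_time years per generation, used only to label outputs
#' @param ancestral_size diploid size of the ancestral (pre-split) population
#' @param split_generation generations before present at which the populations
#'   split; 0 simulates a single panmictic population
#' @param burn_in generations simulated before the split to reach
#'   mutation-drift equilibrium (default `8 * ancestral_size`)
#' @param epochs_focal,epochs_control data.frames with columns `start`
#'   (generations before present at which the size takes effect, strictly
#'   decreasing, first row at `split_generation`) and `size` (diploids)
#' @param migration_rates length-2 numeric `c(focal, control)`: per-generation
#'   probability that a gamete in that population is drawn from the other one
#' @param sample_sizes length-2 integer `c(focal, control)` diploids sampled at
#'   the end of the simulation (defaults 13 and 4)
#' @param sweep optional sweep: list with `position` (bp), `s` (selection
#'   coefficient, genic with h = 0.5), `onset` (generations before present at
#'   which the allele is injected), `population` ("focal" or "control"), and
#'   optionally `mode` ("hard", the default: a single derived copy, with the
#'   sweep phase replayed from the onset until the allele escapes early loss,
#'   up to `max_restarts` times and until it reaches `min_final_freq` (default
#'   0.5) in the target population at sampling; or "standing": `initial_freq` of the target
#'   population's haplotypes become carriers at the onset, no replay) and
#'   `footprint` (bp half-width of the truth interval, default 25000)
#' @param depth_mean mean of the Poisson per-sample read depth written to VCF
#' @param mq_value site RMS mapping quality written to VCF
#' @param mq_corrupt_frac fraction of sites given a low (< 20) MQ so depth/MQ
#'   filters can be exercised; default 0
#' @param cm_per_mb constant genetic-map rate, default 2.53 cM/Mb
#' @param chrom chromosome name
#' @param pop_names names of the two populations
#' @return an object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       sequence_length = 5e5,
                       mutation_rate = 1.17e-6,
                       recombination_rate = 1.97e-6,
                       generation_time = 6.3,
                       ancestral_size = 120L,
                       split_generation = 44L,
                       burn_in = NULL,
                       epochs_focal = NULL,
                       epochs_control = NULL,
                       migration_rates = c(focal = 0, control = 0),
                       sample_sizes = c(focal = 13L, control = 4L),
                       sweep = NULL,
                       depth_mean = 8,
                       mq_value = 40,
                       mq_corrupt_frac = 0,
                       cm_per_mb = 2.53,
                       chrom = "chr1",
                       pop_names = c("focal", "control")) {
  if (!is_count(sequence_length, 1)) stop_input("sequence_length must be a positive integer")
  if (!is_count(ancestral_size, 2)) stop_input("ancestral_size must be >= 2")
  if (!is_count(split_generation, 0)) stop_input("split_generation must be >= 0")
  if (mutation_rate < 0 || recombination_rate < 0) stop_input("rates must be non-negative")
  if (any(migration_rates < 0) || any(migration_rates >= 1)) {
    stop_input("migration rates must be in [0, 1)")
  }
  if (is.null(burn_in)) burn_in <- 8L * as.integer(ancestral_size)
  if (!is_count(burn_in, 1)) stop_input("burn_in must be a positive integer")
  if (is.null(epochs_focal)) {
    epochs_focal <- if (split_generation > 0) {
      data.frame(start = c(split_generation, max(1L, split_generation %/% 2L)),
                 size = c(100L, 44L))
    } else data.frame(start = integer(0), size = integer(0))
  }
  if (is.null(epochs_control)) {
    epochs_control <- if (split_generation > 0) {
      data.frame(start = split_generation, size = 170L)
    } else data.frame(start = integer(0), size = integer(0))
  }
  validate_epochs <- function(ep, lab) {
    if (split_generation == 0L) return(invisible())
    if (nrow(ep) == 0L) stop_input("%s: at least one epoch required", lab)
    if (ep$start[1] < split_generation) {
      stop_input("%s: first epoch must start at or before the split (start >= split_generation)", lab)
    }
    if (nrow(ep) > 1 && any(diff(ep$start) >= 0)) {
      stop_input("%s: epoch starts must be strictly decreasing", lab)
    }
    if (any(ep$size < 2)) stop_input("%s: all sizes must be >= 2", lab)
  }
  validate_epochs(epochs_focal, "epochs_focal")
  validate_epochs(epochs_control, "epochs_control")
  sample_sizes <- as.integer(sample_sizes)
  if (length(sample_sizes) != 2L) stop_input("sample_sizes must have length 2")
  names(sample_sizes) <- c("focal", "control")
  if (split_generation == 0L && sample_sizes[2] > 0) {
    stop_input("no control population without a split; set control sample size to 0")
  }
  if (!is.null(sweep)) {
    if (is.null(sweep$position) || is.null(sweep$s) || is.null(sweep$onset)) {
      stop_input("sweep needs position, s and onset")
    }
    if (sweep$position < 0 || sweep$position >= sequence_length) {
      stop_input("sweep position must lie in [0, sequence_length)")
    }
    if (is.null(sweep$population)) sweep$population <- "focal"
    if (!sweep$population %in% c("focal", "control")) {
      stop_input("sweep population must be 'focal' or 'control'")
    }
    if (is.null(sweep$mode)) sweep$mode <- "hard"
    if (!sweep$mode %in% c("hard", "standing")) {
      stop_input("sweep mode must be 'hard' or 'standing'")
    }
    if (is.null(sweep$initial_freq)) sweep$initial_freq <- 0.1
    ## truth-interval half-width: the classic hitchhiking scale. Variation is
    ## dragged where the per-generation recombination fraction r*d stays below
    ## about s/ln(2Ns) over the sweep, giving d* ~ s / (r ln(2Ns)).
    if (is.null(sweep$footprint)) {
      n_t <- if (split_generation == 0L) ancestral_size else {
        if (sweep$population == "focal") epochs_focal$size[1] else epochs_control$size[1]
      }
      ns2 <- max(2, 2 * n_t * sweep$s)
      d_star <- sweep$s / (max(recombination_rate, 1e-12) * log(ns2))
      sweep$footprint <- round(min(max(d_star, 5000), sequence_length / 4))
    }
  }
  structure(list(
    seed = as.integer(seed), sequence_length = as.integer(sequence_length),
    mutation_rate = mutation_rate, recombination_rate = recombination_rate,
    generation_time = generation_time, ancestral_size = as.integer(ancestral_size),
    split_generation = as.integer(split_generation), burn_in = as.integer(burn_in),
    epochs_focal = epochs_focal, epochs_control = epochs_control,
    migration_rates = migration_rates, sample_sizes = sample_sizes,
    sweep = sweep, depth_mean = depth_mean, mq_value = mq_value,
    mq_corrupt_frac = mq_corrupt_frac, cm_per_mb = cm_per_mb,
    chrom = chrom, pop_names = pop_names), class = "sim_config")
}

## diploid size active `gbp` generations before present
epoch_size <- function(epochs, gbp) {
  active <- epochs$start > gbp
  if (!any(active)) utils::tail(epochs$size, 1) else epochs$size[max(which(active))]
}

## One Wright-Fisher generation. `mat` is sites x haplotypes (0/1 integer),
## `blocks` a list of old haplotype column indices per population, `new_sizes`
## diploid sizes of the offspring populations, `mig[p]` the probability that a
## gamete of population p comes from the other population, `fitness` a list of
## per-diploid parent weights (or NULL for neutrality).
wf_generation <- function(mat, pos, L, mu, p_rec, blocks, new_sizes, mig, fitness) {
  npop <- length(new_sizes)
  base_col <- integer(0)
  sister_col <- integer(0)
  for (p in seq_len(npop)) {
    ng <- 2L * new_sizes[p]
    src <- rep.int(p, ng)
    if (npop == 2L && mig[p] > 0) {
      src[stats::runif(ng) < mig[p]] <- 3L - p
    }
    for (q in unique(src)) {
      take <- which(src == q)
      cols_q <- blocks[[min(q, length(blocks))]]
      npar <- length(cols_q) %/% 2L
      w <- if (!is.null(fitness)) fitness[[min(q, length(fitness))]] else NULL
      par <- sample.int(npar, length(take), replace = TRUE, prob = w)
      which_hap <- sample.int(2L, length(take), replace = TRUE)
      b <- cols_q[2L * (par - 1L) + which_hap]
      s <- cols_q[2L * (par - 1L) + (3L - which_hap)]
      base_col[take + 2L * sum(new_sizes[seq_len(p - 1L)])] <- b
      sister_col[take + 2L * sum(new_sizes[seq_len(p - 1L)])] <- s
    }
  }
  H_new <- 2L * sum(new_sizes)
  newmat <- mat[, base_col, drop = FALSE]
  ## single-crossover recombination
  rec <- stats::runif(H_new) < p_rec
  if (any(rec) && nrow(mat) > 0L) {
    xo <- sample.int(L - 1L, sum(rec), replace = TRUE)
    sis <- mat[, sister_col[rec], drop = FALSE]
    mask <- outer(pos, xo, ">")
    block <- newmat[, rec, drop = FALSE]
    block[mask] <- sis[mask]
    newmat[, rec] <- block
  }
  ## new mutations, infinite-sites style (one derived copy each)
  n_mut <- stats::rpois(1L, H_new * mu * L)
  if (n_mut > 0L) {
    cand <- sample.int(L, n_mut, replace = TRUE)
    cand <- cand[!(cand %in% pos)]
    cand <- cand[!duplicated(cand)]
    if (length(cand) > 0L) {
      add <- matrix(0L, length(cand), H_new)
      add[cbind(seq_along(cand), sample.int(H_new, length(cand), replace = TRUE))] <- 1L
      newmat <- rbind(newmat, add)
      pos <- c(pos, cand)
    }
  }
  list(mat = newmat, pos = pos)
}

#' Simulate a two-population phased cohort under the Wright-Fisher model
#'
#' Forward simulation with per-generation binomial resampling, single-crossover
#' recombination, infinite-sites mutation, an ancestral burn-in followed by a
#' population split with per-population size epochs and optional migration, and
#' an optional injectable hard sweep (genic selection, h = 0.5). Allele 0 is the
#' founding (ancestral) state. Only sites segregating in the sampled cohort are
#' returned. Output is fully determined by the configuration and its seed.
#'
#' @param config a [sim_config()] object
#' @return list with `cohort` (class `phased_cohort`: positions, cM positions,
#'   a sites x haplotypes 0/1 allele matrix, sample ids and population labels)
#'   and `truth` (class `truth_record`: seed, demographic history as realized,
#'   segregating-site count, and the planted-sweep interval with loss/fixation
#'   flags, if a sweep was configured)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  L <- config$sequence_length
  mu <- config$mutation_rate
  p_rec <- 1 - exp(-config$recombination_rate * L)
  split <- config$split_generation
  total_gen <- config$burn_in + split
  N_anc <- config$ancestral_size

  sw <- config$sweep
  state <- list(pos = integer(0), mat = matrix(0L, 0L, 2L * N_anc),
                blocks = list(seq_len(2L * N_anc)), sizes = N_anc,
                sweep_on = FALSE, lost = FALSE, fixed = FALSE)
  spos <- if (!is.null(sw)) as.integer(max(1L, sw$position)) else NA_integer_

  ## advance one generation (reproduction with optional selection, then pruning)
  one_gen <- function(st, t) {
    gbp <- total_gen - t
    if (gbp >= split || split == 0L) {
      new_sizes <- N_anc
    } else {
      new_sizes <- c(epoch_size(config$epochs_focal, gbp),
                     epoch_size(config$epochs_control, gbp))
    }
    fitness <- NULL
    if (st$sweep_on) {
      idx <- match(spos, st$pos)
      if (is.na(idx)) {
        st$sweep_on <- FALSE            # resolved (lost or globally fixed)
      } else {
        target <- if (sw$population == "focal") 1L else 2L
        target <- min(target, length(st$blocks))
        cols <- st$blocks[[target]]
        g <- st$mat[idx, cols[seq_along(cols) %% 2L == 1L]] +
             st$mat[idx, cols[seq_along(cols) %% 2L == 0L]]
        fitness <- vector("list", length(st$blocks))
        fitness[[target]] <- 1 + 0.5 * sw$s * g
      }
    }
    step <- wf_generation(st$mat, st$pos, L, mu, p_rec, st$blocks, new_sizes,
                          config$migration_rates, fitness)
    st$mat <- step$mat
    st$pos <- step$pos
    st$sizes <- new_sizes
    st$blocks <- if (length(new_sizes) == 1L) list(seq_len(2L * new_sizes)) else {
      list(seq_len(2L * new_sizes[1]), 2L * new_sizes[1] + seq_len(2L * new_sizes[2]))
    }
    rs <- rowSums(st$mat)
    H <- ncol(st$mat)
    if (st$sweep_on) {
      idx <- match(spos, st$pos)
      if (!is.na(idx)) {
        if (rs[idx] == 0L) st$lost <- TRUE
        if (rs[idx] == H) st$fixed <- TRUE
      }
    }
    keep <- rs > 0L & rs < H
    if (!all(keep)) {
      st$mat <- st$mat[keep, , drop = FALSE]
      st$pos <- st$pos[keep]
    }
    st
  }
  run_range <- function(st, from, to) {
    for (t in seq_len(to - from + 1L) + from - 1L) st <- one_gen(st, t)
    st
  }
  ## put the derived allele on carriers of the target population: one copy for
  ## a hard sweep, round(initial_freq * 2N) copies for standing variation
  inject <- function(st) {
    target <- if (is.null(sw$population) || sw$population == "focal" ||
                  length(st$blocks) == 1L) 1L else 2L
    cols <- st$blocks[[target]]
    idx <- match(spos, st$pos)
    if (is.na(idx)) {
      st$mat <- rbind(st$mat, matrix(0L, 1L, ncol(st$mat)))
      st$pos <- c(st$pos, spos)
      idx <- length(st$pos)
    } else {
      st$mat[idx, ] <- 0L               # claim the site for the sweep allele
    }
    ncarrier <- if (identical(sw$mode, "standing")) {
      max(1L, round(sw$initial_freq * length(cols)))
    } else 1L
    st$mat[idx, sample(cols, ncarrier)] <- 1L
    st$sweep_on <- TRUE
    st$lost <- FALSE
    st$fixed <- FALSE
    st
  }

  attempts <- 0L
  if (is.null(sw)) {
    state <- run_range(state, 1L, total_gen)
  } else {
    t_inject <- max(1L, total_gen - as.integer(sw$onset))
    state <- run_range(state, 1L, t_inject)
    snapshot <- state <- inject(state)
    max_restarts <- if (identical(sw$mode, "standing")) 0L else
      if (is.null(sw$max_restarts)) 100L else sw$max_restarts
    min_freq <- if (is.null(sw$min_final_freq)) 0.5 else sw$min_final_freq
    repeat {
      state <- if (t_inject < total_gen) run_range(state, t_inject + 1L, total_gen) else state
      attempts <- attempts + 1L
      target <- if (sw$population == "focal" || length(state$blocks) == 1L) 1L else 2L
      idx <- match(spos, state$pos)
      freq_now <- if (state$fixed) 1 else if (is.na(idx)) 0 else {
        mean(state$mat[idx, state$blocks[[target]]])
      }
      established <- !state$lost && freq_now >= min_freq
      if (established || state$fixed || attempts > max_restarts) break
      state <- snapshot         # sweep died out or stalled: replay from the onset
      state$lost <- FALSE
    }
  }
  mat <- state$mat
  pos <- state$pos
  sizes <- state$sizes
  sweep_state <- list(lost = state$lost, fixed = state$fixed)

  ## sample diploids
  ns <- config$sample_sizes
  if (length(sizes) == 1L) {
    if (ns[1] > sizes) stop_input("focal sample size exceeds final population size")
    ind <- sort(sample.int(sizes, ns[1]))
    cols <- as.vector(rbind(2L * ind - 1L, 2L * ind))
    pop_lab <- rep(config$pop_names[1], ns[1])
  } else {
    if (ns[1] > sizes[1] || ns[2] > sizes[2]) {
      stop_input("sample sizes exceed final population sizes")
    }
    ind1 <- sort(sample.int(sizes[1], ns[1]))
    ind2 <- sort(sample.int(sizes[2], ns[2]))
    cols <- c(as.vector(rbind(2L * ind1 - 1L, 2L * ind1)),
              2L * sizes[1] + as.vector(rbind(2L * ind2 - 1L, 2L * ind2)))
    pop_lab <- rep(config$pop_names, ns)
  }
  sub <- mat[, cols, drop = FALSE]
  rs <- rowSums(sub)
  keep <- rs > 0L & rs < ncol(sub)
  sub <- sub[keep, , drop = FALSE]
  spos <- pos[keep]
  ord <- order(spos)
  sub <- sub[ord, , drop = FALSE]
  spos <- spos[ord]

  n_samp <- sum(ns)
  sample_ids <- sprintf("%s_%02d", rep(config$pop_names, ns),
                        unlist(lapply(ns, seq_len), use.names = FALSE))
  cohort <- structure(list(
    chrom = config$chrom, sequence_length = L,
    positions = as.integer(spos),
    cm = spos * config$cm_per_mb / 1e6,
    alleles = sub,
    sample_ids = sample_ids,
    populations = stats::setNames(pop_lab, sample_ids),
    hap_sample = rep(seq_len(n_samp), each = 2L),
    config = config), class = "phased_cohort")

  sweep_truth <- NULL
  if (!is.null(sw)) {
    sidx <- match(as.integer(max(1L, sw$position)), spos)
    freq_focal <- if (!is.na(sidx)) {
      fc <- which(rep(pop_lab, each = 2L) == config$pop_names[1])
      mean(sub[sidx, fc])
    } else if (sweep_state$fixed) 1.0 else 0.0
    sweep_truth <- list(
      position = sw$position, s = sw$s, onset = sw$onset, population = sw$population,
      interval = c(max(0, sw$position - sw$footprint),
                   min(L, sw$position + sw$footprint)),
      lost = sweep_state$lost && !sweep_state$fixed,
      fixed = sweep_state$fixed,
      attempts = attempts,
      freq_focal_sample = freq_focal)
  }
  truth <- structure(list(
    seed = config$seed,
    split_generation = split,
    burn_in = config$burn_in,
    ancestral_size = N_anc,
    epochs_focal = config$epochs_focal,
    epochs_control = config$epochs_control,
    n_segregating = nrow(sub),
    sweep = sweep_truth), class = "truth_record")
  list(cohort = cohort, truth = truth)
}

#' @method print phased_cohort
#' @export
print.phased_cohort <- function(x, ...) {
  cat(sprintf("phased_cohort: %d sites, %d haplotypes (%s), %s:1-%d\n",
              nrow(x$alleles), ncol(x$alleles),
              paste(sprintf("%s=%d", unique(x$populations),
                            table(x$populations)[unique(x$populations)]),
                    collapse = ", "),
              x$chrom, x$sequence_length))
  invisible(x)
}

## haplotype column indices of a population
cohort_hap_cols <- function(cohort, population) {
  if (!population %in% cohort$populations) {
    stop_input("unknown population label '%s'", population)
  }
  which(rep(unname(cohort$populations), each = 2L) == population)
}

#' Write a simulated cohort to standard files
#'
#' Writes a VCF 4.2 (phased GT, per-sample Poisson DP, site INFO MQ), a
#' sample-to-population map TSV, a constant-rate genetic map TSV, and a
#' plain-text truth ledger. REF is the ancestral and ALT the derived allele;
#' bases are taken from `ref_seq` when given, otherwise drawn at random.
#' Output bytes are fully determined by the cohort (and its config seed).
#'
#' @param cohort a `phased_cohort`
#' @param truth the matching `truth_record`
#' @param output_dir directory, created if needed
#' @param ref_seq optional reference chromosome as a single ACGT string used
#'   for REF alleles (e.g. the `sequence` from [make_annotation_and_terms()])
#' @return invisibly, a named list of file paths
#' @export
write_cohort <- function(cohort, truth, output_dir, ref_seq = NULL) {
  if (nrow(cohort$alleles) == 0L) stop_input("refusing to write an empty cohort")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) stop_input("cannot create output directory %s", output_dir)
  cfg <- cohort$config
  set.seed(cfg$seed + 1L)
  m <- nrow(cohort$alleles)
  n <- length(cohort$sample_ids)
  bases <- c("A", "C", "G", "T")
  if (!is.null(ref_seq)) {
    ref <- strsplit(substr(ref_seq, 1, nchar(ref_seq)), "")[[1]][cohort$positions]
    ref <- toupper(ref)
  } else {
    ref <- bases[sample.int(4L, m, replace = TRUE)]
  }
  ## transition-biased substitutions (ts probability 0.72 gives the ts/tv
  ## ratio of about 2.6 typical of mammalian resequencing data)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  alt <- vapply(ref, function(b) {
    if (stats::runif(1) < 0.72) transition[[b]] else {
      sample(setdiff(bases, c(b, transition[[b]])), 1L)
    }
  }, character(1), USE.NAMES = FALSE)
  dp <- matrix(stats::rpois(m * n, cfg$depth_mean), m, n)
  mq <- rep(cfg$mq_value, m)
  if (cfg$mq_corrupt_frac > 0) {
    bad <- stats::runif(m) < cfg$mq_corrupt_frac
    mq[bad] <- stats::runif(sum(bad), 0, 19.5)
  }
  a1 <- cohort$alleles[, seq(1L, 2L * n, by = 2L), drop = FALSE]
  a2 <- cohort$alleles[, seq(2L, 2L * n, by = 2L), drop = FALSE]
  gt <- matrix(paste0(a1, "|", a2, ":", dp), m, n)

  vcf_path <- file.path(output_dir, "cohort.vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", cohort$chrom, cohort$sequence_length),
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            cohort$sample_ids), collapse = "\t"))
  body <- paste(cohort$chrom, cohort$positions, ".", ref, alt, "100", "PASS",
                sprintf("MQ=%.2f", mq), "GT:DP",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf_path)

  popmap_path <- file.path(output_dir, "popmap.tsv")
  writeLines(paste(cohort$sample_ids, unname(cohort$populations), sep = "\t"),
             popmap_path)

  map_path <- file.path(output_dir, "genetic_map.tsv")
  anchors <- unique(c(1L, seq(0L, cohort$sequence_length, by = 100000L)[-1],
                      cohort$sequence_length))
  map_df <- data.frame(chrom = cohort$chrom, bp = anchors,
                       cM = anchors * cfg$cm_per_mb / 1e6)
  utils::write.table(map_df, map_path, sep = "\t", quote = FALSE, row.names = FALSE)

  truth_path <- file.path(output_dir, "truth.txt")
  kv <- c(seed = truth$seed, split_generation = truth$split_generation,
          burn_in = truth$burn_in, ancestral_size = truth$ancestral_size,
          n_segregating = truth$n_segregating)
  if (!is.null(truth$sweep)) {
    kv <- c(kv, sweep_position = truth$sweep$position, sweep_s = truth$sweep$s,
            sweep_onset = truth$sweep$onset, sweep_population = truth$sweep$population,
            sweep_interval_start = truth$sweep$interval[1],
            sweep_interval_end = truth$sweep$interval[2],
            sweep_lost = as.integer(truth$sweep$lost),
            sweep_fixed = as.integer(truth$sweep$fixed),
            sweep_freq_focal_sample = truth$sweep$freq_focal_sample)
  }
  writeLines(paste(names(kv), kv, sep = "\t"), truth_path)

  invisible(list(vcf = vcf_path, popmap = popmap_path, genetic_map = map_path,
                 truth = truth_path))
}
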