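#' Generate toy gene models, a reference sequence and a term map
#'
#' Places `n_genes` non-overlapping genes (1-3 CDS exons each, every CDS length
#' divisible by 3, random strand) on a random ACGT reference chromosome, and
#' assigns each gene 1-3 terms out of `n_terms`. A planted term with a chosen
#' gene subset can be added for enrichment-recovery experiments. Deterministic
#' under the seed.
#'
#' @param sequence_length chromosome length in bp
#' @param n_genes,n_terms counts (0 allowed)
#' @param planted_term optional `list(term = , genes = )` where `genes` are ids
#'   such as "gene001" or indices into the generated genes
#' @param seed integer seed
#' @param chrom chromosome name
#' @param output_dir if given, writes `genes.gff3` (via rtracklayer),
#'   `terms.tsv` and `ref.fa` there
#' @return list of class `gene_annotation`: `genes` (a `gene_models` object
#'   with `genes` and `cds` data.frames plus the reference `sequence`) and
#'   `term_map` (data.frame with columns term, gene)
#' @export
make_annotation_and_terms <- function(sequence_length, n_genes = 30L, n_terms = 20L,
                                      planted_term = NULL, seed = 1L,
                                      chrom = "chr1", output_dir = NULL) {
  if (!is_count(n_genes)) stop_input("n_genes must be a non-negative integer")
  set.seed(seed)
  L <- as.integer(sequence_length)
  sequence <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  genes <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), strand = character(0))
  cds <- data.frame(gene_id = character(0), start = integer(0), end = integer(0))
  placed <- matrix(integer(0), 0, 2)
  for (i in seq_len(n_genes)) {
    ok <- FALSE
    for (attempt in seq_len(500L)) {
      n_ex <- sample.int(3L, 1L)
      ex_len <- 3L * sample(40:160, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1L) sample(80:400, n_ex - 1L, replace = TRUE) else integer(0)
      span <- sum(ex_len) + sum(in_len)
      if (span >= L) next
      start <- sample.int(L - span, 1L)
      end <- start + span - 1L
      if (nrow(placed) == 0L || all(end < placed[, 1] | start > placed[, 2])) {
        gid <- sprintf("gene%03d", i)
        ex_start <- start + cumsum(c(0L, ex_len[-n_ex] + in_len))
        genes <- rbind(genes, data.frame(
          gene_id = gid, chrom = chrom, start = start, end = end,
          strand = sample(c("+", "-"), 1L)))
        cds <- rbind(cds, data.frame(gene_id = gid, start = ex_start,
                                     end = ex_start + ex_len - 1L))
        placed <- rbind(placed, c(start, end))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop_input("could not place %d non-overlapping genes on %d bp", n_genes, L)
  }
  terms <- sprintf("TERM%03d", seq_len(n_terms))
  term_map <- data.frame(term = character(0), gene = character(0))
  if (n_genes > 0L && n_terms > 0L) {
    rows <- lapply(genes$gene_id, function(g) {
      data.frame(term = sample(terms, sample.int(min(3L, n_terms), 1L)), gene = g)
    })
    term_map <- do.call(rbind, rows)
  }
  if (!is.null(planted_term)) {
    pg <- planted_term$genes
    if (is.numeric(pg)) pg <- genes$gene_id[pg]
    if (!all(pg %in% genes$gene_id)) stop_input("planted term genes not in the annotation")
    term_map <- rbind(term_map, data.frame(term = planted_term$term, gene = pg))
  }
  term_map <- unique(term_map)
  rownames(term_map) <- NULL
  models <- structure(list(genes = genes, cds = cds, chrom = chrom,
                           sequence = sequence, sequence_length = L),
                      class = "gene_models")
  out <- structure(list(genes = models, term_map = term_map),
                   class = "gene_annotation")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_gff3(models, file.path(output_dir, "genes.gff3"))
    utils::write.table(term_map, file.path(output_dir, "terms.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    seqs <- Biostrings::DNAStringSet(stats::setNames(sequence, chrom))
    Biostrings::writeXStringSet(seqs, file.path(output_dir, "ref.fa"))
    out$files <- list(gff3 = file.path(output_dir, "genes.gff3"),
                      terms = file.path(output_dir, "terms.tsv"),
                      fasta = file.path(output_dir, "ref.fa"))
  }
  out
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and CDS features (one transcript per gene, CDS phases
#' computed from cumulative coding length) through rtracklayer.
#'
#' @param models a `gene_models` object
#' @param path output path
#' @export
write_gff3 <- function(models, path) {
  g <- models$genes
  if (nrow(g) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  feats <- list()
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    segs <- models$cds[models$cds$gene_id == gid, , drop = FALSE]
    segs <- segs[order(segs$start), , drop = FALSE]
    w <- segs$end - segs$start + 1L
    ## coding bases 5' of each genomic segment (minus strand reads right-to-left)
    cum <- if (g$strand[i] == "-") sum(w) - cumsum(w) else cumsum(c(0L, w))[seq_len(nrow(segs))]
    phase <- (3L - cum %% 3L) %% 3L
    feats[[length(feats) + 1L]] <- data.frame(
      type = c("gene", "mRNA", rep("CDS", nrow(segs))),
      start = c(g$start[i], g$start[i], segs$start),
      end = c(g$end[i], g$end[i], segs$end),
      strand = g$strand[i],
      phase = c(NA, NA, phase),
      ID = c(gid, paste0(gid, ".t1"), rep(NA, nrow(segs))),
      Parent = c(NA, gid, rep(paste0(gid, ".t1"), nrow(segs))))
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(models$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$phase <- as.integer(df$phase)
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- df$Parent
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3 (and optionally a reference FASTA)
#'
#' @param gff path to a GFF3 with gene/mRNA/CDS features
#' @param fasta optional reference FASTA; required for synonymous versus
#'   nonsynonymous classification in [annotate_sites()]
#' @return a `gene_models` object
#' @export
read_gff_genes <- function(gff, fasta = NULL) {
  gr <- rtracklayer::import(gff, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  genes <- data.frame(gene_id = as.character(md$ID[is_gene]),
                      chrom = as.character(GenomicRanges::seqnames(gr)[is_gene]),
                      start = GenomicRanges::start(gr)[is_gene],
                      end = GenomicRanges::end(gr)[is_gene],
                      strand = as.character(GenomicRanges::strand(gr)[is_gene]))
  tx2gene <- character(0)
  is_tx <- md$type %in% c("mRNA", "transcript")
  if (any(is_tx)) {
    tx2gene <- stats::setNames(
      vapply(md$Parent[is_tx], function(p) as.character(p)[1], character(1)),
      as.character(md$ID[is_tx]))
  }
  is_cds <- md$type == "CDS"
  cds_parent <- vapply(md$Parent[is_cds], function(p) as.character(p)[1], character(1))
  cds_gene <- ifelse(cds_parent %in% names(tx2gene), tx2gene[cds_parent], cds_parent)
  cds <- data.frame(gene_id = unname(cds_gene),
                    start = GenomicRanges::start(gr)[is_cds],
                    end = GenomicRanges::end(gr)[is_cds])
  chrom <- if (nrow(genes)) genes$chrom[1] else NA_character_
  sequence <- NULL
  seqlen <- NA_integer_
  if (!is.null(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    sequence <- as.character(ss[[1]])
    seqlen <- nchar(sequence)
    if (is.na(chrom)) chrom <- names(ss)[1]
  }
  structure(list(genes = genes, cds = cds, chrom = chrom,
                 sequence = sequence, sequence_length = seqlen),
            class = "gene_models")
}

## precedence ranks; upstream preferred over downstream on ties
category_rank <- c(intergenic = 1, downstream = 2, upstream = 2.5, intron = 3,
                   exon_synonymous = 4, exon_nonsynonymous = 4, splice_site = 5)

#' Positional annotation of SNPs against gene models
#'
#' Assigns each site exactly one category with precedence splice_site > exon >
#' intron > upstream/downstream > intergenic. Splice sites are positions within
#' 2 bp of an intron boundary; upstream/downstream are within 1 kb of the gene
#' start/end, strand-aware. Exonic SNPs are classified synonymous or
#' nonsynonymous by codon translation under the standard genetic code (minus
#' strand genes are reverse-complemented; stop gain or loss counts as
#' nonsynonymous). A site whose REF allele contradicts the reference sequence
#' gets `error = TRUE` and an NA category.
#'
#' @param table a [variant_table()]
#' @param genes a `gene_models` object; `sequence` is required for the
#'   synonymous/nonsynonymous split (without it exonic sites are `exon_NA`)
#' @param flank bp defining upstream/downstream, default 1000
#' @param splice_bp bp from an intron boundary defining splice sites, default 2
#' @return data.frame: chrom, pos, category, gene_id, aa_change, error
#' @export
annotate_sites <- function(table, genes, flank = 1000L, splice_bp = 2L) {
  m <- n_sites(table)
  out <- data.frame(chrom = table$chrom, pos = table$pos,
                    category = rep("intergenic", m),
                    gene_id = NA_character_, aa_change = NA_character_,
                    error = FALSE, stringsAsFactors = FALSE)
  if (m == 0L || nrow(genes$genes) == 0L) return(out)
  gdf <- genes$genes
  ## per-gene transcript preparation
  gprep <- lapply(seq_len(nrow(gdf)), function(i) {
    segs <- genes$cds[genes$cds$gene_id == gdf$gene_id[i], , drop = FALSE]
    segs <- segs[order(segs$start), , drop = FALSE]
    w <- segs$end - segs$start + 1L
    tx <- NULL
    if (!is.null(genes$sequence)) {
      tx <- paste(substring(genes$sequence, segs$start, segs$end), collapse = "")
      if (gdf$strand[i] == "-") tx <- revcomp(tx)
    }
    introns <- if (nrow(segs) > 1L) {
      data.frame(start = segs$end[-nrow(segs)] + 1L, end = segs$start[-1] - 1L)
    } else data.frame(start = integer(0), end = integer(0))
    list(segs = segs, w = w, cum = cumsum(c(0L, w)), total = sum(w),
         tx = tx, introns = introns)
  })
  sites_gr <- GenomicRanges::GRanges(table$chrom, IRanges::IRanges(table$pos, table$pos))
  genes_gr <- GenomicRanges::GRanges(gdf$chrom,
                                     IRanges::IRanges(pmax(1L, gdf$start - flank),
                                                      gdf$end + flank))
  hits <- GenomicRanges::findOverlaps(sites_gr, genes_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  code <- Biostrings::GENETIC_CODE
  rank_now <- rep(0, m)
  for (h in seq_along(qh)) {
    si <- qh[h]
    gi <- sh[h]
    p <- table$pos[si]
    gp <- gprep[[gi]]
    strand <- gdf$strand[gi]
    cat_h <- NULL; aa <- NA_character_; err <- FALSE
    if (p >= gdf$start[gi] && p <= gdf$end[gi]) {
      in_intron <- nrow(gp$introns) > 0L &&
        any(p >= gp$introns$start & p <= gp$introns$end)
      if (in_intron) {
        near <- any((p - gp$introns$start < splice_bp & p >= gp$introns$start) |
                    (gp$introns$end - p < splice_bp & p <= gp$introns$end))
        cat_h <- if (near) "splice_site" else "intron"
      } else {
        seg_k <- which(p >= gp$segs$start & p <= gp$segs$end)[1]
        if (is.na(seg_k)) { cat_h <- "intron" } else if (is.null(gp$tx)) {
          cat_h <- "exon_NA"
        } else {
          ref_base <- toupper(substr(genes$sequence, p, p))
          if (ref_base != table$ref[si]) {
            err <- TRUE
            cat_h <- NA_character_
          } else {
            off <- gp$cum[seg_k] + (p - gp$segs$start[seg_k] + 1L)
            cds_pos <- if (strand == "+") off else gp$total - off + 1L
            ci <- (cds_pos - 1L) %/% 3L + 1L
            within <- cds_pos - 3L * (ci - 1L)
            codon <- substr(gp$tx, 3L * ci - 2L, 3L * ci)
            alt_b <- if (strand == "+") table$alt[si] else complement_base(table$alt[si])
            alt_codon <- codon
            substr(alt_codon, within, within) <- alt_b
            aa_ref <- code[[codon]]
            aa_alt <- code[[alt_codon]]
            cat_h <- if (aa_ref == aa_alt) "exon_synonymous" else "exon_nonsynonymous"
            aa <- sprintf("%s%d%s", aa_ref, ci, aa_alt)
          }
        }
      }
    } else {
      before <- p < gdf$start[gi]
      cat_h <- if ((before && strand == "+") || (!before && strand == "-")) {
        "upstream"
      } else "downstream"
    }
    r <- if (err) 4 else if (cat_h %in% names(category_rank)) category_rank[[cat_h]] else 4
    if (r > rank_now[si]) {
      rank_now[si] <- r
      out$category[si] <- cat_h
      out$gene_id[si] <- gdf$gene_id[gi]
      out$aa_change[si] <- aa
      out$error[si] <- err
    }
  }
  out
}
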