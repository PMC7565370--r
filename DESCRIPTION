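Package: sweepscan
Title: Selective-Sweep Scans for Two-Population Whole-Genome Resequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects selective sweeps from biallelic SNP data for a focal and a
    control population. Implements the standard resequencing quality filters
    (depth, RMS mapping quality, missingness, minor allele frequency, proximal-SNP
    removal), positional SNP annotation against gene models (splice/exon/intron/
    up-downstream/intergenic, synonymous versus nonsynonymous), windowed nucleotide
    diversity and Weir-Cockerham Fst with Z-transformation, log2 diversity-ratio
    scans with joint top-quantile outlier calling, cross-population extended
    haplotype homozygosity (XP-EHH) on a genetic map, linkage-disequilibrium decay
    curves with half-decay distance, candidate-region merging and gene mapping,
    and hypergeometric term enrichment. A forward Wright-Fisher simulator with
    population splits, bottlenecks, migration and injectable hard sweeps generates
    fully self-contained test cohorts in standard formats (VCF, GFF3, TSV).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
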