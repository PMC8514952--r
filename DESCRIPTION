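Package: trlocus
Title: Annotation of T-Cell Receptor Germline Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural annotation of T-cell receptor (TRA/D, TRG, TRB) germline
    loci from genomic sequence. Locates candidate V, D, J and C genes by k-mer
    seeded local alignment against reference germline sets, describes their full
    structure (leader parts and splice sites, V-exon framework/CDR partition and
    conserved residues, G-rich D cores, J motifs and donor splices,
    reference-guided C exon chains), scans and scores recombination signal
    sequences (heptamer/spacer/nonamer) by mutation counting, classifies every
    gene as functional, ORF or pseudogene from a transparent severity table,
    clusters V genes into subgroups at a nucleotide-identity threshold with a
    phylogenetic override, builds neighbor-joining trees with bootstrap support,
    and emits IMGT-style names, GFF3/BED annotations and per-locus reports.
    Includes a synthetic-locus generator that plants genes with full ground
    truth so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stringr,
    tibble,
    tidyr,
    stats,
    utils
Suggests:
    igraph,
    knitr,
    optparse,
    rmarkdown,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
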