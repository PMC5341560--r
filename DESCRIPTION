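Package: isomapr
Title: Hybrid Long-Read and Short-Read Transcriptome Reconciliation
    Without a Reference Genome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconciles error-corrected long-read transcript sequences
    (e.g. PacBio Iso-Seq) with de novo short-read assemblies (e.g. Trinity
    contigs) for organisms lacking a reference genome.  Removes redundant
    long reads by a containment rule, groups reads and contigs into genes,
    selects the per-gene longest qualifying contig as a splice-detection
    reference, catalogues alternative splicing as long alignment gaps,
    estimates isoform abundance from short-read compatibility by
    expectation-maximisation, and screens differential isoform expression
    with fold-change and false-discovery cutoffs.  Includes a
    ground-truthed synthetic transcriptome generator, a block-structured
    affine-gap aligner, and PSL/PAF alignment parsers, so every pipeline
    stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
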