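Package: rpkum
Title: Mappability-Aware Pseudogene Expression Quantification and ceRNA Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies pseudogene expression from short-read RNA-seq in a way
    that is robust to unique misalignment between highly similar loci. Computes
    a discrete, mismatch-tolerant (epsilon-safety-margin) transcriptome
    mappability track at read length k, extended across splice junctions via
    synthetic regions; filters alignments to uniquely mappable reads; and
    reports expression as Reads Per Kilobase of Uniquely mappable transcript
    per Million reads (RPKUM). Includes a downstream competing endogenous RNA
    (ceRNA) screen: pseudo-3' UTR annotation by local alignment to the parent
    gene's 3' UTR, canonical miRNA seed-site matching, and correlation analysis
    with permutation-based null models. Ships a synthetic-data generator for
    genomes with processed, duplicated and unitary pseudogenes, subject-genome
    SNPs, error-bearing reads, and expression matrices with planted ceRNA
    structure.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
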