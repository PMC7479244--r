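Package: rrbsmeth
Title: Differential DNA Methylation Analysis for Reduced Representation
    Bisulfite Sequencing with a Synthetic Data Generator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for differential DNA methylation analysis of
    reduced representation bisulfite sequencing (RRBS) count data: coverage
    filtering and quality-control summaries, correlation-based hierarchical
    clustering of samples, differentially methylated cytosine (DMC) calling
    with a dispersion-shrunk beta-binomial Wald test and covariate-weighted
    false discovery rate adjustment, merging of DMCs into differentially
    methylated regions (DMRs), genomic-context annotation (gene features,
    CpG islands/shores/shelves, repeats), and pyrosequencing-concordance
    statistics with stratified permutation tests.  A first-class synthetic
    RRBS generator performs an in-silico MspI reduced-representation digest
    of a toy genome and simulates bimodal per-CpG bisulfite count data with
    planted group effects, emitting the standard file formats the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    ape,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
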