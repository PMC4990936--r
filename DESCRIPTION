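Package: stimulon
Title: Flavonoid Stimulon Analysis from Regulator-Knockout RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting a bacterial flavonoid stimulon from RNA-seq
    count data collected in a wild-type strain and regulator knockouts.
    Implements library normalization and an exact conditioned-binomial test
    for differential expression against a no-inducer baseline, degenerate
    promoter-box scanning (nod boxes, tts boxes, SyrM boxes) with mismatch
    budgets and mandatory core motifs, epistasis rules that call each
    promoter box functional or not from the induction pattern across
    genetic backgrounds, operon-aware assembly of the inducer-affected
    gene set, assignment of responsive genes to regulon groups with
    regulator-dependence flags, delta-delta-Ct qPCR validation, and a
    negative-binomial count simulator that plants the same regulatory
    structure so every stage can be verified against a known truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    BiocGenerics,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
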