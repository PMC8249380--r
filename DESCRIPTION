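Package: promdiv
Title: Comparative Promoterome Analysis of CAGE Transcription Start Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of transcription start site (TSS)
    usage from CAGE data. Extracts and filters per-nucleotide CAGE tag
    starting sites (CTSSs) from alignments, normalizes tag counts to a common
    power-law reference distribution expressed in tags per million, calls
    distance-based tag clusters and cross-sample consensus clusters, annotates
    them against a gene model, and computes a battery of between-group
    statistics: divergent-cluster profiles, dominant-TSS translocation
    distances, promoter shifting scores with a TPM-weighted Kolmogorov-Smirnov
    test, Shannon diversity of TSS usage, crossover TSS switching between
    developmental stages via an interaction linear model, and an FST-based
    selection scan with hypergeometric minor-allele-frequency bin enrichment.
    Includes synthetic-data generators with known ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
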