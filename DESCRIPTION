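Package: osmoseq
Title: Noise-Floored Differential Expression Analysis for Bulk RNA-Seq and
    Microarray Studies of Osmotic Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible implementation of a classical bulk expression
    analysis workflow for two-class designs with few biological replicates,
    as used in transcriptome studies of the hypothalamic supraoptic nucleus
    under chronic salt loading. Covers paired-end FASTQ read cleaning
    (adapter clipping, fixed and quality-based end trimming, ambiguity and
    length pair filters), RPKM computation with pedestalled log2 transform,
    quantile normalization, microarray batch baseline subtraction against a
    common reference library, LOWESS-based detection of the expression level
    at which the coefficient of variation decouples from the mean (the
    "confidence criterion"), noise-biased gene removal and flooring,
    gene-by-gene Welch t-tests with Benjamini-Hochberg correction and signed
    linear fold-change selection, QC projections (Tukey summaries, covariance
    PCA, correlation heat-map data), cross-platform gene-symbol
    intersections and fold-change concordance, Fisher exact gene-set
    enrichment, and delta-delta-Ct qPCR validation. Includes synthetic-data
    generators with planted ground truth (differential genes, CV elbow,
    batch offsets, qPCR fold changes) so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    rtracklayer
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
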