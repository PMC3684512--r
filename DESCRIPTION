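Package: tfrank
Title: Ranking Transcription-Factor Bound Genes by Truncated Absolute
    Correlation Against an Expression Compendium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prioritizes transcription-factor (TF) bound genes from
    ChIP-seq/ChIP-chip experiments by fusing the peak-based binding rank
    with a truncated absolute correlation computed between the TF and each
    bound gene across a large standardized gene-expression compendium.
    Includes tools to build and standardize compendia from normalized
    probeset- or gene-level matrices, assign ranked peaks to genes through
    strand-aware transcription-start-site windows, evaluate rankings with
    positive-predictive-value curves and normalized AUC against a
    gold-standard gene set, and generate seeded synthetic benchmarks with
    planted context-dependent regulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    graphics,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
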