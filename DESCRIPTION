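Package: clonescreen
Title: Analysis Pipeline for an In Vivo Tumor-Progression RNAi Screen
Version: 0.1.0
Authors@R:
    person("Maintainer", "Clonescreen", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable analysis stages for a clonal tumor-progression RNAi
    screen scored across ordinal phenotype categories: score-database
    validation and aggregation, blinded-scorer and RNAi-line-pair quality
    control, interquartile-range hit calling, model-based and consensus
    clustering of phenotype profiles, hypergeometric annotation enrichment,
    invasion-suppressor network construction with molecular-complex
    (MCODE-style) detection, single-cell invasion track metrics, and a
    fold-change/significance differential-expression stage. Every input can
    be simulated by seeded generators with known ground truth, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
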