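Package: regulonet
Title: Transcription-Factor Regulon Enrichment Networks from RNA-seq Contrasts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers transcription-factor activity from bulk RNA-seq contrasts
    by scoring each factor's regulon (its known target set in a directed
    interaction database) for enrichment or depletion among differentially
    expressed genes, using hypergeometric tail probabilities with
    Benjamini-Hochberg false-discovery control and a signed log-FDR activity
    score. Includes median-of-ratios normalisation, per-gene Welch tests on
    log-transformed counts, data-driven regulon selection, upstream-regulator
    set algebra, GO cellular-component category graphs with shared-gene edge
    weights, marker-panel row z-score matrices, Cytoscape-ready GraphML/SIF
    export, and a negative-binomial synthetic-data generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
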