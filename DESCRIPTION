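Package: gzexit
Title: Quantification of Germinal-Zone Exit, Zeb1 Binding-Site Association,
    and Supporting qPCR and Labeling-Index Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reusable, tested implementations of the quantitative procedures
    used to study transcription-factor control of germinal-zone exit in the
    developing cerebellum: per-cell migration-distance measurement against a
    pial-surface polyline with histogram summaries and a chi-square/t-test
    rescue classification; ChIP-peak-to-nearest-TSS assignment with a
    size-matched gene-set resampling null and a cumulative-fraction enrichment
    map; E-box motif density profiles around peak summits; deregulated-gene
    selection with Benjamini-Hochberg FDR; delta-delta-Ct relative
    quantification against a reference gene; ChIP-qPCR fold enrichment; and
    marker labeling indices with proportion tests. A synthetic-data module
    generates every input the pipeline consumes, parameterized by the
    per-condition means, standard deviations and cell counts printed in the
    study's figures, so every stage is testable without the deposited arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
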