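Package: phenogrid
Title: Colony-Array Phenomics: Grid Normalization, Hit Calling and
    Phenotype Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for colony-based high-throughput phenomics
    screens of fission-yeast mutant libraries. Provides reference-grid
    spatial normalization of 384-colony plates with row/column median
    correction and quality control, replicate summarization with Welch
    tests and per-condition Benjamini-Hochberg adjustment for growth and
    viability hit calling, phenotype-profile z-scoring, condition
    aggregation, ternary discretization, hierarchical clustering and
    Pearson correlation networks, plus cell-size/cell-cycle statistics
    from high-throughput microscopy and meiotic differentiation
    measures. Includes a seeded synthetic-data generator emulating plate
    spatial gradients, batch effects and replicate structure with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
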