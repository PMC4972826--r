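Package: colonynet
Title: Dominance Hierarchies and Social Network Communities in
    Group-Housed Mouse Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analyse agonistic-interaction and spatial-census records from
    large group-housed rodent colonies.  Builds frequency and binarized
    win/loss sociomatrices, computes dominance-hierarchy statistics
    (directional consistency, de Vries' modified h', David's scores and
    hierarchy steepness, triangle transitivity, I&SI ranking) with
    Monte-Carlo randomization tests, directed-network structure and
    position metrics with null-model significance, Girvan-Newman
    community detection with bootstrap comembership consensus,
    half-weight association indices with Mantel and within/between
    community tests, and spatial-usage analyses (Shannon evenness,
    non-metric multidimensional scaling).  A synthetic colony generator
    with planted hierarchy and community structure supports testing and
    calibration of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
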