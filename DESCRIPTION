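Package: stresscreen
Title: Stress-Tolerance Variety Screening and Weighted Co-Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for screening crop varieties for
    abiotic-stress tolerance and linking physiology to gene expression.
    Implements grey relational analysis (Deng type) with CRITIC objective
    weighting and ranking-agreement gating, log-logistic LC50 dose-response
    fitting by binomial maximum likelihood with exact one-dimensional
    k-means tolerance classification, a weighted gene co-expression network
    stage (soft-threshold scan, adjacency, topological overlap, module
    detection, module eigengenes, module-trait correlation), degree-based
    intramodular hub-gene selection, and Mantel-test linkage of hub
    expression to physiological indicators. Seeded simulators generate
    indicator panels, binomial mortality tables and planted-module
    expression matrices so the whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
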