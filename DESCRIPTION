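Package: hypermem
Title: Hypergraph Recognition Memory for Lifelong Learning on Categorical
    Event Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An incremental (lifelong-learning) model of recognition memory
    for multivariate categorical event streams. Events are subsampled into
    position-anchored hyperedges that accumulate into a layered hypernetwork
    with half-sigmoid link weights; familiarity (old/new) judgment asks
    whether a probe activates a fully linked closed route through the store,
    a weight-sum similarity supports signal-detection (ROC) analysis, and
    pattern completion reconstructs full instances from partial probes.
    Includes a nonstationary synthetic stream generator, experiment
    harnesses for edge-configuration sweeps, temporal sections, study
    duration, and online versus offline expectation, plus TSV/JSON
    serialization and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
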