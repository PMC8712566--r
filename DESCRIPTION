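Package: choqfuse
Title: Classifier Fusion with Generalized Choquet Integrals for EEG Network Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fusing the probabilistic outputs of classifier
    ensembles with Sugeno lambda-fuzzy measures and generalized Choquet
    (pre-aggregation) integrals parameterized by triangular-norm families,
    together with the upstream feature pipeline used in resting-state EEG
    studies of schizophrenia: band-wise directed connectivity from linear
    Granger causality on vector-autoregressive models, maximum spanning
    trees of the connectivity network, and five global tree metrics per
    frequency band. Includes synthetic generators for VAR-coupled
    multichannel signals, tree-metric feature tables, and correlated
    classifier-score ensembles, so the full fusion experiment can be run
    end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
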