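Package: styledyn
Title: Dynamic Dirichlet Mixture Modelling of Creation-Style Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying, clustering and forecasting populations of
    discrete probability vectors ("creation styles"), such as pitch and rhythm
    bigram statistics of melodies or token unigram statistics. Implements
    featurization of symbolic sequences, EM clustering of count vectors,
    time-resolved Dirichlet mixture estimation with exponential-decay
    smoothing, replicator-dynamics forecasting of mixture weights,
    concentrations and mean distributions via local-linear-trend state-space
    models, backtesting metrics, and a generative simulator of time-evolving
    Dirichlet mixtures and agent-based cultural transmission.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
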