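Package: forestdem
Title: Spatial Econometrics of Tropical Forest Cover Across Jurisdictional Levels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for multi-level spatial econometric
    analysis of forest cover in nested jurisdictional units. Builds the
    logistic-linearized forest-cover response and log-standardized driver
    variables from per-unit attributes, constructs sphere-of-influence (SOI)
    spatial weights, screens collinearity, selects regressors by backwards
    BIC, tests residual spatial dependence (Moran's I with Cliff-Ord moments,
    Lagrange multiplier diagnostics), estimates SLX, spatial error (SEM) and
    spatial Durbin error (SDEM) models by maximum likelihood, decomposes
    direct/indirect/total impacts, and selects among the nested model family
    by likelihood-ratio tests. Ships a synthetic-data generator for nested
    macro/meso/micro lattices with known spatial structure so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
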