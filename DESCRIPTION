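Package: aqpd
Title: Phase-Based Variance Decomposition and Health Impact Assessment for
    Air-Quality Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to separate meteorological from intervention-phase drivers
    of urban air-pollutant variability and to translate fine-particle (PM2.5)
    changes into cardiovascular mortality burden. Provides a seeded synthetic
    generator for hourly pollutant and meteorology series with phase-specific
    mean shifts, completeness-based daily aggregation, phase-stratified
    descriptive statistics and nonparametric contrasts, nested linear models
    with incremental R-squared variance decomposition and
    heteroscedasticity-robust inference, random-forest permutation importance
    as a nonparametric cross-check, and a log-linear concentration-response
    health impact assessment with Monte Carlo uncertainty propagation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    yaml,
    zoo,
    sandwich,
    randomForest,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
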