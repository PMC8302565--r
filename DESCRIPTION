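Package: rivalr
Title: Analysis of Perceptual Rivalry Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing perceptual bistability (rivalry)
    experiments in which observers continuously report which of two
    competing percepts dominates. Parses keypress report traces into
    dominance phases, applies trial-exclusion and rebalancing rules,
    computes Levelt-proposition-II condition curves and the
    equidominance point, runs within-subject ANOVA with Mauchly
    sphericity tests and Greenhouse-Geisser correction, fits gamma and
    log-normal phase-duration distributions with Kolmogorov-Smirnov
    goodness of fit, assesses the scaling property of normalized
    moments, and measures lag-1/lag-2 correlations between successive
    phase durations by pooled and single-trial methods. A synthetic
    experiment generator with a latent autoregressive Gaussian copula
    makes every stage testable without experimental data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    stats,
    generics,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    withr
Config/testthat/edition: 3
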