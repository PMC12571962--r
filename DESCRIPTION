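Package: bayesbold
Title: Bayesian Parcel-Wise Analysis of Emotional Task fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis of block-design emotional-picture fMRI
    experiments at the brain-parcel level. Provides first-level general linear
    models with canonical double-gamma hemodynamic convolution, parametric
    valence/arousal modulation, discrete-cosine high-pass filtering and AR(1)
    restricted-maximum-likelihood prewhitening; psychophysiological-interaction
    (PPI) connectivity with ridge-regularised hemodynamic deconvolution; and
    Bayesian group inference: Jeffreys-Zellner-Siow t-test Bayes factors,
    Gunel-Dickey contingency-table tests, Bayesian correlation, inclusion
    Bayes factors for repeated-measures ANCOVA via model averaging, and a
    dual-threshold region-selection rule separating group differences from
    group similarities. A synthetic-cohort generator with planted amplitude,
    rating-slope and connectivity effects makes every stage testable without
    access to scanner data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
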