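Package: graftann
Title: Kidney Graft Survival Prediction with a Buffalo-Optimized Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting five-year kidney graft
    survival from donor and recipient covariates. Implements the African
    Buffalo Optimization (ABO) metaheuristic as a general continuous
    minimizer, a hybrid feature-selection scheme (information-gain filter,
    ABO wrapper search, accuracy-driven backward elimination), and a
    single-hidden-layer perceptron whose weights are trained by ABO rather
    than by gradient descent. Includes a synthetic transplant-cohort
    generator with planted ground truth, preprocessing with
    temporal-neighbour mean imputation and five-year censoring label
    derivation, confusion-matrix performance metrics, and a reproducible
    command-line pipeline.
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
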