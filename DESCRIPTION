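Package: herbenergy
Title: Energy Evaluation of Alpine Herbage from Sheep Digestibility Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating the digestible (DE) and metabolizable
    (ME) energy concentration of fresh herbage from sheep digestibility
    trial data. Provides a machine-readable registry of published linear
    prediction equations for DE, ME, DE/GE and ME/GE with unit-aware
    evaluation; an equation-development engine based on linear mixed
    models fitted by residual maximum likelihood (REML) with nested
    deviance tests for trial-structure random effects; an internal and
    external validation harness built on the mean-square-prediction-error
    (MSPE) technique and Lin's concordance correlation; and a synthetic
    generator of seasonal digestibility-trial datasets with an internally
    consistent gross/digestible/metabolizable energy balance for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
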