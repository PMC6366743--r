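Package: riskupdate
Title: External Validation and Updating of Clinical Risk Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to externally validate published logistic risk prediction
    models and to update them for a new population: intercept adjustment,
    logistic calibration, model revision via likelihood-ratio screening of
    coefficient deviations, complete re-estimation, extension with new
    predictors, and de novo backward-stepwise development, all with bootstrap
    parameterwise shrinkage. Ships a declarative registry of five published
    prevalent-diabetes risk models (Cambridge, Kuwaiti, Omani, Rotterdam,
    simplified Finnish), a synthetic screening-cohort generator for fully
    reproducible end-to-end experiments, and discrimination and calibration
    metrics: C-statistic with DeLong intervals, expected/observed event
    ratio with Poisson intervals, Brier score, Yates slope and calibration
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
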