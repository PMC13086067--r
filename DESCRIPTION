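Package: attrnoise
Title: Attribute-Noise Sensitivity Simulation for Binary Clinical Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for studying how attribute (feature) noise in
    binary electronic-health-record style data degrades classifier
    discrimination and the stability of per-feature impact scores. Generates
    balanced case-control cohorts with binary comorbidity-block features and
    planted log-odds effects, injects noise under three mechanisms (completely
    at random, at random, and not at random) at exact cell budgets, fits
    logistic regression, linear support vector machine and gradient boosting
    models, and summarises the resulting change in AUC, accuracy, impact
    scores and their dispersion, including a repeated-measures ANOVA across
    noise proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    data.table,
    kernlab,
    xgboost,
    pROC,
    jsonlite,
    yaml,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
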