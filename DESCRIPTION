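Package: miascore
Title: Rupture-Source Prediction Score for Multiple Intracranial Aneurysms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derivation and application of an aneurysm-specific prediction
    score that identifies the ruptured aneurysm in subarachnoid-hemorrhage
    patients harboring multiple intracranial aneurysms. Implements
    component-wise gradient boosting for the binomial model with logistic
    link, linear base learners and a ridge-penalized patient random
    intercept; single logistic-regression imputation of missing aneurysm
    shape; patient-level ten-fold cross-validation with nested tuning of the
    stopping iteration, stratified correct-classification rates, rank-based
    AUC and calibration binning; the published closed-form score with
    within-patient argmax ranking; and a synthetic cohort generator with a
    configurable ground-truth rupture model for parameter-recovery and null
    experiments. Ships the published 34-patient prospective validation
    cohort as a plain-text fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
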