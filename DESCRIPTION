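Package: breathvoc
Title: Electronic-Nose Breath VOC Tensor Classification Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for classifying exhaled-breath volatile organic compound
    (VOC) patterns measured by a temperature-cycled metal-oxide electronic
    nose. Each measurement is a 32 (temperature step) x 36 (cycle) x 3
    (sensor) conductivity tensor; cohorts are compressed by PARAFAC or
    Tucker3 tensor decomposition under an ensemble of scaling designs, scored
    by a small feed-forward neural network with leave-one-out
    cross-validation, filtered by per-protocol exclusion of chronically
    misclassified patients, and summarised with threshold-optimised
    diagnostic metrics (sensitivity, specificity, accuracy, Matthews
    correlation, ROC-AUC with DeLong intervals). A synthetic breath-cohort
    generator with class, smoking, fasting and device effects makes the full
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
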