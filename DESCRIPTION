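Package: svrs
Title: Stable Variable Ranking and Selection for Severely Imbalanced Binary Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Variable ranking and selection for regularized logistic regression
    under severe class imbalance. Repeated response-based downsampling of the
    majority class yields an ensemble of balanced datasets; cross-validated
    Lasso, adaptive Lasso or ridge logistic models are fitted to each, and
    standardized-coefficient ranks are aggregated into stable per-covariate
    rank scores that are thresholded by single mean-changepoint detection.
    Includes a synthetic-data module with NORTA-based correlated binary and
    nominal covariates for simulation studies of selection performance
    (TPR/FPR/FDR/AUC) at imbalance ratios from 1:50 to 1:1000.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    data.table,
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
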