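Package: rxremit
Title: Drug-Specific Prediction of Antidepressant Remission from Genetic
    and Clinical Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derivation and external validation of antidepressant-specific
    models of depression remission in randomized two-arm pharmacogenetic
    cohorts. Implements correlation-adjusted t-score (CAT) feature ranking
    with local false discovery rates, stability selection over repeated
    cross-validation, elastic-net logistic regression with repeated
    cross-validated hyperparameter tuning, and validation metrics (AUC with
    DeLong confidence intervals, sensitivity, specificity, Nagelkerke
    pseudo-R2), together with genotype quality control, bagged-tree
    imputation of clinical predictors, cross-drug specificity analysis, and
    a synthetic cohort generator with known ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    rpart,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
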