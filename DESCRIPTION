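Package: hdboost
Title: Boosting Algorithms for High-Dimensional Two-Class Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Boosting ensembles of depth-capped classification and regression
    trees for two-class prediction when the number of variables greatly
    exceeds the number of samples, as in gene-expression studies. Implements
    AdaBoost.M1 and a variant that drives the weight updates with an
    internally cross-validated per-sample error estimate instead of the
    resubstitution error, gradient boosting under the exponential loss,
    stochastic gradient boosting with subsampling and shrinkage, and
    LogitBoost. Includes seeded simulation designs (block-correlated
    multivariate normal data with differentially expressed variables,
    independent null data, variance-shift separation), performance measures
    (class-specific accuracies, AUC, g-means), cross-validated and
    out-of-bag selection of the number of boosting iterations, classifier
    ranking with signed-rank tests, and a replicated experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
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
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
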