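Package: featrepl
Title: Feature Replacement and Imputation for Ordinal Behavioral Rating
    Scoresheets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Missing-value management for ordinal behavioral rating
    scoresheets such as those produced when non-expert raters score short
    videos of children for autism screening. Implements listwise deletion,
    univariate (mean/median/mode) and iterative multivariate round-robin
    imputation (ridge, decision-tree and Gaussian-mixture estimators), and
    general and dynamic feature replacement, which fill a missing model
    feature by copying the value of its closest substitute feature from an
    expanded feature set (scored by Spearman correlation, Euclidean
    proximity or mutual information). Includes the two downstream
    classifiers (L2-penalised logistic regression and a boosted alternating
    decision tree), an evaluation harness with stratified cross-validated
    grid search optimizing unweighted average recall, mode aggregation of
    repeated ratings, Welch t-tests with Bonferroni correction against a
    listwise-deletion baseline, and a synthetic scoresheet simulator with
    configurable MCAR/MAR/MNAR missingness mechanisms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    mclust,
    rpart,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
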