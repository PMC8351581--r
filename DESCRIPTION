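Package: pmpred
Title: Sequence-Based Prediction of Plant Moonlighting Proteins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts plant moonlighting proteins (single polypeptides
    performing two or more unrelated functions) from amino-acid sequence
    alone. Implements 16 classical sequence descriptor families
    (tripeptide composition, k-spaced pair compositions, conjoint triads,
    dipeptide deviation from expectation, composition/transition/
    distribution, autocorrelations, sequence-order and pseudo amino-acid
    compositions), an information-gain feature filter with a top-80%
    fallback, min-max normalization, PCA reduction to 10 components, and
    grid-searched training of five classifiers (XGBoost, SVM, random
    forest, decision tree, k-nearest neighbours) under stratified 5-fold
    cross-validation with AUPRC as the primary model-selection metric.
    Includes greedy sequence-redundancy reduction in the style of CD-HIT,
    a species-wise train/test splitter, a calibrated synthetic sequence
    generator for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    class,
    e1071,
    jsonlite,
    methods,
    randomForest,
    rpart,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
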