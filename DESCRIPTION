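Package: hepascreen
Title: Combined-Classifier QSAR Models and Ingredient Screening for
    Herb-Induced Liver Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building stacked (combined-classifier) QSAR models of
    drug-induced liver injury and for screening hepatotoxic ingredients in
    multi-ingredient herbal medicines. Implements a three-stage feature
    selection cascade (Boruta all-relevant selection, pairwise correlation
    pruning, recursive feature elimination), a registry of eight base
    learning algorithms with grid-based hyperparameter tuning, a Naive Bayes
    meta-classifier over the base learners' binary predictions, stratified
    cross-validation with Y-randomization, and a three-channel screening
    procedure that integrates classifier predictions, a herb-induced liver
    injury reference list, and a herb-ingredient bipartite network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    caret,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ChemmineR,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
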