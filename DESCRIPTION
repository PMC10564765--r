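Package: mstabu
Title: Multistart Tabu Search Feature Selection for Clinical Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Wrapper feature selection for binary diagnosis datasets using a
    multistart metaheuristic: greedy randomized construction (GRASP-style
    restricted candidate list) followed by tabu search over add/remove/swap
    moves, maximizing a composite objective that balances resubstitution
    accuracy against subset size. Includes the three classifiers the wrapper
    evaluates subsets with (linear discriminant analysis, logistic regression,
    linear support vector machine) behind a common fit/predict contract, a
    stratified k-fold cross-validation harness with confusion-matrix metrics
    (accuracy, balanced-accuracy AUC, geometric mean, F1) and paired t-tests,
    a synthetic benchmark generator with known informative features, and an
    exhaustive-enumeration oracle for small feature universes.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml,
    withr,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
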