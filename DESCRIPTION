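Package: synfold
Title: Synthetic Ground-Truth Generation and Evaluation for RNA Secondary
    Structure Machine Learning
Version: 0.1.0
Authors@R:
    person("synfold", "maintainers", email = "synfold@example.org",
           role = c("aut", "cre"))
Description: Generates controlled synthetic RNA secondary-structure datasets
    from a built-in nearest-neighbor minimum-free-energy folding engine
    (Turner-2004 core parameter set), trains small reference neural
    predictors (sliding-window feed-forward and convolutional paired/unpaired
    classifiers, a bidirectional LSTM sequence labeler, and base-pair-matrix
    convolutional models), and quantifies what such models do and do not
    learn: loop-decomposition statistics, base-pair-type frequencies,
    length-distribution bias, quadratic base-pair scaling, and
    structure-bias overfitting diagnosed with inverse folding and
    dinucleotide shuffling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
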