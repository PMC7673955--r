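Package: succpred
Title: Lysine Succinylation Site Prediction with Incremental Feature
    Selection and Bayesian-Optimized Gradient Boosting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for predicting lysine succinylation sites from protein
    sequences. Extracts fixed-length lysine-centered peptide windows, encodes
    them with four sequence featurizations (composition of k-spaced amino acid
    pairs, per-residue intrinsic disorder scores, Type-1 pseudo amino acid
    composition, and position-specific scoring matrix features) fused into a
    2501-dimensional vector, ranks features by gradient-boosting gain
    importance, selects an optimal subset by incremental feature selection
    under cross-validation, evaluates models with confusion-matrix metrics
    (accuracy, recall, precision, MCC, F-measure), and tunes classifier
    hyperparameters by Gaussian-process Bayesian optimization with the
    expected-improvement acquisition or by grid search. Includes parsers for
    PSI-BLAST ASCII PSSM profiles and per-residue disorder tables, and a
    synthetic-data generator with controllable class signal for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    lhs,
    stats,
    utils,
    withr,
    xgboost
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
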