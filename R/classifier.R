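## Pluggable gradient-boosted classifier. The boosted-tree learner itself is
## an external dependency, not part of this package's contribution; xgboost
## provides it here. gbdt_config() speaks the hyperparameter vocabulary of
## the histogram-based GBDT family (learning_rate, num_leaves, max_bin,
## reg_alpha, boosting_type, n_estimators) and is mapped onto the backend.

#' Gradient-boosted classifier configuration
#'
#' Parameters are named as in the histogram-GBDT family. `NULL` means "use
#' the backend library default". Mapping onto the xgboost backend:
#' `learning_rate` -> `eta`, `n_estimators` -> boosting rounds,
#' `reg_alpha` -> `alpha`, `max_bin` -> `max_bin` (histogram bins),
#' `num_leaves` -> `max_leaves` with leaf-wise (`lossguide`) growth.
#' `boosting_type` maps `"gbdt"` to plain gradient boosting, `"dart"` to
#' the dart booster, `"rf"` to random-forest-style per-round subsampling
#' (`subsample` 0.632, `colsample_bynode` 0.8); `"goss"` (gradient one-side
#' sampling) has no xgboost equivalent and falls back to plain boosting —
#' it is kept in the vocabulary so tuning over the full search space
#' remains expressible.
#'
#' @param n_estimators Number of boosting rounds (default 100).
#' @param learning_rate Shrinkage step; NULL = backend default.
#' @param max_depth Maximum tree depth; NULL = backend default.
#' @param num_leaves Maximum leaves per tree (leaf-wise growth); values
#'   below 2 are clamped to 2 with a warning. NULL = depth-wise growth.
#' @param max_bin Histogram bin count; NULL = backend default.
#' @param reg_alpha L1 regularization; NULL = backend default.
#' @param boosting_type One of "gbdt", "goss", "rf", "dart".
#' @param seed Integer seed passed to the backend (default 0).
#' @param nthread Threads (default 1, for reproducibility).
#' @return A list of class `gbdt_config`.
#' @export
gbdt_config <- function(n_estimators = 100L, learning_rate = NULL,
                        max_depth = NULL, num_leaves = NULL, max_bin = NULL,
                        reg_alpha = NULL,
                        boosting_type = c("gbdt", "goss", "rf", "dart"),
                        seed = 0L, nthread = 1L) {
  boosting_type <- match.arg(boosting_type)
  if (!is.null(num_leaves) && num_leaves < 2L) {
    warning("num_leaves < 2 is not a meaningful tree; clamping to 2")
    num_leaves <- 2L
  }
  structure(list(n_estimators = as.integer(n_estimators),
                 learning_rate = learning_rate, max_depth = max_depth,
                 num_leaves = num_leaves, max_bin = max_bin,
                 reg_alpha = reg_alpha, boosting_type = boosting_type,
                 seed = as.integer(seed), nthread = as.integer(nthread)),
            class = "gbdt_config")
}

.xgb_params <- function(cfg) {
  p <- list(objective = "binary:logistic", nthread = cfg$nthread,
            tree_method = "hist", seed = cfg$seed)
  if (!is.null(cfg$learning_rate)) p$eta <- cfg$learning_rate
  if (!is.null(cfg$max_depth)) p$max_depth <- cfg$max_depth
  if (!is.null(cfg$max_bin)) p$max_bin <- as.integer(cfg$max_bin)
  if (!is.null(cfg$reg_alpha)) p$alpha <- cfg$reg_alpha
  if (!is.null(cfg$num_leaves)) {
    p$grow_policy <- "lossguide"
    p$max_leaves <- as.integer(cfg$num_leaves)
    if (is.null(cfg$max_depth)) p$max_depth <- 0L  # leaf-count limited only
  }
  if (cfg$boosting_type == "dart") p$booster <- "dart"
  if (cfg$boosting_type == "rf") {
    p$subsample <- 0.632
    p$colsample_bynode <- 0.8
  }
  p
}

#' Turn a configuration into a fit/predict classifier interface
#'
#' A classifier is a list with `fit(X, y01) -> model` and
#' `predict(model, X) -> P(positive)`. [gbdt_config()] objects are wrapped
#' around the xgboost backend; a list already carrying `fit` and `predict`
#' is passed through, which is how alternative learners plug in.
#'
#' @param classifier A `gbdt_config` or a list with `fit` and `predict`.
#' @return A classifier interface list.
#' @export
as_classifier <- function(classifier) {
  if (is.list(classifier) && !is.null(classifier$fit) &&
      !is.null(classifier$predict)) return(classifier)
  if (!inherits(classifier, "gbdt_config"))
    stop("classifier must be a gbdt_config or a list with fit/predict")
  cfg <- classifier
  list(
    fit = function(X, y01) {
      dm <- xgboost::xgb.DMatrix(as.matrix(X), label = y01)
      # the R backend draws subsampling randomness from R's RNG
      withr::with_seed(cfg$seed,
        xgboost::xgb.train(params = .xgb_params(cfg), data = dm,
                           nrounds = cfg$n_estimators, verbose = 0))
    },
    predict = function(model, X) {
      stats::predict(model, xgboost::xgb.DMatrix(as.matrix(X)))
    })
}

#' Fit the classifier on a full training set
#'
#' @param X Feature matrix.
#' @param y Labels (factor with level "positive", or 0/1).
#' @param classifier Configuration or interface (see [as_classifier()]).
#' @return A fitted model wrapped with its feature names, class
#'   `succ_model`.
#' @export
train_classifier <- function(X, y, classifier = gbdt_config()) {
  clf <- as_classifier(classifier)
  structure(list(model = clf$fit(as.matrix(X), .as01(y)),
                 predict_fun = clf$predict,
                 features = colnames(X)),
            class = "succ_model")
}

#' Predict modification scores for encoded windows
#'
#' @param object A `succ_model` from [train_classifier()].
#' @param X Feature matrix (columns may be a superset of the training
#'   features; they are aligned by name when named).
#' @param threshold Score cutoff for a positive call (default 0.5).
#' @param ... Unused.
#' @return Data frame with `score` and `call` (factor
#'   negative/positive).
#' @export
predict.succ_model <- function(object, X, threshold = 0.5, ...) {
  X <- as.matrix(X)
  if (!is.null(object$features) && !is.null(colnames(X)))
    X <- X[, object$features, drop = FALSE]
  s <- object$predict_fun(object$model, X)
  data.frame(score = s,
             call = factor(ifelse(s >= threshold, "positive", "negative"),
                           levels = c("negative", "positive")))
}
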