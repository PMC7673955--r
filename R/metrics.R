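## model_eval: confusion-matrix metrics, stratified k-fold cross-validation
## and the repeated-CV stability harness.

#' Confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts; at least one must be
#'   positive.
#' @return A list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || anyNA(v)) stop("confusion counts must be non-negative")
  if (sum(v) < 1) stop("confusion table is empty (all counts zero)")
  structure(as.list(v), class = "confusion_counts")
}

#' Confusion counts from labels and predictions
#'
#' @param truth Factor or 0/1 vector of true labels ("positive" = 1).
#' @param predicted Factor or 0/1 vector of predicted labels.
#' @return A [confusion_counts()] object.
#' @export
confusion_from_labels <- function(truth, predicted) {
  t1 <- .as01(truth); p1 <- .as01(predicted)
  confusion_counts(tp = sum(t1 == 1 & p1 == 1),
                   fp = sum(t1 == 0 & p1 == 1),
                   tn = sum(t1 == 0 & p1 == 0),
                   fn = sum(t1 == 1 & p1 == 0))
}

.as01 <- function(y) {
  if (is.factor(y)) as.integer(y == "positive")
  else if (is.character(y)) as.integer(y == "positive")
  else as.integer(y != 0)
}

#' Five classification metrics from a confusion table
#'
#' Computes accuracy, recall (sensitivity), precision, the Matthews
#' correlation coefficient and the F-measure:
#'
#'   accuracy  = (TP + TN) / (TP + FP + TN + FN)
#'   recall    = TP / (TP + FN)
#'   precision = TP / (TP + FP)
#'   MCC       = (TP*TN - FP*FN) /
#'               sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))
#'   F-measure = 2 * precision * recall / (precision + recall)
#'
#' Zero-denominator conventions (fixed and unit-tested): recall, precision
#' and F-measure are 0 when their denominator is 0; MCC is 0 when any of
#' the four marginals is empty.
#'
#' @param counts A [confusion_counts()] object.
#' @return A list of class `metrics_bundle` with fields `accuracy`,
#'   `recall`, `precision`, `mcc`, `f_measure`.
#' @export
#' @examples
#' compute_metrics(confusion_counts(40, 10, 30, 20))
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  acc <- (tp + tn) / n
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  pre <- if (tp + fp > 0) tp / (tp + fp) else 0
  fme <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(marg == 0)) 0 else
    (tp * tn - fp * fn) / sqrt(prod(marg))
  structure(list(accuracy = acc, recall = rec, precision = pre,
                 mcc = mcc, f_measure = fme),
            class = "metrics_bundle")
}

#' @export
print.metrics_bundle <- function(x, ...) {
  cat(sprintf("ACC %.4f  Recall %.4f  Precision %.4f  MCC %.4f  F-measure %.4f\n",
              x$accuracy, x$recall, x$precision, x$mcc, x$f_measure))
  invisible(x)
}

## Stratified fold assignment: within each class, indices are shuffled with
## the given seed and dealt round-robin into k folds. withr::with_seed keeps
## this deterministic without disturbing the caller's RNG state.
stratified_folds <- function(y, k, seed) {
  y01 <- .as01(y)
  folds <- integer(length(y01))
  withr::with_seed(seed, {
    for (cls in unique(y01)) {
      idx <- which(y01 == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified k-fold cross-validation
#'
#' Splits samples into k stratified folds (seeded shuffling within each
#' class), trains the classifier on each training split and predicts the
#' held-out fold. Metrics are computed on the pooled out-of-fold
#' predictions — one confusion table over all folds, which keeps MCC
#' well-defined with small folds — and also per fold, with the per-fold
#' macro-average returned for comparison.
#'
#' @param X Numeric feature matrix.
#' @param y Labels (factor with level "positive", or 0/1).
#' @param classifier A [gbdt_config()] or any object accepted by
#'   [as_classifier()].
#' @param k Number of folds (default 10); must be at least 2 and at most
#'   the smaller class count.
#' @param seed Integer seed controlling the fold assignment.
#' @return List of class `cv_result`: `pooled` (a `metrics_bundle`),
#'   `per_fold` (list of bundles), `fold_mean` (macro-averaged bundle),
#'   `folds` (fold assignment), `predictions` (out-of-fold scores).
#' @export
cross_validate <- function(X, y, classifier = gbdt_config(), k = 10L,
                           seed = 0L) {
  if (k < 2L) stop("k must be at least 2")
  y01 <- .as01(y)
  if (length(unique(y01)) < 2L) stop("labels are single-class")
  if (min(table(y01)) < k)
    stop("k = ", k, " exceeds the smaller class count (", min(table(y01)), ")")
  clf <- as_classifier(classifier)
  folds <- stratified_folds(y01, k, seed)
  scores <- numeric(length(y01))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    model <- clf$fit(X[tr, , drop = FALSE], y01[tr])
    scores[!tr] <- clf$predict(model, X[!tr, , drop = FALSE])
    per_fold[[f]] <- compute_metrics(
      confusion_from_labels(y01[!tr], as.integer(scores[!tr] >= 0.5)))
  }
  pooled <- compute_metrics(
    confusion_from_labels(y01, as.integer(scores >= 0.5)))
  fold_mean <- structure(as.list(colMeans(
    do.call(rbind, lapply(per_fold, function(b) unlist(b))))),
    class = "metrics_bundle")
  structure(list(pooled = pooled, per_fold = per_fold,
                 fold_mean = fold_mean, folds = folds,
                 predictions = scores),
            class = "cv_result")
}

#' Repeated cross-validation stability harness
#'
#' Runs [cross_validate()] once per seed and summarizes each metric over
#' repeats with its mean, standard deviation and maximum — the protocol
#' behind "repeat 10-fold CV 100 times with different random seeds" model
#' stability comparisons. Per-repeat values are retained so distributions
#' can be exported and histogrammed.
#'
#' @inheritParams cross_validate
#' @param n_repeats Number of repeats (default 100).
#' @param seeds Integer vector of distinct seeds, one per repeat
#'   (default `0:(n_repeats-1)`).
#' @return List of class `repeated_cv_summary`: `per_repeat` (data frame,
#'   one row per repeat, metric columns), `mean`, `std`, `max` (named
#'   numeric vectors), `seeds`.
#' @export
repeated_cv <- function(X, y, classifier = gbdt_config(), n_repeats = 100L,
                        k = 10L, seeds = seq_len(n_repeats) - 1L) {
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  if (length(seeds) != n_repeats)
    stop("need exactly n_repeats seeds")
  rows <- lapply(seeds, function(s)
    unlist(cross_validate(X, y, classifier, k = k, seed = s)$pooled))
  per_repeat <- as.data.frame(do.call(rbind, rows))
  per_repeat$seed <- seeds
  m <- as.matrix(per_repeat[, names(rows[[1]])])
  structure(list(per_repeat = per_repeat,
                 mean = colMeans(m),
                 std = if (n_repeats == 1L)
                   stats::setNames(rep(0, ncol(m)), colnames(m))
                 else apply(m, 2, stats::sd),
                 max = apply(m, 2, max),
                 seeds = seeds),
            class = "repeated_cv_summary")
}

#' Write a metrics table as TSV
#'
#' Columns mirror the reporting convention of the field's comparison
#' tables: ACC, Recall, MCC, Precision, F-measure.
#'
#' @param bundles Named list of `metrics_bundle` objects (one row each).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(bundles, path) {
  df <- do.call(rbind, lapply(bundles, function(b)
    data.frame(ACC = b$accuracy, Recall = b$recall, MCC = b$mcc,
               Precision = b$precision, `F-measure` = b$f_measure,
               check.names = FALSE)))
  df <- cbind(model = names(bundles), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
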