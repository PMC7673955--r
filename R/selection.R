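## feature_selection: gain-importance ranking and incremental feature
## selection (IFS). Ranking and subset evaluation are deliberately separate
## stages so a ranking can be reused across classifiers.

#' Rank features by gradient-boosting gain importance
#'
#' Fits a single boosted-tree ensemble on all features (fixed seed) and
#' ranks features by their total gain — the summed reduction in the
#' boosting objective attributed to splits on each feature. Features never
#' used in a split get gain 0. Ties (including the all-zero case) are
#' broken by ascending original column index, so the ranking is fully
#' deterministic.
#'
#' @param X Feature matrix with column names.
#' @param y Binary labels (factor with level "positive", or 0/1).
#' @param trainer A [gbdt_config()] for the ranking model (default:
#'   backend defaults with 100 boosting rounds, seed 0).
#' @return Data frame of class `ranked_features` with columns `feature`,
#'   `importance` (non-increasing), `orig_index`; attribute `ranker`.
#' @export
rank_by_gain <- function(X, y, trainer = gbdt_config()) {
  y01 <- .as01(y)
  if (length(unique(y01)) < 2L) stop("labels are single-class")
  if (min(table(y01)) < 2L) stop("need at least 2 samples per class")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  clf <- as_classifier(trainer)
  model <- clf$fit(X, y01)
  imp <- xgboost::xgb.importance(model = model)
  gain <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (nrow(imp)) gain[imp$Feature] <- imp$Gain
  ord <- order(-gain, seq_along(gain))
  structure(data.frame(feature = names(gain)[ord],
                       importance = unname(gain)[ord],
                       orig_index = ord,
                       stringsAsFactors = FALSE),
            class = c("ranked_features", "data.frame"),
            ranker = "gain")
}

#' Rank features by one-way ANOVA F statistic
#'
#' For each feature, computes the one-way ANOVA F statistic between the two
#' classes (equivalent to the squared two-sample t statistic) and ranks
#' descending. A feature with zero within-class variance but distinct class
#' means gets F = +Inf and ranks first; zero within- and between-class
#' variance gives F = 0. Ties break by ascending original index.
#'
#' @inheritParams rank_by_gain
#' @return A `ranked_features` data frame; attribute `ranker` = "anova_f".
#' @export
rank_by_anova <- function(X, y) {
  y01 <- .as01(y)
  if (length(unique(y01)) < 2L) stop("labels are single-class")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  n <- nrow(X)
  g1 <- y01 == 1
  n1 <- sum(g1); n0 <- n - n1
  m1 <- colMeans(X[g1, , drop = FALSE])
  m0 <- colMeans(X[!g1, , drop = FALSE])
  gm <- (n1 * m1 + n0 * m0) / n
  ss_between <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
  ss_within <- colSums((X[g1, , drop = FALSE] -
                          rep(m1, each = n1))^2) +
               colSums((X[!g1, , drop = FALSE] -
                          rep(m0, each = n0))^2)
  fstat <- ifelse(ss_within == 0,
                  ifelse(ss_between == 0, 0, Inf),
                  (ss_between / 1) / (ss_within / (n - 2)))
  ord <- order(-fstat, seq_along(fstat))
  structure(data.frame(feature = colnames(X)[ord],
                       importance = unname(fstat)[ord],
                       orig_index = ord,
                       stringsAsFactors = FALSE),
            class = c("ranked_features", "data.frame"),
            ranker = "anova_f")
}

#' Incremental feature selection
#'
#' Walks the ranked feature list in increasing subset sizes (top-`step`,
#' top-`2*step`, ...), evaluates the classifier on each nested subset by
#' stratified k-fold cross-validation, and selects as optimum the smallest
#' subset size attaining the maximal fitness (ties favor fewer features).
#' Fitness defaults to the F-measure of the pooled out-of-fold confusion
#' table.
#'
#' @param ranked A `ranked_features` data frame ([rank_by_gain()] /
#'   [rank_by_anova()]); its feature names must be columns of `X`.
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param classifier Classifier configuration (see [as_classifier()]).
#' @param k Cross-validation folds (default 10).
#' @param seed Fold-assignment seed, shared by every subset evaluation.
#' @param step Subset-size increment (default 1).
#' @param max_size Largest subset size to evaluate (default: all ranked
#'   features; clipped with a warning if larger).
#' @param fitness Metric choosing the optimum (default `"f_measure"`).
#' @return List of class `ifs_curve`: `curve` (data frame with `size` and
#'   the five pooled metrics), `optimum` (size), `optimal_features`
#'   (character vector), `fitness`.
#' @export
run_ifs <- function(ranked, X, y, classifier = gbdt_config(), k = 10L,
                    seed = 0L, step = 1L, max_size = NULL,
                    fitness = c("f_measure", "accuracy", "recall",
                                "precision", "mcc")) {
  fitness <- match.arg(fitness)
  stopifnot(inherits(ranked, "ranked_features"), step >= 1L)
  if (!all(ranked$feature %in% colnames(X)))
    stop("ranked feature names must all be columns of X")
  if (is.null(max_size)) max_size <- nrow(ranked)
  if (max_size > nrow(ranked)) {
    warning("max_size exceeds the number of ranked features; clipping to ",
            nrow(ranked))
    max_size <- nrow(ranked)
  }
  sizes <- seq.int(step, max_size, by = step)
  rows <- vector("list", length(sizes))
  for (si in seq_along(sizes)) {
    i <- sizes[si]
    feats <- ranked$feature[seq_len(i)]
    cv <- cross_validate(X[, feats, drop = FALSE], y, classifier,
                         k = k, seed = seed)
    rows[[si]] <- data.frame(size = i, accuracy = cv$pooled$accuracy,
                             recall = cv$pooled$recall,
                             precision = cv$pooled$precision,
                             mcc = cv$pooled$mcc,
                             f_measure = cv$pooled$f_measure)
  }
  curve <- do.call(rbind, rows)
  best <- which.max(curve[[fitness]])  # first maximizer = fewest features
  structure(list(curve = curve, optimum = curve$size[best],
                 optimal_features = ranked$feature[seq_len(curve$size[best])],
                 fitness = fitness),
            class = "ifs_curve")
}

#' Write an IFS curve as TSV
#'
#' Columns: size, ACC, Recall, Precision, MCC, F-measure — the data behind
#' the usual IFS curve plots.
#'
#' @param ifs An `ifs_curve` from [run_ifs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ifs_curve <- function(ifs, path) {
  df <- ifs$curve
  names(df) <- c("size", "ACC", "Recall", "Precision", "MCC", "F-measure")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot an IFS curve
#'
#' @param x An `ifs_curve`.
#' @param metrics Curve columns to draw (default accuracy and the fitness
#'   metric).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ifs_curve <- function(x, metrics = unique(c("accuracy", x$fitness)),
                           ...) {
  graphics::matplot(x$curve$size, as.matrix(x$curve[, metrics]),
                    type = "l", lty = 1, xlab = "number of features",
                    ylab = "metric", ...)
  graphics::abline(v = x$optimum, lty = 2, col = "grey50")
  graphics::legend("bottomright", legend = metrics, lty = 1,
                   col = seq_along(metrics), bty = "n")
  invisible(x)
}
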