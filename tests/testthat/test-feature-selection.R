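test_that("gain ranking puts a label-copy feature first across seeds", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 500
    X <- matrix(rnorm(n * 10), n, 10)
    colnames(X) <- paste0("f", 1:10)
    y <- rbinom(n, 1, 0.5)
    X[, 1] <- y  # feature 1 is the label
    ranked <- rank_by_gain(X, y, light_gbdt(seed = s))
    if (ranked$feature[1] == "f1") hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("all-constant features all get zero gain in original index order", {
  X <- matrix(1, 60, 5)
  colnames(X) <- paste0("c", 1:5)
  y <- rep(c(1, 0), 30)
  ranked <- rank_by_gain(X, y, light_gbdt())
  expect_true(all(ranked$importance == 0))
  expect_equal(ranked$feature, paste0("c", 1:5))
})

test_that("permuting columns permutes names but not the name-to-score map", {
  set.seed(8)
  n <- 300
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- paste0("f", 1:6)
  y <- rbinom(n, 1, 0.5)
  X[, 2] <- X[, 2] + 2 * y
  X[, 5] <- X[, 5] + 1 * y
  r1 <- rank_by_gain(X, y, light_gbdt())
  perm <- c(4, 2, 6, 1, 5, 3)
  r2 <- rank_by_gain(X[, perm], y, light_gbdt())
  s1 <- setNames(r1$importance, r1$feature)
  s2 <- setNames(r2$importance, r2$feature)
  expect_equal(s1[sort(names(s1))], s2[sort(names(s2))], tolerance = 1e-9)
})

test_that("gain ranking rejects degenerate labels", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(rank_by_gain(X, rep(1, 20)), "single-class")
})

test_that("ANOVA ranking separates a shifted feature from noise", {
  set.seed(21)
  n <- 200
  X <- matrix(rnorm(n * 8), n, 8)
  colnames(X) <- paste0("f", 1:8)
  y <- rep(c(1, 0), n / 2)
  X[, 4] <- X[, 4] + 5 * y
  ranked <- rank_by_anova(X, y)
  expect_equal(ranked$feature[1], "f4")
  expect_true(all(diff(ranked$importance) <= 0))
})

test_that("ANOVA F agrees with aov() on toy data and handles equal means", {
  set.seed(22)
  X <- matrix(rnorm(12 * 3), 12, 3)
  colnames(X) <- c("a", "b", "c")
  y <- rep(c(1, 0), each = 6)
  X[, 2] <- X[, 2] + 1.3 * y
  ranked <- rank_by_anova(X, y)
  for (j in 1:3) {
    f_ref <- summary(aov(X[, j] ~ factor(y)))[[1]]$`F value`[1]
    expect_equal(ranked$importance[ranked$feature == colnames(X)[j]],
                 f_ref, tolerance = 1e-8)
  }
  # identical class means: tiny F, no crash
  Z <- matrix(rep(rnorm(6), 2), 12, 1)
  colnames(Z) <- "z"
  expect_true(is.finite(rank_by_anova(cbind(X, Z), y)$importance[4]))
})

test_that("zero within-group variance ranks first as infinite F", {
  X <- cbind(sep = rep(c(1, 0), each = 10), noise = rnorm(20))
  y <- rep(c(1, 0), each = 10)
  ranked <- rank_by_anova(X, y)
  expect_equal(ranked$feature[1], "sep")
  expect_equal(ranked$importance[1], Inf)
})

test_that("manual F statistic on a hand-computable toy set", {
  # class 1: 1, 2, 3; class 0: 5, 6, 7 -> between SS = 24, within MS = 1
  X <- matrix(c(1, 2, 3, 5, 6, 7), 6, 1)
  colnames(X) <- "x"
  y <- c(1, 1, 1, 0, 0, 0)
  ranked <- rank_by_anova(X, y)
  expect_equal(ranked$importance[1], 24)
})

test_that("IFS evaluates the exact subset-size schedule and picks the first maximizer", {
  set.seed(30)
  n <- 120
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- paste0("f", 1:6)
  y <- rep(c(1, 0), n / 2)
  X[, 1] <- X[, 1] + 3 * y
  ranked <- rank_by_anova(X, y)
  ifs <- run_ifs(ranked, X, y, threshold_classifier(), k = 5, seed = 0,
                 step = 1, max_size = 3)
  expect_equal(ifs$curve$size, 1:3)
  # threshold classifier only looks at the top feature: fitness is constant,
  # so the tie rule must pick the smallest subset
  expect_equal(ifs$optimum, 1L)
  expect_equal(ifs$optimal_features, ranked$feature[1])
})

test_that("IFS clips an oversized max_size with a warning", {
  set.seed(31)
  X <- matrix(rnorm(60 * 3), 60, 3)
  colnames(X) <- paste0("f", 1:3)
  y <- rep(c(1, 0), 30)
  ranked <- rank_by_anova(X, y)
  expect_warning(ifs <- run_ifs(ranked, X, y, majority_classifier(),
                                k = 5, seed = 0, max_size = 99),
                 "clipping")
  expect_equal(max(ifs$curve$size), 3L)
})

test_that("IFS is reproducible and its optimum re-evaluates identically", {
  set.seed(32)
  n <- 150
  X <- matrix(rnorm(n * 8), n, 8)
  colnames(X) <- paste0("f", 1:8)
  y <- rep(c(1, 0), n / 2)
  X[, 2] <- X[, 2] + 2 * y
  ranked <- rank_by_anova(X, y)
  a <- run_ifs(ranked, X, y, light_gbdt(), k = 5, seed = 3, max_size = 4)
  b <- run_ifs(ranked, X, y, light_gbdt(), k = 5, seed = 3, max_size = 4)
  expect_identical(a$curve, b$curve)
  expect_identical(a$optimum, b$optimum)
  redo <- cross_validate(X[, a$optimal_features, drop = FALSE], y,
                         light_gbdt(), k = 5, seed = 3)
  expect_equal(a$curve$f_measure[a$curve$size == a$optimum],
               redo$pooled$f_measure)
})

test_that("IFS recovers planted informative features with rising fitness", {
  set.seed(33)
  n <- 400
  p <- 25
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", 1:p)
  y <- rep(c(1, 0), n / 2)
  for (j in 1:5) X[, j] <- X[, j] + 1.2 * y
  ranked <- rank_by_anova(X, y)
  expect_true(all(paste0("f", 1:5) %in% ranked$feature[1:8]))
  ifs <- run_ifs(ranked, X, y, light_gbdt(), k = 5, seed = 0,
                 max_size = 10)
  expect_lte(ifs$optimum, 10)
  f_at_5 <- ifs$curve$f_measure[5]
  expect_gt(f_at_5, ifs$curve$f_measure[1] - 0.02)
  expect_gt(max(ifs$curve$f_measure), 0.75)
})

test_that("IFS curve TSV carries the five metric columns", {
  curve <- structure(list(
    curve = data.frame(size = 1:2, accuracy = c(0.6, 0.7),
                       recall = c(0.5, 0.6), precision = c(0.6, 0.7),
                       mcc = c(0.2, 0.4), f_measure = c(0.55, 0.65)),
    optimum = 2L, optimal_features = c("a", "b"),
    fitness = "f_measure"), class = "ifs_curve")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ifs_curve(curve, path)
  df <- read.delim(path, check.names = FALSE)
  expect_equal(names(df), c("size", "ACC", "Recall", "Precision", "MCC",
                            "F-measure"))
  expect_equal(nrow(df), 2L)
})
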