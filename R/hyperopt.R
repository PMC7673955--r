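## hyperopt: hyperparameter search by Gaussian-process Bayesian
## optimization with the expected-improvement acquisition, and exhaustive
## grid search. The GP surrogate (Matern 5/2 ARD kernel with observation
## noise, hyperparameters fit by marginal-likelihood maximization) is
## implemented here directly; it is a standard, compact construction.

#' Declare hyperparameters
#'
#' Constructors for the three parameter kinds of a search space: bounded
#' reals (optionally searched on a log scale), bounded integers, and
#' categorical choices.
#'
#' @param name Parameter name.
#' @param lower,upper Bounds (inclusive).
#' @param log Search this real on a log10 scale (sensible when the range
#'   spans decades).
#' @param choices Character vector of categorical values.
#' @return A list of class `hp_param`.
#' @export
param_real <- function(name, lower, upper, log = FALSE) {
  stopifnot(lower < upper, !log || lower > 0)
  structure(list(name = name, kind = "real", lower = lower, upper = upper,
                 log = log), class = "hp_param")
}

#' @rdname param_real
#' @export
param_int <- function(name, lower, upper) {
  stopifnot(lower < upper)
  structure(list(name = name, kind = "integer", lower = as.integer(lower),
                 upper = as.integer(upper), log = FALSE),
            class = "hp_param")
}

#' @rdname param_real
#' @export
param_cat <- function(name, choices) {
  stopifnot(length(choices) >= 1L)
  structure(list(name = name, kind = "categorical",
                 choices = as.character(choices)), class = "hp_param")
}

#' Assemble a hyperparameter space
#'
#' @param ... `hp_param` objects.
#' @return A named list of class `hyperparameter_space`.
#' @export
hp_space <- function(...) {
  params <- list(...)
  stopifnot(all(vapply(params, inherits, logical(1), "hp_param")))
  names(params) <- vapply(params, `[[`, character(1), "name")
  if (anyDuplicated(names(params))) stop("duplicate parameter names")
  structure(params, class = "hyperparameter_space")
}

#' Default search space for the gradient-boosted classifier
#'
#' Seven parameters: learning_rate (0.01, 1.0) on a log scale; max_depth
#' (1, 50); max_bin (10, 100); reg_alpha (1e-9, 1.0) on a log scale;
#' boosting_type in \{gbdt, goss, rf, dart\}; num_leaves (2, 50) — a
#' nominal lower bound of 1 is below the minimum meaningful leaf count and
#' is clamped to 2; n_estimators (100, 600).
#'
#' @return A `hyperparameter_space`.
#' @export
default_gbdt_space <- function() {
  hp_space(
    param_real("learning_rate", 0.01, 1.0, log = TRUE),
    param_int("max_depth", 1L, 50L),
    param_int("max_bin", 10L, 100L),
    param_real("reg_alpha", 1e-9, 1.0, log = TRUE),
    param_cat("boosting_type", c("gbdt", "goss", "rf", "dart")),
    param_int("num_leaves", 2L, 50L),
    param_int("n_estimators", 100L, 600L)
  )
}

## --- point encoding ------------------------------------------------------
## Reals/integers map to [0,1] (log10 scale where requested); categoricals
## one-hot. The GP sees only the encoded cube.

.encode_dim <- function(space)
  sum(vapply(space, function(p)
    if (p$kind == "categorical") length(p$choices) else 1L, integer(1)))

.encode_point <- function(space, point) {
  out <- numeric(0)
  for (p in space) {
    v <- point[[p$name]]
    out <- c(out, switch(p$kind,
      real = if (p$log) (log10(v) - log10(p$lower)) /
               (log10(p$upper) - log10(p$lower))
             else (v - p$lower) / (p$upper - p$lower),
      integer = (v - p$lower) / (p$upper - p$lower),
      categorical = as.numeric(p$choices == v)))
  }
  out
}

## unit-cube vector (one coordinate per param; categoricals as index in
## [0,1)) -> named parameter list
.decode_unit <- function(space, u) {
  point <- list()
  for (i in seq_along(space)) {
    p <- space[[i]]
    ui <- u[i]
    point[[p$name]] <- switch(p$kind,
      real = if (p$log) 10^(log10(p$lower) +
                              ui * (log10(p$upper) - log10(p$lower)))
             else p$lower + ui * (p$upper - p$lower),
      integer = as.integer(round(p$lower + ui * (p$upper - p$lower))),
      categorical = p$choices[1L + min(length(p$choices) - 1L,
                                       floor(ui * length(p$choices)))])
  }
  point
}

#' Probability- and expected-improvement acquisition values
#'
#' For a minimization objective with incumbent (lowest observed) value
#' `f_best` and GP posterior mean `mu` and standard deviation `sigma` at a
#' candidate point:
#'
#'   gamma = (f_best - mu) / sigma
#'   PI    = Phi(gamma)
#'   EI    = sigma * (gamma * Phi(gamma) + phi(gamma))
#'
#' with Phi/phi the standard normal CDF/density. At sigma = 0 the limits
#' are used: EI = max(f_best - mu, 0); PI = 1 if mu < f_best, else 0.
#'
#' @param mu Posterior mean(s).
#' @param sigma Posterior standard deviation(s), >= 0.
#' @param f_best Incumbent objective value.
#' @return A list of class `acquisition_eval` with vectors `gamma`, `a_pi`,
#'   `a_ei`.
#' @export
#' @examples
#' acquisition(0, 1, 0)  # gamma 0, PI 0.5, EI = dnorm(0)
acquisition <- function(mu, sigma, f_best) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  gamma <- ifelse(sigma > 0, (f_best - mu) / sigma,
                  ifelse(mu < f_best, Inf, -Inf))
  a_pi <- ifelse(sigma > 0, stats::pnorm(gamma),
                 as.numeric(mu < f_best))
  a_ei <- ifelse(sigma > 0,
                 sigma * (gamma * stats::pnorm(gamma) +
                            stats::dnorm(gamma)),
                 pmax(f_best - mu, 0))
  structure(list(gamma = gamma, a_pi = a_pi, a_ei = a_ei),
            class = "acquisition_eval")
}

## --- Gaussian process ----------------------------------------------------

.matern52 <- function(X1, X2, ls, s2) {
  X1s <- sweep(X1, 2, ls, "/"); X2s <- sweep(X2, 2, ls, "/")
  d2 <- outer(rowSums(X1s^2), rowSums(X2s^2), "+") -
    2 * tcrossprod(X1s, X2s)
  d <- sqrt(pmax(d2, 0))
  s2 * (1 + sqrt(5) * d + 5 * d^2 / 3) * exp(-sqrt(5) * d)
}

## Fit GP hyperparameters (log lengthscales per dim, log amplitude, log
## noise) by L-BFGS-B on the negative log marginal likelihood. y is
## standardized internally.
.gp_fit <- function(X, y) {
  ym <- mean(y); ys <- stats::sd(y); if (!is.finite(ys) || ys == 0) ys <- 1
  yz <- (y - ym) / ys
  d <- ncol(X); n <- nrow(X)
  nll <- function(theta) {
    ls <- exp(theta[1:d]); s2 <- exp(theta[d + 1]); nz <- exp(theta[d + 2])
    K <- .matern52(X, X, ls, s2) + diag(nz + 1e-8, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), yz))
    0.5 * sum(yz * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  }
  init <- c(rep(log(0.3), d), log(1), log(1e-3))
  opt <- stats::optim(init, nll, method = "L-BFGS-B",
                      lower = c(rep(log(0.01), d), log(1e-4), log(1e-8)),
                      upper = c(rep(log(10), d), log(100), log(1)))
  ls <- exp(opt$par[1:d]); s2 <- exp(opt$par[d + 1])
  nz <- exp(opt$par[d + 2])
  K <- .matern52(X, X, ls, s2) + diag(nz + 1e-8, n)
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yz))
  list(X = X, chol = ch, alpha = alpha, ls = ls, s2 = s2, noise = nz,
       y_mean = ym, y_sd = ys)
}

.gp_predict <- function(gp, Xnew) {
  Ks <- .matern52(Xnew, gp$X, gp$ls, gp$s2)
  mu <- as.vector(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$chol), t(Ks))
  var <- pmax(gp$s2 - colSums(v^2), 0)
  list(mu = mu * gp$y_sd + gp$y_mean, sd = sqrt(var) * gp$y_sd)
}

#' Minimize an objective by Gaussian-process Bayesian optimization
#'
#' Evaluates `n_init` space-filling points (Latin hypercube), then for
#' `n_iter` rounds fits the GP surrogate to all observations and evaluates
#' the objective at the candidate (from `n_candidates` random draws)
#' maximizing the acquisition function. The incumbent is the lowest
#' observed objective value. To maximize a score (e.g. a cross-validated
#' F-measure), pass its negative as the objective.
#'
#' @param objective Function taking a named parameter list, returning a
#'   finite numeric scalar to minimize.
#' @param space A `hyperparameter_space`.
#' @param n_init Initial design size (>= 2; default 10).
#' @param n_iter Surrogate-guided evaluations (default 50).
#' @param seed Integer seed (candidate draws, initial design).
#' @param n_candidates Random candidates per round (default 2048).
#' @param acq `"ei"` (default) or `"pi"`.
#' @return List of class `bo_result`: `best_point`, `best_value`, `trace`
#'   (data frame with one row per evaluation: parameters, `value`,
#'   `incumbent`).
#' @export
bo_minimize <- function(objective, space, n_init = 10L, n_iter = 50L,
                        seed = 0L, n_candidates = 2048L,
                        acq = c("ei", "pi")) {
  acq <- match.arg(acq)
  stopifnot(inherits(space, "hyperparameter_space"))
  if (n_init < 2L) stop("n_init must be at least 2 to fit the surrogate")
  d_unit <- length(space)
  points <- list(); values <- numeric(0)
  withr::with_seed(seed, {
    U <- lhs::randomLHS(n_init, d_unit)
    for (i in seq_len(n_init)) {
      points[[i]] <- .decode_unit(space, U[i, ])
      values[i] <- objective(points[[i]])
    }
    for (it in seq_len(n_iter)) {
      Xenc <- do.call(rbind, lapply(points, .encode_point, space = space))
      gp <- .gp_fit(Xenc, values)
      Ucand <- matrix(stats::runif(n_candidates * d_unit), n_candidates)
      cand <- lapply(seq_len(n_candidates),
                     function(j) .decode_unit(space, Ucand[j, ]))
      Cenc <- do.call(rbind, lapply(cand, .encode_point, space = space))
      pr <- .gp_predict(gp, Cenc)
      a <- acquisition(pr$mu, pr$sd, min(values))
      pick <- which.max(if (acq == "ei") a$a_ei else a$a_pi)
      points[[n_init + it]] <- cand[[pick]]
      values[n_init + it] <- objective(cand[[pick]])
    }
  })
  if (any(!is.finite(values))) stop("objective returned a non-finite value")
  trace <- cbind(do.call(rbind, lapply(points, function(p)
    as.data.frame(p, stringsAsFactors = FALSE))),
    value = values, incumbent = cummin(values))
  best <- which.min(values)
  structure(list(best_point = points[[best]], best_value = values[best],
                 trace = trace),
            class = "bo_result")
}

#' Exhaustive grid search
#'
#' Evaluates the objective on the full Cartesian product of the supplied
#' per-parameter value lists, in lexicographic grid order (first parameter
#' varying fastest); ties on the best value go to the earliest row.
#'
#' @param objective Function taking a named parameter list, returning a
#'   numeric scalar to minimize.
#' @param grid Named list of per-parameter value vectors.
#' @return List of class `grid_result`: `best_point`, `best_value`,
#'   `table` (the full grid with a `value` column).
#' @export
grid_search <- function(objective, grid) {
  stopifnot(is.list(grid), length(grid) >= 1L, !is.null(names(grid)))
  tab <- expand.grid(grid, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  values <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    pt <- as.list(tab[i, , drop = FALSE])
    names(pt) <- names(tab)
    values[i] <- tryCatch(objective(pt), error = function(e)
      stop("objective failed at grid row ", i, " (",
           paste(names(pt), unlist(pt), sep = "=", collapse = ", "),
           "): ", conditionMessage(e)))
  }
  tab$value <- values
  best <- which.min(values)  # first minimizer
  bp <- as.list(tab[best, setdiff(names(tab), "value"), drop = FALSE])
  names(bp) <- setdiff(names(tab), "value")
  structure(list(best_point = bp, best_value = values[best], table = tab),
            class = "grid_result")
}

#' Cross-validated tuning objective for the boosted classifier
#'
#' Builds the objective used to tune [gbdt_config()] hyperparameters: a
#' function mapping a parameter list to the negative pooled
#' cross-validation F-measure (negated because the optimizers minimize).
#'
#' @param X Feature matrix (typically restricted to the IFS-optimal
#'   subset).
#' @param y Binary labels.
#' @param k CV folds (default 10).
#' @param seed Fold seed.
#' @param fitness Metric to maximize (default `"f_measure"`).
#' @param base Base configuration whose unspecified fields the tuned
#'   parameters overwrite.
#' @return Function suitable for [bo_minimize()] / [grid_search()].
#' @export
cv_objective <- function(X, y, k = 10L, seed = 0L, fitness = "f_measure",
                         base = gbdt_config()) {
  force(X); force(y)
  function(point) {
    cfg <- base
    for (nm in names(point)) cfg[[nm]] <- point[[nm]]
    if (!is.null(cfg$num_leaves) && cfg$num_leaves < 2L) cfg$num_leaves <- 2L
    cv <- cross_validate(X, y, cfg, k = k, seed = seed)
    -cv$pooled[[fitness]]
  }
}
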