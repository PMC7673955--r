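# Shared fixtures, built in code at test time.

# A tiny in-memory dataset with optional planted PSSM signal.
tiny_dataset <- function(n_pos = 10, n_neg = 10, seed = 1, signal = 0,
                         motif = NULL) {
  if (is.null(motif) && signal != 0)
    motif <- data.frame(offset = c(-1L, 1L), residue = c("L", "E"),
                        prob = 0)
  generate_dataset(synthetic_spec(n_positive = n_pos, n_negative = n_neg,
                                  motif = motif, pssm_signal = signal,
                                  seed = seed))
}

# Random window strings over the standard alphabet, optionally with pads
# and ambiguity letters mixed in.
random_window <- function(len = 21, pads = 0, ambig = 0) {
  res <- sample(succpred::aa_alphabet(), len, replace = TRUE)
  if (pads > 0) res[seq_len(pads)] <- "X"
  if (ambig > 0) res[len - seq_len(ambig) + 1] <- sample(c("B", "Z", "U", "O", "J"), ambig,
                                                          replace = TRUE)
  paste(res, collapse = "")
}

# A deterministic toy classifier: thresholds the first feature at its
# training-set midpoint. Used where tree training would be noise.
threshold_classifier <- function() {
  list(fit = function(X, y01) {
    mean(c(mean(X[y01 == 1, 1]), mean(X[y01 == 0, 1])))
  },
  predict = function(model, X) as.numeric(X[, 1] > model))
}

# A classifier that always predicts the majority training class.
majority_classifier <- function() {
  list(fit = function(X, y01) as.numeric(mean(y01) >= 0.5),
       predict = function(model, X) rep(model, nrow(X)))
}

# Light boosted config for test loops (shallow trees, fewer rounds).
light_gbdt <- function(seed = 0L) {
  gbdt_config(n_estimators = 50L, max_depth = 3L, seed = seed)
}
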