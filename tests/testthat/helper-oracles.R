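# Independent formula oracles: literal loop transcriptions of the encoder
# and metric definitions. They deliberately share no code with the package
# implementation (the PseAAC property table is configuration, not code).

oracle_cksaap <- function(window, k_max = 4) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  ch <- strsplit(window, "")[[1]]
  L <- length(ch)
  out <- c()
  for (k in 0:k_max) {
    counts <- matrix(0, 20, 20, dimnames = list(aa, aa))
    for (i in 1:(L - k - 1)) {
      a <- ch[i]; b <- ch[i + k + 1]
      if (a %in% aa && b %in% aa) counts[a, b] <- counts[a, b] + 1
    }
    out <- c(out, as.vector(t(counts)) / (L - k - 1))
  }
  out
}

oracle_pseaac <- function(window, lambda, w) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  tab <- succpred::aaindex_table()
  ch <- strsplit(window, "")[[1]]
  L <- length(ch)
  std <- ch %in% aa
  f <- sapply(aa, function(a) sum(ch == a))
  f <- f / sum(f)
  b <- numeric(lambda)
  for (j in 1:lambda) {
    terms <- c()
    for (i in 1:(L - j)) {
      if (std[i] && std[i + j]) {
        terms <- c(terms, ((tab[ch[i], "H1"] - tab[ch[i + j], "H1"])^2 +
                           (tab[ch[i], "H2"] - tab[ch[i + j], "H2"])^2 +
                           (tab[ch[i], "M"] - tab[ch[i + j], "M"])^2) / 3)
      }
    }
    b[j] <- if (length(terms)) sum(terms) / length(terms) else 0
  }
  denom <- sum(f) + w * sum(b)
  unname(c(f / denom, w * b / denom))
}

oracle_pssm <- function(M) {
  flat <- c()
  for (i in 1:nrow(M)) for (j in 1:20) flat <- c(flat, M[i, j])
  means <- c()
  for (j in 1:20) means <- c(means, sum(M[, j]) / nrow(M))
  c(flat, means)
}

oracle_metrics <- function(tp, fp, tn, fn) {
  acc <- (tp + tn) / (tp + fp + tn + fn)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  pre <- if (tp + fp == 0) 0 else tp / (tp + fp)
  fme <- if (pre + rec == 0) 0 else 2 * pre * rec / (pre + rec)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  c(accuracy = acc, recall = rec, precision = pre, mcc = mcc,
    f_measure = fme)
}
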