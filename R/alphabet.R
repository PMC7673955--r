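#' @keywords internal
"_PACKAGE"

## Canonical amino-acid order used for every feature block. This is the
## PSI-BLAST PSSM column order; all parsed profiles are remapped to it so
## feature positions are stable across inputs.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## Ambiguity / non-standard letters tolerated in sequences. 'X' doubles as
## the window padding character.
AA_EXTRA <- c("B", "Z", "U", "X", "O", "J")

PAD_CHAR <- "X"

#' Canonical amino-acid alphabet
#'
#' Returns the 20 standard amino-acid one-letter codes in the canonical
#' column order used throughout the package (the PSI-BLAST PSSM order:
#' A, R, N, D, C, Q, E, G, H, I, L, K, M, F, P, S, T, W, Y, V).
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() AA20

#' Physicochemical property table for Type-1 pseudo amino acid composition
#'
#' Hydrophobicity, hydrophilicity and side-chain mass for the 20 standard
#' amino acids, both raw and standardized. These are the property scales of
#' Chou's original pseudo amino acid composition web server
#' (hydrophobicity: Tanford-style scale; hydrophilicity: Hopp-Woods;
#' side-chain mass in Daltons). Standardized columns (`H1`, `H2`, `M`) have
#' zero mean and unit standard deviation over the 20 amino acids, using the
#' population SD (divisor 20), which is the PseAAC convention.
#'
#' The table is built in code rather than shipped as binary data so the
#' scales can be audited and swapped: pass any data frame with the same
#' columns to [encode_pseaac()].
#'
#' @return A data frame with row names the amino acids (canonical order) and
#'   columns `H1_raw`, `H2_raw`, `M_raw`, `H1`, `H2`, `M`.
#' @export
#' @examples
#' tab <- aaindex_table()
#' colMeans(tab[, c("H1", "H2", "M")])  # ~0
aaindex_table <- function() {
  h1_raw <- c(A =  0.62, R = -2.53, N = -0.78, D = -0.90, C =  0.29,
              Q = -0.85, E = -0.74, G =  0.48, H = -0.40, I =  1.38,
              L =  1.06, K = -1.50, M =  0.64, F =  1.19, P =  0.12,
              S = -0.18, T = -0.05, W =  0.81, Y =  0.26, V =  1.08)
  h2_raw <- c(A = -0.5, R =  3.0, N =  0.2, D =  3.0, C = -1.0,
              Q =  0.2, E =  3.0, G =  0.0, H = -0.5, I = -1.8,
              L = -1.8, K =  3.0, M = -1.3, F = -2.5, P =  0.0,
              S =  0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5)
  m_raw  <- c(A =  15, R = 101, N =  58, D =  59, C =  47,
              Q =  72, E =  73, G =   1, H =  82, I =  57,
              L =  57, K =  73, M =  75, F =  91, P =  42,
              S =  31, T =  45, W = 130, Y = 107, V =  43)
  std <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  out <- data.frame(
    H1_raw = h1_raw[AA20], H2_raw = h2_raw[AA20], M_raw = m_raw[AA20],
    H1 = std(h1_raw[AA20]), H2 = std(h2_raw[AA20]), M = std(m_raw[AA20]),
    row.names = AA20
  )
  out
}

#' Order/disorder call from a quantitative disorder score
#'
#' Disorder predictors emit per-residue scores in \[0, 1\]; by convention a
#' score above 0.5 marks a residue as intrinsically disordered. The
#' quantitative scores themselves are what enter the feature vector; this
#' predicate is a convenience for qualitative summaries only.
#'
#' @param score Numeric vector of disorder scores in \[0, 1\].
#' @param threshold Boundary between order and disorder (default 0.5).
#' @return Logical vector, `TRUE` where disordered.
#' @export
is_disordered <- function(score, threshold = 0.5) {
  stopifnot(is.numeric(score), all(score >= 0 & score <= 1))
  score > threshold
}
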