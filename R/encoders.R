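## feature_encoders: the four window featurizations and their fusion.
##
## A 21-residue window is encoded as:
##   CKSAAP   2000 = 400 ordered residue pairs x (k_max + 1 = 5) spacings
##   disorder   21 = the per-residue disorder scores, pass-through
##   PseAAC     40 = 20 composition fractions + lambda = 20 correlation terms
##   PSSM      440 = 420 flattened conservation scores + 20 column means
## fused in that order into a 2501-dimensional vector.
##
## Non-standard residues (B, Z, U, O, J) and the pad character 'X' are
## treated as missing data: they are skipped in pair counts and composition
## frequencies, and correlation terms touching them are dropped with the
## divisor reduced accordingly.

#' CKSAAP encoder configuration
#'
#' @param k_max Largest spacing between the two residues of a pair
#'   (default 4, i.e. k = 0..4, giving 400 x 5 = 2000 features).
#' @return A list of class `cksaap_config`.
#' @export
cksaap_config <- function(k_max = 4L) {
  k_max <- as.integer(k_max)
  stopifnot(k_max >= 0L)
  structure(list(k_max = k_max), class = "cksaap_config")
}

#' PseAAC encoder configuration
#'
#' @param lambda Number of sequence-order correlation tiers (default 20).
#' @param w Weight balancing composition against correlation terms
#'   (default 0.05).
#' @return A list of class `pseaac_config`.
#' @export
pseaac_config <- function(lambda = 20L, w = 0.05) {
  lambda <- as.integer(lambda)
  stopifnot(lambda >= 1L, w > 0)
  structure(list(lambda = lambda, w = w), class = "pseaac_config")
}

#' Feature block layout of the fused vector
#'
#' @param window_length Window length (default 21).
#' @param cksaap A [cksaap_config()].
#' @param pseaac A [pseaac_config()].
#' @return A data frame of class `feature_layout` with columns `block`,
#'   `dim`, `offset` (0-based start of each block), and attribute `total`.
#' @export
#' @examples
#' feature_layout()  # 2000 / 21 / 40 / 440, total 2501
feature_layout <- function(window_length = 21L, cksaap = cksaap_config(),
                           pseaac = pseaac_config()) {
  dims <- c(CKSAAP = 400L * (cksaap$k_max + 1L),
            disorder = as.integer(window_length),
            PseAAC = 20L + pseaac$lambda,
            PSSM = 20L * as.integer(window_length) + 20L)
  out <- data.frame(block = names(dims), dim = unname(dims),
                    offset = cumsum(c(0L, unname(dims)[-4L])),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- sum(dims)
  class(out) <- c("feature_layout", class(out))
  out
}

#' Global feature names for the fused vector
#'
#' Names follow `"<block>:<local-index>:<description>"`, e.g.
#' `"CKSAAP:1:k0_AA"`, `"disorder:11:pos0"`, `"PseAAC:21:lambda1"`,
#' `"PSSM:421:mean_A"`. Disorder positions are named by their offset from
#' the central lysine; PSSM flatten cells by window row and column residue.
#'
#' @inheritParams feature_layout
#' @return Character vector of length `attr(feature_layout(), "total")`.
#' @export
feature_names <- function(window_length = 21L, cksaap = cksaap_config(),
                          pseaac = pseaac_config()) {
  r <- (window_length - 1L) %/% 2L
  pairs <- as.vector(t(outer(AA20, AA20, paste0)))  # AA, AR, ..., VV
  cks <- unlist(lapply(0:cksaap$k_max,
                       function(k) paste0("k", k, "_", pairs)))
  dis <- paste0("pos", seq_len(window_length) - r - 1L)
  pse <- c(paste0("comp_", AA20), paste0("lambda", seq_len(pseaac$lambda)))
  psm <- c(as.vector(t(outer(seq_len(window_length), AA20,
                             function(i, a) paste0("p", i, "_", a)))),
           paste0("mean_", AA20))
  blocks <- list(CKSAAP = cks, disorder = dis, PseAAC = pse, PSSM = psm)
  unlist(lapply(names(blocks), function(b)
    paste0(b, ":", seq_along(blocks[[b]]), ":", blocks[[b]])),
    use.names = FALSE)
}

## Split a window string into residue indices in 1..20 (NA = non-standard/pad).
.residue_idx <- function(residues) {
  match(strsplit(residues, "")[[1]], AA20)
}

#' Composition of k-spaced amino-acid pairs (CKSAAP)
#'
#' For each spacing k in 0..`k_max` and each ordered pair (i, j) of the 20
#' standard amino acids, counts occurrences of residue i followed, k
#' positions later plus one, by residue j, and divides by the number of
#' k-spaced pairs the window holds, `N_total = L - k - 1` (20, 19, 18, 17,
#' 16 for a 21-residue window with k = 0..4). Pairs touching a non-standard
#' or pad character are not counted, but the denominator is unchanged, so
#' padded windows shrink toward zero rather than renormalizing.
#'
#' @param residues Window string (length L >= k_max + 2).
#' @param cfg A [cksaap_config()].
#' @return Numeric vector of length `400 * (k_max + 1)`; blocks ordered
#'   k = 0 first, pairs row-major in canonical order (AA, AR, ..., VV).
#' @export
#' @examples
#' v <- encode_cksaap("AAAAAAAAAAKAAAAAAAAAA")
#' v[1]  # N_AA / 20 = 18/20
encode_cksaap <- function(residues, cfg = cksaap_config()) {
  idx <- .residue_idx(residues)
  L <- length(idx)
  if (L < cfg$k_max + 2L)
    stop("window of length ", L, " too short for k_max = ", cfg$k_max)
  out <- numeric(400L * (cfg$k_max + 1L))
  for (k in 0:cfg$k_max) {
    a <- idx[1:(L - k - 1L)]
    b <- idx[(k + 2L):L]
    ok <- !is.na(a) & !is.na(b)
    counts <- tabulate((a[ok] - 1L) * 20L + b[ok], nbins = 400L)
    out[k * 400L + seq_len(400L)] <- counts / (L - k - 1L)
  }
  out
}

#' Disorder feature block
#'
#' Identity pass-through of the 21 window-aligned quantitative disorder
#' scores (see [slice_profile()]); padded positions carry 0. The 0.5
#' order/disorder threshold is deliberately not applied — the quantitative
#' scores are the features (see [is_disordered()] for the predicate).
#'
#' @param scores Numeric vector of window-aligned disorder scores in
#'   \[0, 1\].
#' @return The scores, unchanged.
#' @export
encode_disorder <- function(scores) {
  if (!is.numeric(scores) || anyNA(scores))
    stop("disorder scores must be numeric and non-missing")
  if (any(scores < 0 | scores > 1))
    stop("disorder scores must lie in [0, 1]")
  as.numeric(scores)
}

#' Type-1 pseudo amino acid composition (PseAAC)
#'
#' Encodes a window as 20 composition terms plus `lambda` sequence-order
#' correlation factors over three standardized physicochemical properties
#' (hydrophobicity H1, hydrophilicity H2, side-chain mass M; see
#' [aaindex_table()]). The j-th correlation factor is the average over all
#' residue pairs (i, i+j) of the mean of the three squared property
#' differences; the composition fractions f and factors b are combined as
#'
#'   p_n = f_n / (1 + w * sum(b))            for n = 1..20
#'   p_n = w * b_(n-20) / (1 + w * sum(b))   for n = 21..20+lambda
#'
#' so all `20 + lambda` components sum to 1. Non-standard and pad residues
#' are excluded from the composition counts; correlation terms touching
#' them are dropped and the divisor reduced. A tier with no valid pair
#' (possible only in heavily padded windows) contributes b_j = 0.
#'
#' With the default 21-residue window and `lambda = 20`, the last tier
#' averages a single pair (positions 1 and 21); this extreme is allowed and
#' exercised by the test-suite.
#'
#' @param residues Window string.
#' @param table Property table as returned by [aaindex_table()].
#' @param cfg A [pseaac_config()]; `lambda` must be < the window length.
#' @return Numeric vector of length `20 + lambda`.
#' @export
encode_pseaac <- function(residues, table = aaindex_table(),
                          cfg = pseaac_config()) {
  idx <- .residue_idx(residues)
  L <- length(idx)
  if (cfg$lambda >= L)
    stop("lambda (", cfg$lambda, ") must be smaller than window length ", L)
  std <- !is.na(idx)
  if (!any(std))
    stop("window contains no standard residues; composition undefined")
  f <- tabulate(idx[std], nbins = 20L)
  f <- f / sum(f)
  P <- as.matrix(table[, c("H1", "H2", "M")])[idx, , drop = FALSE]  # NA rows
  b <- numeric(cfg$lambda)
  for (j in seq_len(cfg$lambda)) {
    i1 <- seq_len(L - j)
    d2 <- (P[i1, , drop = FALSE] - P[i1 + j, , drop = FALSE])^2
    theta <- rowMeans(d2)  # mean of the three squared differences
    ok <- !is.na(theta)
    b[j] <- if (any(ok)) sum(theta[ok]) / sum(ok) else 0
  }
  denom <- 1 + cfg$w * sum(b)
  c(f / denom, cfg$w * b / denom)
}

#' PSSM feature block
#'
#' Flattens the window-aligned 21 x 20 conservation-score matrix row-major
#' (residue-major: S_1A, S_1R, ..., S_1V, S_2A, ...; 420 values) and
#' appends the 20 per-column means over the 21 rows, giving 440 features.
#'
#' @param window_pssm Numeric matrix with one row per window position and
#'   20 columns in canonical amino-acid order (see [slice_profile()]).
#' @return Numeric vector of length `nrow * 20 + 20`.
#' @export
encode_pssm <- function(window_pssm) {
  if (!is.matrix(window_pssm) || ncol(window_pssm) != 20L)
    stop("window PSSM must be a matrix with 20 columns, got ",
         paste(dim(window_pssm), collapse = " x "))
  c(as.vector(t(window_pssm)), colMeans(window_pssm))
}

#' Fuse encoder blocks into the full feature vector
#'
#' @param blocks Named list with elements `CKSAAP`, `disorder`, `PseAAC`,
#'   `PSSM`, each a numeric vector of the block's dimensionality.
#' @param layout A [feature_layout()].
#' @return Named numeric vector of length `attr(layout, "total")` (2501 by
#'   default), names from [feature_names()].
#' @export
fuse_features <- function(blocks, layout = feature_layout()) {
  missing <- setdiff(layout$block, names(blocks))
  if (length(missing))
    stop("missing encoder block(s): ", paste(missing, collapse = ", "))
  for (i in seq_len(nrow(layout))) {
    b <- layout$block[i]
    if (length(blocks[[b]]) != layout$dim[i])
      stop("block ", b, " has length ", length(blocks[[b]]),
           ", expected ", layout$dim[i])
  }
  v <- unlist(blocks[layout$block], use.names = FALSE)
  if (!all(is.finite(v))) stop("non-finite value in fused feature vector")
  names(v) <- feature_names(
    window_length = layout$dim[layout$block == "disorder"],
    cksaap = cksaap_config(layout$dim[layout$block == "CKSAAP"] / 400L - 1L),
    pseaac = pseaac_config(layout$dim[layout$block == "PseAAC"] - 20L))
  v
}

#' Encode a window table into the fused feature matrix
#'
#' Runs all four encoders over every window and fuses the blocks. PSSM and
#' disorder profiles are supplied as lists keyed by protein id and are
#' sliced per window ([slice_profile()]).
#'
#' @param windows Window data frame ([extract_windows_all()]).
#' @param pssms Named list of `pssm_profile` objects, keyed by protein id.
#' @param disorder Named list of `disorder_profile` objects, same keys.
#' @param cksaap,pseaac Encoder configurations.
#' @param aaindex Property table for PseAAC.
#' @return Numeric matrix, one row per window, 2501 named columns, with the
#'   window labels attached as attribute `labels` (factor, NA when
#'   unlabeled).
#' @export
encode_windows <- function(windows, pssms, disorder,
                           cksaap = cksaap_config(),
                           pseaac = pseaac_config(),
                           aaindex = aaindex_table()) {
  wlen <- nchar(windows$residues[1])
  layout <- feature_layout(wlen, cksaap, pseaac)
  X <- matrix(NA_real_, nrow(windows), attr(layout, "total"))
  colnames(X) <- feature_names(wlen, cksaap, pseaac)
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, , drop = FALSE]
    pid <- w$protein_id
    if (is.null(pssms[[pid]])) stop("no PSSM profile for protein ", pid)
    if (is.null(disorder[[pid]])) stop("no disorder profile for protein ", pid)
    X[i, ] <- fuse_features(list(
      CKSAAP = encode_cksaap(w$residues, cksaap),
      disorder = encode_disorder(slice_profile(disorder[[pid]], w)),
      PseAAC = encode_pseaac(w$residues, aaindex, pseaac),
      PSSM = encode_pssm(slice_profile(pssms[[pid]], w))), layout)
  }
  attr(X, "labels") <- windows$label
  X
}

#' Write / read an encoded feature matrix
#'
#' `write_feature_matrix()` writes one row per window with named feature
#' columns and the label last, as TSV (`format = "tsv"`) or as an RDS
#' sidecar (`format = "rds"`) for fast reload; `read_feature_matrix()`
#' inverts either. Both round-trip the matrix, column names and labels.
#'
#' @param X Feature matrix with `labels` attribute (see [encode_windows()]).
#' @param path Output path.
#' @param format `"tsv"` or `"rds"`.
#' @return `path` invisibly (write); the matrix with `labels` attribute
#'   (read).
#' @export
write_feature_matrix <- function(X, path, format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") { saveRDS(X, path); return(invisible(path)) }
  df <- as.data.frame(X, check.names = FALSE)
  df$label <- as.character(attr(X, "labels"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") return(readRDS(path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  lab <- factor(df$label, levels = c("negative", "positive"))
  df$label <- NULL
  X <- as.matrix(df)
  attr(X, "labels") <- lab
  X
}
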