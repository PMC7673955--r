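## profile_io: parsers for per-protein PSSM and disorder predictor output,
## plus slicing of whole-protein profiles down to 21-residue windows.

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the standard `-out_ascii_pssm` dialect: a two-line preamble, a
#' header row of 40 amino-acid letters (20 log-odds columns followed by 20
#' weighted-percentage columns), one row per residue (index, residue letter,
#' 20 integers, 20 percentages, optional trailing statistics), then summary
#' lines. The 20 log-odds columns become the score matrix; the percentage
#' columns, divided by 100, become the frequency matrix (the PSFM).
#' Columns are remapped from the file's header order to the canonical
#' amino-acid order ([aa_alphabet()]) so feature positions are stable
#' across PSI-BLAST versions.
#'
#' @param path Path to the ASCII PSSM file.
#' @param protein_id Identifier to attach; defaults to the file name without
#'   extension.
#' @return An object of class `pssm_profile`: a list with `protein_id`,
#'   `residues` (character vector), `scores` (L x 20 numeric matrix,
#'   canonical column order) and `frequencies` (L x 20, in \[0, 1\]).
#' @export
#' @examples
#' p <- read_ascii_pssm(system.file("extdata", "example.pssm",
#'                                  package = "succpred"))
#' dim(p$scores)
read_ascii_pssm <- function(path, protein_id = NULL) {
  if (is.null(protein_id))
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  header_i <- NA_integer_
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) == 40L && all(tok %in% AA20)) { header_i <- i; break }
  }
  if (is.na(header_i))
    stop("not a PSI-BLAST ASCII PSSM (no 40-letter header row): ", path)
  col_order <- strsplit(trimws(lines[header_i]), "\\s+")[[1]][1:20]

  scores <- list(); freqs <- list(); residues <- character()
  i <- header_i + 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") break
    tok <- strsplit(ln, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", tok[1])) break  # summary statistics block
    if (length(tok) < 42L)
      stop("malformed PSSM row at line ", i, " of ", path,
           ": expected at least 42 fields, got ", length(tok))
    vals <- suppressWarnings(as.numeric(tok[3:42]))
    if (anyNA(vals))
      stop("non-numeric PSSM value at line ", i, " of ", path)
    residues <- c(residues, tok[2])
    scores[[length(scores) + 1L]] <- vals[1:20]
    freqs[[length(freqs) + 1L]] <- vals[21:40] / 100
    i <- i + 1L
  }
  if (length(scores) == 0L)
    stop("no residue rows found in PSSM file: ", path)
  S <- do.call(rbind, scores)
  Fq <- do.call(rbind, freqs)
  remap <- match(AA20, col_order)
  S <- S[, remap, drop = FALSE]
  Fq <- Fq[, remap, drop = FALSE]
  colnames(S) <- AA20; colnames(Fq) <- AA20
  structure(list(protein_id = protein_id, residues = residues,
                 scores = S, frequencies = Fq),
            class = "pssm_profile")
}

#' Write a PSI-BLAST-style ASCII PSSM file
#'
#' Emits the same dialect [read_ascii_pssm()] reads (preamble, 40-letter
#' header, per-residue rows with 20 log-odds and 20 percentage columns,
#' trailing statistics). Used by the synthetic-data generator; also serves
#' as executable documentation of the format.
#'
#' @param profile A `pssm_profile` (scores required; frequencies optional,
#'   defaulting to zero).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_pssm <- function(profile, path) {
  S <- profile$scores
  Fq <- profile$frequencies
  if (is.null(Fq)) Fq <- matrix(0, nrow(S), 20L)
  res <- profile$residues
  if (is.null(res)) res <- rep("A", nrow(S))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position,",
          "and relative weight of gapless real matches to pseudocounts")),
    con)
  writeLines(paste0("           ",
                    paste(sprintf("%3s", c(AA20, AA20)), collapse = "")), con)
  for (i in seq_len(nrow(S))) {
    writeLines(paste0(sprintf("%5d %s ", i, res[i]),
                      paste(sprintf("%4d", as.integer(round(S[i, ]))),
                            collapse = ""),
                      " ",
                      paste(sprintf("%4d", as.integer(round(Fq[i, ] * 100))),
                            collapse = ""),
                      sprintf("  %5.2f %9.2f", 0, 0)), con)
  }
  writeLines(c("", "                      K         Lambda",
               "Standard Ungapped    0.1347     0.3176",
               "Standard Gapped      0.0410     0.2670"), con)
  invisible(path)
}

#' Read a per-residue disorder score table
#'
#' Reads the TSV emitted by VSL2B-like disorder predictors: columns
#' `residue_index`, `residue`, `score`, one row per residue, scores in
#' \[0, 1\]. A header line is detected and skipped if present.
#'
#' @param path Path to the TSV file.
#' @param protein_id Identifier to attach; defaults to the file name without
#'   extension.
#' @return An object of class `disorder_profile`: list with `protein_id`,
#'   `residues`, `scores` (numeric vector in \[0, 1\]).
#' @export
#' @examples
#' d <- read_disorder_profile(system.file("extdata", "example_disorder.tsv",
#'                                        package = "succpred"))
#' d$scores
read_disorder_profile <- function(path, protein_id = NULL) {
  if (is.null(protein_id))
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z_]{2,}", sub("\t.*", "", first))
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("disorder table needs 3 columns ",
                          "(residue_index, residue, score): ", path)
  names(df)[1:3] <- c("residue_index", "residue", "score")
  if (!is.numeric(df$score) || anyNA(df$score))
    stop("non-numeric disorder score in ", path)
  if (any(df$score < 0 | df$score > 1))
    stop("disorder scores must lie in [0, 1]: ", path)
  if (!identical(as.integer(df$residue_index), seq_len(nrow(df))))
    stop("disorder residue_index must be 1..L in order: ", path)
  structure(list(protein_id = protein_id, residues = df$residue,
                 scores = df$score),
            class = "disorder_profile")
}

#' Write a per-residue disorder score table
#'
#' @param profile A `disorder_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_disorder_profile <- function(profile, path) {
  df <- data.frame(residue_index = seq_along(profile$scores),
                   residue = if (is.null(profile$residues))
                     rep("A", length(profile$scores)) else profile$residues,
                   score = profile$scores)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Slice a whole-protein profile to a window
#'
#' Aligns a per-residue profile to the 21 positions of a peptide window.
#' Padded positions (beyond the protein termini) are filled with zero rows
#' (PSSM) or score 0 (disorder) — zero is the neutral element for both the
#' flattened and the averaged PSSM features.
#'
#' @param profile A `pssm_profile` or `disorder_profile`.
#' @param window One row of a window data frame (see [extract_windows()]).
#' @return For a PSSM: a `(2r+1) x 20` matrix. For disorder: a numeric
#'   vector of length `2r + 1`.
#' @export
slice_profile <- function(profile, window) {
  if (profile$protein_id != window$protein_id)
    stop("profile/window protein_id mismatch: ", profile$protein_id,
         " vs ", window$protein_id)
  wlen <- nchar(window$residues)
  r <- (wlen - 1L) %/% 2L
  pos <- (window$center_position - r):(window$center_position + r)
  L <- if (inherits(profile, "pssm_profile")) nrow(profile$scores)
       else length(profile$scores)
  inside <- pos >= 1L & pos <= L
  if (inherits(profile, "pssm_profile")) {
    out <- matrix(0, wlen, 20L, dimnames = list(NULL, AA20))
    out[inside, ] <- profile$scores[pos[inside], , drop = FALSE]
    out
  } else {
    out <- numeric(wlen)
    out[inside] <- profile$scores[pos[inside]]
    out
  }
}
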