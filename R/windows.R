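## peptide_windows: lysine-centered fixed-length fragments.
##
## A "window" is a 2r+1-residue fragment centered on a candidate lysine
## (r = 10 by default, so 21 residues). Windows truncated by a protein
## terminus are padded with 'X'; padding counts are recorded so downstream
## encoders can treat padded positions as missing data.

#' Read protein sequences from a FASTA file
#'
#' Reads a multi-record, possibly line-wrapped FASTA file of amino-acid
#' sequences. Trailing '*' stop characters are stripped; sequences are
#' upper-cased. The record identifier is the first whitespace-delimited
#' token of the header.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` and `sequence`.
#' @export
read_fasta_proteins <- function(path) {
  aset <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aset), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(gsub("\\*", "", as.character(aset)))
  if (anyDuplicated(ids))
    stop("duplicate protein ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(nchar(seqs) == 0L)) stop("empty sequence in FASTA: ", path)
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Read a site label table
#'
#' Reads a TSV of candidate sites with columns `protein_id`, `position`
#' (1-based residue index) and `label` (1 = positive / modified,
#' 0 = negative). A header line is detected and skipped if present.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `protein_id` (character), `position`
#'   (integer), `label` (factor with levels `negative`, `positive`).
#' @export
read_site_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("protein_id", first, fixed = TRUE)
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) names(df)[1:3] <- c("protein_id", "position", "label")
  if (!all(c("protein_id", "position", "label") %in% names(df)))
    stop("site table must have columns protein_id, position, label: ", path)
  if (!all(df$label %in% c(0L, 1L)))
    stop("site labels must be 0 or 1: ", path)
  data.frame(protein_id = as.character(df$protein_id),
             position = as.integer(df$position),
             label = factor(ifelse(df$label == 1L, "positive", "negative"),
                            levels = c("negative", "positive")),
             stringsAsFactors = FALSE)
}

## Build one padded window string around `pos` (1-based) in `sequence`.
.window_at <- function(sequence, pos, r) {
  L <- nchar(sequence)
  lo <- pos - r
  hi <- pos + r
  pad_l <- max(0L, 1L - lo)
  pad_r <- max(0L, hi - L)
  core <- substr(sequence, max(1L, lo), min(L, hi))
  list(residues = paste0(strrep(PAD_CHAR, pad_l), core, strrep(PAD_CHAR, pad_r)),
       n_pad_left = pad_l, n_pad_right = pad_r)
}

#' Extract labeled lysine-centered windows
#'
#' For each labeled site, extracts the `2r + 1`-residue fragment centered on
#' that position. Sites truncated by a protein terminus are padded with
#' `'X'` and the pad counts recorded. A site whose position is out of range,
#' or that does not point at a lysine (K), is a hard error: silently
#' relabeling or skipping such sites would corrupt a training set.
#'
#' @param protein A one-row data frame (or list) with `id` and `sequence`,
#'   as returned by [read_fasta_proteins()].
#' @param sites Data frame with columns `protein_id`, `position`, `label`
#'   (see [read_site_table()]); only rows matching `protein$id` are used.
#' @param r Number of residues taken on each side of the lysine
#'   (default 10, giving 21-residue windows).
#' @return A data frame of windows, one row per site, in the order of the
#'   input site list, with columns `protein_id`, `center_position`,
#'   `residues`, `n_pad_left`, `n_pad_right`, `label`.
#' @export
#' @examples
#' prot <- data.frame(id = "P1", sequence = "KAAAAAAAAAAAAAAAAAAAA")
#' sites <- data.frame(protein_id = "P1", position = 1,
#'                     label = factor("positive", c("negative", "positive")))
#' extract_windows(prot, sites)$residues  # "XXXXXXXXXXKAAAAAAAAAA"
extract_windows <- function(protein, sites, r = 10L) {
  stopifnot(r >= 1L)
  sites <- sites[sites$protein_id == protein$id, , drop = FALSE]
  n <- nrow(sites)
  L <- nchar(protein$sequence)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- sites$position[i]
    if (is.na(pos) || pos < 1L || pos > L)
      stop("site position out of range: protein ", protein$id,
           " position ", pos, " (length ", L, ")")
    if (substr(protein$sequence, pos, pos) != "K")
      stop("site does not point at a lysine: protein ", protein$id,
           " position ", pos, " is '",
           substr(protein$sequence, pos, pos), "'")
    w <- .window_at(protein$sequence, pos, r)
    out[[i]] <- data.frame(protein_id = protein$id, center_position = pos,
                           residues = w$residues,
                           n_pad_left = w$n_pad_left,
                           n_pad_right = w$n_pad_right,
                           label = as.character(sites$label[i]),
                           stringsAsFactors = FALSE)
  }
  res <- if (n == 0L) {
    data.frame(protein_id = character(), center_position = integer(),
               residues = character(), n_pad_left = integer(),
               n_pad_right = integer(), label = character(),
               stringsAsFactors = FALSE)
  } else do.call(rbind, out)
  res$label <- factor(res$label, levels = c("negative", "positive"))
  res
}

#' Scan every lysine of a protein into unlabeled windows
#'
#' Prediction-mode counterpart of [extract_windows()]: emits one unlabeled
#' window per lysine in the sequence, with the same `'X'` padding rule at
#' the termini.
#'
#' @inheritParams extract_windows
#' @return A window data frame as in [extract_windows()], with `label` NA.
#' @export
scan_all_lysines <- function(protein, r = 10L) {
  positions <- which(strsplit(protein$sequence, "")[[1]] == "K")
  sites <- data.frame(protein_id = rep(protein$id, length(positions)),
                      position = positions,
                      label = factor(rep(NA_character_, length(positions)),
                                     levels = c("negative", "positive")),
                      stringsAsFactors = FALSE)
  extract_windows(protein, sites, r = r)
}

#' Extract windows for a whole dataset
#'
#' Convenience wrapper applying [extract_windows()] across all proteins,
#' preserving the order of the site table.
#'
#' @param proteins Data frame from [read_fasta_proteins()].
#' @param sites Data frame from [read_site_table()].
#' @param r Window radius (default 10).
#' @return Window data frame, one row per site row, in site-table order.
#' @export
extract_windows_all <- function(proteins, sites, r = 10L) {
  missing <- setdiff(unique(sites$protein_id), proteins$id)
  if (length(missing))
    stop("sites reference unknown proteins: ", paste(missing, collapse = ", "))
  key <- split(seq_len(nrow(sites)), sites$protein_id)
  pieces <- lapply(names(key), function(pid) {
    prot <- proteins[proteins$id == pid, , drop = FALSE]
    w <- extract_windows(prot, sites[key[[pid]], , drop = FALSE], r = r)
    w$.orig <- key[[pid]]
    w
  })
  res <- do.call(rbind, pieces)
  res <- res[order(res$.orig), , drop = FALSE]
  res$.orig <- NULL
  rownames(res) <- NULL
  res
}
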