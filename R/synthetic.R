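## synthetic_data: labeled peptide datasets with controllable class signal,
## written in the same three formats the real pipeline reads (FASTA,
## PSI-BLAST ASCII PSSM, disorder TSV), so every stage is testable without
## any external predictor run or database download.

#' Background amino-acid frequencies
#'
#' `"uniform"` gives 1/20 per residue; `"swissprot"` gives the overall
#' Swiss-Prot composition (release-averaged percentages, a realistic
#' background for protein-like sequences).
#'
#' @param type `"uniform"` or `"swissprot"`.
#' @return Named numeric vector over the 20 amino acids, summing to 1.
#' @export
aa_background <- function(type = c("uniform", "swissprot")) {
  type <- match.arg(type)
  if (type == "uniform")
    return(stats::setNames(rep(1 / 20, 20), AA20))
  f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93,
         E = 6.72, G = 7.07, H = 2.27, I = 5.91, L = 9.65, K = 5.80,
         M = 2.41, F = 3.86, P = 4.74, S = 6.65, T = 5.36, W = 1.10,
         Y = 2.92, V = 6.86)
  f[AA20] / sum(f)
}

#' Specification for a synthetic succinylation dataset
#'
#' Each sample is an independent `2r + 1`-residue protein with a central
#' lysine. Class signal enters through three controllable channels:
#' sequence motif enrichment (per-rule: at `offset` from the center, set
#' the residue to `residue` with probability `prob` in positive samples),
#' PSSM score shifts (`pssm_signal` added, in positive samples, to the
#' motif residue's column at the motif offset's row), and class-dependent
#' disorder score means. With no motif rules, `pssm_signal = 0` and equal
#' disorder means the generator is an exact no-signal null. Default sample
#' counts mirror the published succinylation training sets (5049 positive,
#' 5526 negative sites).
#'
#' @param n_positive,n_negative Sample counts per class.
#' @param r Window radius (default 10; windows of 21).
#' @param motif Data frame with columns `offset` (in -r..r, nonzero),
#'   `residue` (standard AA) and `prob` (enrichment probability in
#'   \[0, 1\]); NULL for none.
#' @param background Named amino-acid frequency vector
#'   ([aa_background()]).
#' @param pssm_signal Integer added to planted PSSM cells of positive
#'   samples (default 0).
#' @param pssm_range Range of the background PSSM log-odds integers
#'   (default c(-5, 5), within the conventional \[-10, 10\] span).
#' @param disorder_means Length-2 named vector, mean disorder score per
#'   class (default 0.5 / 0.5).
#' @param disorder_sd Spread of disorder scores around the class mean
#'   before clamping to \[0, 1\] (default 0.15).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_positive = 5049L, n_negative = 5526L, r = 10L,
                           motif = NULL,
                           background = aa_background("uniform"),
                           pssm_signal = 0, pssm_range = c(-5L, 5L),
                           disorder_means = c(positive = 0.5,
                                              negative = 0.5),
                           disorder_sd = 0.15, seed = 0L) {
  stopifnot(n_positive >= 1L, n_negative >= 1L, r >= 1L)
  if (!is.null(motif)) {
    stopifnot(all(c("offset", "residue", "prob") %in% names(motif)),
              all(abs(motif$offset) <= r), all(motif$offset != 0),
              all(motif$residue %in% AA20),
              all(motif$prob >= 0 & motif$prob <= 1))
  }
  stopifnot(abs(sum(background) - 1) < 1e-8,
            identical(names(background), AA20),
            all(c("positive", "negative") %in% names(disorder_means)),
            all(disorder_means >= 0 & disorder_means <= 1))
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative), r = as.integer(r),
                 motif = motif, background = background,
                 pssm_signal = pssm_signal, pssm_range = pssm_range,
                 disorder_means = disorder_means,
                 disorder_sd = disorder_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic dataset
#'
#' Draws the dataset defined by a [synthetic_spec()]. In-memory objects are
#' always returned; when `dir` is given, the four artifacts are also
#' written in the formats the pipeline readers consume —
#' `proteins.fasta`, `sites.tsv`, `pssm/<id>.pssm` (PSI-BLAST ASCII
#' dialect) and `disorder/<id>.tsv` — and round-trip through
#' [read_fasta_proteins()], [read_site_table()], [read_ascii_pssm()] and
#' [read_disorder_profile()].
#'
#' @param spec A `synthetic_spec`.
#' @param dir Output directory (created if missing), or NULL for in-memory
#'   only.
#' @return List with `proteins`, `sites`, `windows` (data frames),
#'   `pssms`, `disorder` (lists keyed by protein id), `planted_features`
#'   (global names of the PSSM cells carrying `pssm_signal`, empty when no
#'   signal), and `paths` when written.
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_positive + spec$n_negative
  wlen <- 2L * spec$r + 1L
  center <- spec$r + 1L
  labels <- c(rep("positive", spec$n_positive),
              rep("negative", spec$n_negative))
  ids <- sprintf("S%05d", seq_len(n))

  proteins <- vector("list", n); pssms <- vector("list", n)
  disorder <- vector("list", n)
  withr::with_seed(spec$seed, {
    for (i in seq_len(n)) {
      seq_i <- sample(AA20, wlen, replace = TRUE, prob = spec$background)
      seq_i[center] <- "K"
      if (labels[i] == "positive" && !is.null(spec$motif)) {
        for (m in seq_len(nrow(spec$motif))) {
          if (stats::runif(1) < spec$motif$prob[m])
            seq_i[center + spec$motif$offset[m]] <- spec$motif$residue[m]
        }
      }
      S <- matrix(sample(spec$pssm_range[1]:spec$pssm_range[2],
                         wlen * 20L, replace = TRUE), wlen, 20L,
                  dimnames = list(NULL, AA20))
      if (labels[i] == "positive" && spec$pssm_signal != 0 &&
          !is.null(spec$motif)) {
        for (m in seq_len(nrow(spec$motif)))
          S[center + spec$motif$offset[m], spec$motif$residue[m]] <-
            S[center + spec$motif$offset[m], spec$motif$residue[m]] +
            spec$pssm_signal
      }
      Fq <- t(apply(S, 1, function(row) {
        e <- exp(row / 2); e / sum(e)
      }))
      dis <- pmin(1, pmax(0, stats::rnorm(
        wlen, spec$disorder_means[[labels[i]]], spec$disorder_sd)))
      proteins[[i]] <- paste(seq_i, collapse = "")
      pssms[[i]] <- structure(list(protein_id = ids[i], residues = seq_i,
                                   scores = S, frequencies = Fq),
                              class = "pssm_profile")
      disorder[[i]] <- structure(list(protein_id = ids[i],
                                      residues = seq_i, scores = dis),
                                 class = "disorder_profile")
    }
  })
  prot_df <- data.frame(id = ids, sequence = unlist(proteins),
                        stringsAsFactors = FALSE)
  sites <- data.frame(protein_id = ids, position = center,
                      label = factor(labels,
                                     levels = c("negative", "positive")),
                      stringsAsFactors = FALSE)
  names(pssms) <- ids; names(disorder) <- ids
  windows <- extract_windows_all(prot_df, sites, r = spec$r)

  planted <- character(0)
  if (!is.null(spec$motif) && spec$pssm_signal != 0) {
    rows <- center + spec$motif$offset
    cols <- match(spec$motif$residue, AA20)
    local_idx <- (rows - 1L) * 20L + cols
    nm <- feature_names(window_length = wlen)
    pssm_block <- nm[grepl("^PSSM:", nm)]
    planted <- pssm_block[local_idx]
  }

  out <- list(proteins = prot_df, sites = sites, windows = windows,
              pssms = pssms, disorder = disorder,
              planted_features = planted)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "pssm"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "disorder"), showWarnings = FALSE)
    fasta <- file.path(dir, "proteins.fasta")
    writeLines(paste0(">", prot_df$id, "\n", prot_df$sequence), fasta)
    sites_path <- file.path(dir, "sites.tsv")
    utils::write.table(
      data.frame(protein_id = sites$protein_id, position = sites$position,
                 label = as.integer(sites$label == "positive")),
      sites_path, sep = "\t", quote = FALSE, row.names = FALSE)
    for (id in ids) {
      write_ascii_pssm(pssms[[id]], file.path(dir, "pssm",
                                              paste0(id, ".pssm")))
      write_disorder_profile(disorder[[id]],
                             file.path(dir, "disorder",
                                       paste0(id, ".tsv")))
    }
    out$paths <- list(fasta = fasta, sites = sites_path,
                      pssm_dir = file.path(dir, "pssm"),
                      disorder_dir = file.path(dir, "disorder"))
  }
  out
}

#' Random confusion tables for metric fuzz tests
#'
#' Draws `n` non-degenerate confusion tables (each count uniform on
#' 0..`max_count`, resampled if all four are zero).
#'
#' @param n Number of tables.
#' @param seed Integer seed.
#' @param max_count Largest count per cell (default 200).
#' @return List of [confusion_counts()] objects.
#' @export
generate_confusion_tables <- function(n, seed = 0L, max_count = 200L) {
  if (n == 0L) return(list())
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      repeat {
        v <- sample.int(max_count + 1L, 4L, replace = TRUE) - 1L
        if (sum(v) >= 1L) break
      }
      confusion_counts(v[1], v[2], v[3], v[4])
    })
  })
}
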