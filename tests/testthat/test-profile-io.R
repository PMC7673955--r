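# A hand-written ASCII PSSM in the PSI-BLAST dialect, with a column order
# different from the canonical one on purpose? No: PSI-BLAST always prints
# A R N D C Q E G H I L K M F P S T W Y V; rows here use score i+j so the
# remap and cell order are both checked.
make_pssm_text <- function(L = 5, score_fun = function(i, j) 0) {
  aa <- aa_alphabet()
  header <- paste0("           ", paste(sprintf("%3s", c(aa, aa)), collapse = ""))
  rows <- vapply(seq_len(L), function(i) {
    sc <- vapply(1:20, function(j) score_fun(i, j), numeric(1))
    paste0(sprintf("%5d %s ", i, "A"),
           paste(sprintf("%3d", as.integer(sc)), collapse = ""), " ",
           paste(sprintf("%4d", rep(5L, 20)), collapse = ""),
           "  0.30      0.10")
  }, character(1))
  c("", "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    header, rows, "", "                      K         Lambda",
    "Standard Ungapped    0.1347     0.3176")
}

test_that("an all-zero ASCII PSSM parses to a zero score matrix", {
  path <- withr::local_tempfile(fileext = ".pssm")
  writeLines(make_pssm_text(5), path)
  p <- read_ascii_pssm(path, "P1")
  expect_s3_class(p, "pssm_profile")
  expect_equal(dim(p$scores), c(5L, 20L))
  expect_true(all(p$scores == 0))
  expect_true(all(p$frequencies == 0.05))
})

test_that("every parsed cell reproduces the written value (i + j fixture)", {
  path <- withr::local_tempfile(fileext = ".pssm")
  writeLines(make_pssm_text(7, function(i, j) i + j), path)
  p <- read_ascii_pssm(path, "P1")
  expected <- outer(1:7, 1:20, `+`)
  expect_equal(unname(p$scores), expected)
})

test_that("a row with missing score columns is a parse error naming the line", {
  txt <- make_pssm_text(4)
  txt[6] <- substr(txt[6], 1, 40)  # truncate the 3rd residue row
  path <- withr::local_tempfile(fileext = ".pssm")
  writeLines(txt, path)
  expect_error(read_ascii_pssm(path), "line 6")
})

test_that("writer and reader are inverse on scores and frequencies", {
  set.seed(7)
  for (i in 1:5) {
    L <- sample(5:30, 1)
    prof <- structure(list(protein_id = "Q",
                           residues = sample(aa_alphabet(), L, TRUE),
                           scores = matrix(sample(-10:10, L * 20, TRUE), L, 20),
                           frequencies = matrix(sample(0:100, L * 20, TRUE) / 100,
                                                L, 20)),
                      class = "pssm_profile")
    path <- withr::local_tempfile(fileext = ".pssm")
    write_ascii_pssm(prof, path)
    back <- read_ascii_pssm(path, "Q")
    expect_equal(unname(back$scores), unname(prof$scores))
    expect_equal(unname(back$frequencies), unname(prof$frequencies))
  }
})

test_that("disorder tables round-trip and enforce the [0,1] range", {
  prof <- structure(list(protein_id = "D1", residues = rep("A", 6),
                         scores = c(0, 0.2, 0.5, 0.77, 1, 0.31)),
                    class = "disorder_profile")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_disorder_profile(prof, path)
  back <- read_disorder_profile(path, "D1")
  expect_equal(back$scores, prof$scores)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("residue_index\tresidue\tscore", "1\tA\t1.2"), bad)
  expect_error(read_disorder_profile(bad), "\\[0, 1\\]")
})

test_that("slicing an unpadded window takes rows center-r .. center+r in order", {
  L <- 60
  prof <- structure(list(protein_id = "P", residues = rep("A", L),
                         scores = matrix(seq_len(L * 20), L, 20),
                         frequencies = NULL),
                    class = "pssm_profile")
  w <- data.frame(protein_id = "P", center_position = 30L,
                  residues = strrep("A", 21), n_pad_left = 0L,
                  n_pad_right = 0L)
  s <- slice_profile(prof, w)
  expect_equal(dim(s), c(21L, 20L))
  expect_equal(unname(s), unname(prof$scores[20:40, ]))
})

test_that("padded positions slice to zero rows / zero scores", {
  L <- 12
  prof <- structure(list(protein_id = "P", residues = rep("A", L),
                         scores = matrix(1, L, 20), frequencies = NULL),
                    class = "pssm_profile")
  w <- data.frame(protein_id = "P", center_position = 8L,
                  residues = strrep("A", 21), n_pad_left = 3L,
                  n_pad_right = 6L)
  s <- slice_profile(prof, w)
  expect_equal(nrow(s), 21L)
  expect_true(all(s[1:3, ] == 0))
  expect_true(all(s[16:21, ] == 0))
  expect_true(all(s[4:15, ] == 1))

  dprof <- structure(list(protein_id = "P", residues = rep("A", L),
                          scores = rep(0.9, L)),
                     class = "disorder_profile")
  ds <- slice_profile(dprof, w)
  expect_equal(length(ds), 21L)
  expect_equal(ds, c(rep(0, 3), rep(0.9, 12), rep(0, 6)))
})

test_that("protein id mismatch between profile and window is an error", {
  prof <- structure(list(protein_id = "A", residues = "A",
                         scores = matrix(0, 1, 20), frequencies = NULL),
                    class = "pssm_profile")
  w <- data.frame(protein_id = "B", center_position = 1L,
                  residues = strrep("A", 21))
  expect_error(slice_profile(prof, w), "mismatch")
})
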