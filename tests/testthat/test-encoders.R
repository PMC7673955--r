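test_that("property table standardization has zero mean and unit SD over the 20 AAs", {
  tab <- aaindex_table()
  for (col in c("H1", "H2", "M")) {
    expect_lt(abs(mean(tab[[col]])), 1e-9)
    expect_lt(abs(sqrt(mean((tab[[col]] - mean(tab[[col]]))^2)) - 1), 1e-9)
  }
})

test_that("CKSAAP hand-counted example: A/K homopeptide window", {
  v <- encode_cksaap("AAAAAAAAAAKAAAAAAAAAA")
  nm <- feature_names()[1:2000]
  k0 <- v[1:400]
  names(k0) <- sub("^CKSAAP:\\d+:k0_", "", nm[1:400])
  expect_equal(unname(k0["AA"]), 18 / 20)
  expect_equal(unname(k0["AK"]), 1 / 20)
  expect_equal(unname(k0["KA"]), 1 / 20)
  expect_equal(sum(k0), 1)
  expect_true(all(k0[setdiff(names(k0), c("AA", "AK", "KA"))] == 0))
})

test_that("CKSAAP of an all-pad window is zero; denominators unchanged", {
  v <- encode_cksaap(strrep("X", 21))
  expect_equal(length(v), 2000L)
  expect_true(all(v == 0))
})

test_that("CKSAAP per-k blocks sum to one on standard-alphabet windows", {
  set.seed(3)
  for (i in 1:10) {
    v <- encode_cksaap(random_window())
    for (k in 0:4) expect_equal(sum(v[k * 400 + 1:400]), 1)
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("CKSAAP matches the loop oracle, including ambiguous and padded windows", {
  set.seed(11)
  wins <- c(replicate(6, random_window()),
            replicate(3, random_window(pads = 5)),
            replicate(3, random_window(pads = 2, ambig = 3)))
  for (win in wins)
    expect_equal(encode_cksaap(win), oracle_cksaap(win), tolerance = 1e-12)
})

test_that("windows shorter than k_max + 2 are rejected", {
  expect_error(encode_cksaap("AKAX", cksaap_config(4)), "too short")
})

test_that("disorder encoding is an identity with range validation", {
  expect_equal(encode_disorder(rep(0.5, 21)), rep(0.5, 21))
  s <- seq(0, 1, length.out = 21)
  expect_equal(encode_disorder(s), s)
  expect_error(encode_disorder(c(rep(0.5, 20), 1.3)), "\\[0, 1\\]")
})

test_that("PseAAC of a homopolymer has zero correlation factors and unit composition", {
  p <- encode_pseaac(strrep("A", 21))
  expect_equal(length(p), 40L)
  expect_equal(unname(p[1]), 1)        # A is first in canonical order
  expect_true(all(p[-1] == 0))         # all b_j vanish
})

test_that("PseAAC output length is 20 + lambda and components sum to one", {
  set.seed(5)
  for (i in 1:8) {
    win <- random_window()
    p <- encode_pseaac(win)
    expect_equal(length(p), 40L)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    lam5 <- encode_pseaac(win, cfg = pseaac_config(lambda = 5))
    expect_equal(length(lam5), 25L)
    expect_equal(sum(lam5), 1, tolerance = 1e-9)
  }
})

test_that("PseAAC matches the literal formula oracle", {
  win <- "ARNDCQEGHILKMFPSTWYVK"
  expect_equal(encode_pseaac(win, cfg = pseaac_config(lambda = 2, w = 0.05)),
               unname(oracle_pseaac(win, lambda = 2, w = 0.05)),
               tolerance = 1e-12)
  set.seed(13)
  for (i in 1:6) {
    win <- random_window()
    expect_equal(encode_pseaac(win),
                 unname(oracle_pseaac(win, lambda = 20, w = 0.05)),
                 tolerance = 1e-12)
  }
  # padded windows: dropped terms with divisor reduction
  for (i in 1:4) {
    win <- random_window(pads = 6)
    expect_equal(encode_pseaac(win),
                 unname(oracle_pseaac(win, lambda = 20, w = 0.05)),
                 tolerance = 1e-12)
  }
})

test_that("PseAAC lambda = 20 with a 21-residue window (single-pair last tier) is allowed", {
  win <- random_window()
  p <- encode_pseaac(win, cfg = pseaac_config(lambda = 20))
  expect_equal(length(p), 40L)
  expect_true(all(is.finite(p)))
  expect_error(encode_pseaac(win, cfg = pseaac_config(lambda = 21)),
               "smaller than window length")
  expect_error(encode_pseaac(strrep("X", 21)), "no standard residues")
})

test_that("PSSM encoding flattens row-major then appends column means", {
  expect_equal(encode_pssm(matrix(0, 21, 20)), rep(0, 440))
  M <- matrix(rep(1:20, each = 21), 21, 20)
  e <- encode_pssm(M)
  expect_equal(length(e), 440L)
  expect_equal(e[421:440], as.numeric(1:20))
  expect_equal(e[1:20], as.numeric(1:20))  # first row, row-major
  expect_error(encode_pssm(matrix(0, 21, 19)), "20 columns")
})

test_that("PSSM encoder equals the loop oracle on random matrices", {
  set.seed(17)
  for (i in 1:10) {
    M <- matrix(sample(-10:10, 21 * 20, TRUE), 21, 20)
    expect_equal(encode_pssm(M), oracle_pssm(M), tolerance = 1e-12)
  }
})

test_that("fusion concatenates blocks in layout order with stable global names", {
  lay <- feature_layout()
  v <- fuse_features(list(CKSAAP = rep(0, 2000), disorder = rep(0, 21),
                          PseAAC = rep(0, 40), PSSM = rep(0, 440)), lay)
  expect_equal(length(v), 2501L)
  expect_true(all(v == 0))
  expect_match(names(v)[2001], "^disorder:1:")
  expect_match(names(v)[1], "^CKSAAP:1:k0_AA$")
  expect_match(names(v)[2501], "^PSSM:440:mean_V$")
  expect_error(fuse_features(list(CKSAAP = rep(0, 2000))), "missing")
  expect_error(fuse_features(list(CKSAAP = rep(0, 3), disorder = rep(0, 21),
                                  PseAAC = rep(0, 40), PSSM = rep(0, 440))),
               "length")
})

test_that("encoders are pure: identical input gives bit-identical output", {
  win <- random_window()
  expect_identical(encode_cksaap(win), encode_cksaap(win))
  expect_identical(encode_pseaac(win), encode_pseaac(win))
  M <- matrix(rnorm(420), 21, 20)
  expect_identical(encode_pssm(M), encode_pssm(M))
})

test_that("feature matrices round-trip through TSV and RDS", {
  ds <- tiny_dataset(4, 4)
  X <- encode_windows(ds$windows, ds$pssms, ds$disorder)
  expect_equal(dim(X), c(8L, 2501L))
  for (fmt in c("tsv", "rds")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_feature_matrix(X, path, fmt)
    back <- read_feature_matrix(path, fmt)
    expect_equal(unname(back), unname(X), tolerance = 1e-12)
    expect_equal(colnames(back), colnames(X))
    expect_equal(attr(back, "labels"), attr(X, "labels"))
  }
})
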