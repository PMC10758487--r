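test_that("one-hot, chemical-property and EIIP encoders reproduce the canonical mappings", {
  oh <- encode_one_hot(c("A", "U", "G", "C", "N"))
  expect_equal(unname(oh), rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0),
                                 c(0, 0, 0, 1), c(0, 0, 0, 0)))
  cp <- encode_chemprop(c("A", "U", "G", "C", "N"))
  expect_equal(unname(cp), rbind(c(1, 1, 1), c(0, 0, 1), c(0, 1, 0),
                                 c(1, 0, 0), c(0, 0, 0)))
  expect_equal(unname(encode_eiip("AUGC")[1, ]), c(0.1260, 0.1335, 0.0806, 0.1340))
  expect_equal(unname(encode_eiip("NN")[1, ]), c(0, 0))
})

test_that("per-encoder dimensionality at 41 nt matches the construction", {
  w <- random_windows(3, L = 41, seed = 1)
  expect_identical(ncol(encode_one_hot(w)), 164L)
  expect_identical(ncol(encode_chemprop(w)), 123L)
  expect_identical(ncol(encode_eiip(w)), 41L)
  expect_identical(ncol(encode_conposi(w)), 16L)
  expect_identical(ncol(encode_anf(w)), 41L)
  expect_identical(ncol(encode_autocor(w)), 12L)       # 6 properties x 2 lags
  expect_identical(ncol(encode_crosscor(w)), 60L)      # 6*5 ordered pairs x 2 lags
  expect_identical(ncol(encode_pseknc(w)), 19L)        # 4^2 + 3
})

test_that("dinucleotide composition is a frequency vector excluding N steps", {
  v <- encode_conposi("AAAA")[1, ]
  expect_equal(unname(v["CONPOSI.AA"]), 1.0)
  expect_equal(sum(v), 1.0)

  v2 <- encode_conposi("AUAU")[1, ]
  expect_equal(unname(v2["CONPOSI.AU"]), 2 / 3)
  expect_equal(unname(v2["CONPOSI.UA"]), 1 / 3)

  # N-containing dinucleotides drop out of numerator and denominator
  v3 <- encode_conposi("ANAU")[1, ]
  expect_equal(unname(v3["CONPOSI.AU"]), 1.0)
  expect_equal(sum(encode_conposi("NNNN")), 0)

  for (w in random_windows(5, L = 41, seed = 2))
    expect_equal(sum(encode_conposi(w)), 1.0)
})

test_that("accumulated nucleotide frequency follows the prefix-count definition", {
  expect_equal(unname(encode_anf("GACG")[1, ]), c(1, 1 / 2, 1 / 3, 2 / 4))
  expect_equal(unname(encode_anf("UUUU")[1, ]), rep(1, 4))
  w <- random_windows(5, L = 21, seed = 3)
  a <- encode_anf(w)
  expect_true(all(a[, 1] == 1))            # first position count is always 1
  expect_true(all(a > 0 & a <= 1))
  expect_equal(unname(encode_anf("NAAN")[1, ]), c(0, 1 / 2, 2 / 3, 0))
})

test_that("the bundled property table standardizes to mean 0, sd 1 per row", {
  raw <- dhu_properties(standardize = FALSE)
  expect_identical(dim(raw), c(6L, 16L))
  std <- dhu_properties()
  expect_true(all(abs(rowMeans(std)) < 1e-9))
  expect_true(all(abs(apply(std, 1, sd) - 1) < 1e-9))
  expect_error(standardize_properties(matrix(1, 2, 16,
    dimnames = list(NULL, colnames(raw)))), "constant")
})

test_that("auto-covariance matches a brute-force double loop and vanishes on constant series", {
  props <- dhu_properties()
  # all dinucleotides identical -> zero deviations -> all AC terms zero
  expect_equal(max(abs(encode_autocor("AAAAAAAA", props))), 0)
  for (w in random_windows(25, L = 21, seed = 4)) {
    expect_equal(unname(encode_autocor(w, props)[1, ]),
                 brute_autocor(w, props), tolerance = 1e-10)
  }
  # N-padded windows still agree with the N-aware oracle
  w <- paste0("NNN", substr(random_windows(1, L = 15, seed = 5), 4, 15))
  expect_equal(unname(encode_autocor(w, props)[1, ]),
               brute_autocor(w, props), tolerance = 1e-10)
  expect_error(encode_autocor("NNUNN", props), "non-N")
})

test_that("cross-covariance matches brute force and degenerates to AC for duplicated properties", {
  props <- dhu_properties()
  for (w in random_windows(15, L = 21, seed = 6)) {
    expect_equal(unname(encode_crosscor(w, props)[1, ]),
                 brute_crosscor(w, props), tolerance = 1e-10)
  }
  dupe <- props[c(1, 1), ]
  rownames(dupe) <- c("p1", "p2")
  w <- random_windows(1, L = 21, seed = 7)
  cc <- encode_crosscor(w, dupe)
  ac <- encode_autocor(w, props[1, , drop = FALSE])
  expect_equal(unname(cc[1, 1:2]), unname(ac[1, 1:2]), tolerance = 1e-12)
})

test_that("PseKNC reduces to k-mer frequencies at w = 0 and matches a hand-built theta", {
  w <- random_windows(4, L = 21, seed = 8)
  p0 <- encode_pseknc(w, w = 0)
  expect_equal(unname(rowSums(p0[, 1:16])), rep(1, 4))
  expect_true(all(p0[, 17:19] == 0))

  props <- dhu_properties()
  toy <- "AUGCAUGC"
  enc <- encode_pseknc(toy, k = 2, lam = 1, w = 0.1, props = props)
  expect_identical(ncol(enc), 17L)
  # brute-force theta_1: mean over adjacent dinucleotide pairs of the mean
  # squared property difference
  ch <- strsplit(toy, "")[[1]]
  di <- paste0(ch[-8], ch[-1])
  th <- mean(sapply(1:6, function(i) mean((props[, di[i]] - props[, di[i + 1]])^2)))
  f <- tabulate(factor(di, levels = sub("PseKNC\\.", "", colnames(enc)[1:16])), 16) / 7
  expect_equal(unname(enc[1, 17]), 0.1 * th / (1 + 0.1 * th), tolerance = 1e-12)
  expect_equal(unname(enc[1, 1:16]), f / (1 + 0.1 * th), tolerance = 1e-12)

  expect_error(encode_pseknc("AUGCU", k = 2, lam = 3), "too large")
  expect_error(encode_pseknc(toy, k = 3, lam = 2), "require k = 2")
})

test_that("encoders are pure functions and concatenation preserves order and descriptors", {
  w <- rep(random_windows(1, L = 41, seed = 9), 2)
  x <- encode_windows(w)
  expect_identical(x[1, ], x[2, ])
  expect_identical(ncol(x), 476L)
  expect_identical(unique(feature_encoder(x)), dhu_encoders())

  x2 <- encode_windows(w, c("EIIP", "CONPOSI"))
  expect_identical(ncol(x2), 57L)
  expect_identical(feature_encoder(x2), rep(c("EIIP", "CONPOSI"), c(41, 16)))

  expect_error(encode_windows(w, c("EIIP", "EIIP")), "duplicate")
  expect_error(encode_windows(w, "nope"), "unknown")

  empty <- encode_windows(character(0), c("EIIP", "PseKNC"), window_length = 41)
  expect_identical(dim(empty), c(0L, 60L))
  expect_identical(ncol(empty), 41L + 19L)
})

test_that("feature matrices survive a TSV round trip", {
  x <- encode_windows(random_windows(4, L = 21, seed = 10), c("EIIP", "CONPOSI"))
  tf <- tempfile(fileext = ".tsv")
  write_features(x, tf)
  back <- read_features(tf)
  expect_identical(colnames(back), colnames(x))
  expect_equal(back, x, tolerance = 1e-12, ignore_attr = TRUE)
})
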