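test_that("FASTA reading normalizes case and alphabet and survives a round trip", {
  tf <- tempfile(fileext = ".fa")
  writeLines(c(">tx1", "acgt", ">tx2 some description", "AUGCN"), tf)
  seqs <- read_fasta(tf)
  expect_identical(seqs, c(tx1 = "ACGU", tx2 = "AUGCN"))

  out <- tempfile(fileext = ".fa")
  write_fasta(seqs, out)
  expect_identical(read_fasta(out), seqs)
})

test_that("FASTA contract errors: duplicate IDs, bad characters, missing/empty file", {
  tf <- tempfile(fileext = ".fa")
  writeLines(c(">a", "AU", ">a", "GC"), tf)
  expect_error(read_fasta(tf), "duplicate")
  writeLines(c(">a", "AXGC"), tf)
  expect_error(read_fasta(tf), "outside")
  expect_error(read_fasta(tempfile()), "not found")
  file.create(tf2 <- tempfile(fileext = ".fa"))
  expect_error(read_fasta(tf2))
})

test_that("window extraction centers on U, pads with N, and respects the default flank", {
  expect_identical(extract_window("AAUAA", 3, flank = 2), "AAUAA")
  expect_identical(extract_window("UA", 1, flank = 2), "NNUAN")
  tx <- paste(rep("A", 100), collapse = "")
  substr(tx, 50, 50) <- "U"
  expect_identical(nchar(extract_window(tx, 50)), 41L)
  expect_error(extract_window("AAUAA", 2), "must be 'U'")
  expect_error(extract_window("AAUAA", 9), "out of range")
})

test_that("random extractions always satisfy the window invariants", {
  set.seed(42)
  for (rep in 1:40) {
    tx <- paste(sample(c("A", "C", "G", "U"), 80, replace = TRUE), collapse = "")
    upos <- which(strsplit(tx, "")[[1]] == "U")
    if (!length(upos)) next
    for (p in sample(upos, min(25, length(upos)))) {
      w <- extract_window(tx, p, flank = 7)
      expect_identical(nchar(w), 15L)
      expect_identical(substr(w, 8, 8), "U")
      expect_false(grepl("[^ACGUN]", w))
    }
  }
})

test_that("negative sampling is disjoint, exact at ratio 1, seeded, and fails on exhaustion", {
  set.seed(1)
  tx <- c(t1 = paste(sample(c("A", "U", "G", "C"), 200, replace = TRUE), collapse = ""),
          t2 = paste(sample(c("A", "U", "G", "C"), 200, replace = TRUE), collapse = ""))
  upos <- lapply(tx, function(s) which(strsplit(s, "")[[1]] == "U"))
  pos <- data.frame(transcript_id = rep(names(tx), c(5, 5)),
                    position = c(upos$t1[1:5], upos$t2[1:5]),
                    label = "positive", stringsAsFactors = FALSE)
  neg <- sample_negatives(tx, pos, ratio = 1, seed = 9)
  expect_identical(nrow(neg), 10L)
  expect_length(intersect(paste(neg$transcript_id, neg$position),
                          paste(pos$transcript_id, pos$position)), 0L)
  neg2 <- sample_negatives(tx, pos, ratio = 1, seed = 9)
  expect_identical(neg, neg2)
  expect_false(identical(neg, sample_negatives(tx, pos, ratio = 1, seed = 10)))

  # zero positives legitimately yields zero negatives
  expect_identical(nrow(sample_negatives(tx, pos[0, ], ratio = 1, seed = 1)), 0L)
  # a uridine-free transcriptome cannot supply negatives
  allA <- c(t1 = strrep("A", 100))
  expect_error(sample_negatives(allA, data.frame(transcript_id = "t1", position = 1,
                                                 label = "positive"),
                                ratio = 1, seed = 1), "not enough")
})

test_that("stratified split hits the per-class test counts and ignores input order", {
  w <- random_windows(200, L = 21, seed = 3)
  ds <- dhu_dataset(w, rep(c(1, 0), each = 100))
  sp <- split_dataset(ds, test_fraction = 0.2, seed = 5)
  expect_identical(sum(sp$partition == "test" & sp$labels == 1), 20L)
  expect_identical(sum(sp$partition == "test" & sp$labels == 0), 20L)

  sp0 <- split_dataset(ds, test_fraction = 0, seed = 5)
  expect_identical(sum(sp0$partition == "test"), 0L)

  # permuting rows must not change which windows land in the test set
  perm <- sample(200)
  ds_p <- dhu_dataset(w[perm], ds$labels[perm])
  sp_p <- split_dataset(ds_p, test_fraction = 0.2, seed = 5)
  expect_setequal(sp_p$windows[sp_p$partition == "test"],
                  sp$windows[sp$partition == "test"])

  tiny <- dhu_dataset(w[1:8], c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_error(split_dataset(tiny, 0.2, seed = 1), ">= 5 samples")
})

test_that("dataset validation enforces the window invariants", {
  expect_error(dhu_dataset(c("AAUAA", "AAAAA"), c(1, 0)), "center")
  expect_error(dhu_dataset("AUUA", 1), "odd")
  expect_error(dhu_dataset(c("AAUAA", "AAUAAAA"), c(1, 0)), "one odd length")
  expect_error(dhu_dataset("AAUAA", 2), "0/1")
})

test_that("window FASTA round trip preserves sequences, labels and provenance", {
  ds <- dhu_dataset(random_windows(6, L = 11, seed = 4), rep(c(1, 0), 3),
                    transcript_id = paste0("tx", 1:6), position = 101:106)
  tf <- tempfile(fileext = ".fa")
  write_windows_fasta(ds, tf)
  back <- read_windows_fasta(tf)
  expect_identical(back$windows, ds$windows)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$position, ds$position)
})

test_that("site tables round-trip and BED import shifts coordinates", {
  sites <- data.frame(transcript_id = c("a", "b"), position = c(5L, 9L),
                      label = c("positive", "negative"), stringsAsFactors = FALSE)
  tf <- tempfile(fileext = ".tsv")
  write_sites(sites, tf)
  expect_identical(read_sites(tf), sites)

  bed <- tempfile(fileext = ".bed")
  writeLines(c("a\t4\t5", "b\t8\t9"), bed)
  imported <- read_sites(bed, bed = TRUE)
  expect_identical(imported$position, c(5L, 9L))
  expect_true(all(imported$label == "positive"))
})
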