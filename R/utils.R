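# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

RNA_ALPHABET <- c("A", "C", "G", "U", "N")
RNA_BASES <- c("A", "U", "G", "C")   # canonical channel order for encoders

# Split window strings into a character matrix, one row per window.
seq_to_matrix <- function(windows) {
  L <- unique(nchar(windows))
  if (length(L) != 1L)
    stop("all windows must have equal length; got lengths ", paste(L, collapse = ", "))
  matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
         nrow = length(windows), ncol = L, byrow = TRUE)
}

check_alphabet <- function(seqs, where = "sequence") {
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad))
    stop(where, " contains characters outside {A,C,G,U,N}: first offender index ",
         which(bad)[1L])
  invisible(seqs)
}

# Normalize raw nucleotide text: uppercase, DNA T -> RNA U.
normalize_rna <- function(seqs) {
  seqs <- chartr("t", "T", toupper(seqs))
  chartr("T", "U", seqs)
}

check_binary_labels <- function(labels, n = NULL) {
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1")
  labels <- as.integer(labels)
  if (!is.null(n) && length(labels) != n)
    stop("labels length (", length(labels), ") does not match number of samples (", n, ")")
  labels
}

# Stratified fold assignment, reproducible under seed.
stratified_folds <- function(labels, folds, seed) {
  labels <- check_binary_labels(labels)
  if (folds < 2L) stop("folds must be >= 2")
  if (min(table(labels)) < folds)
    stop("fold count (", folds, ") exceeds size of the smaller class (",
         min(table(labels)), ")")
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- which(labels == cl)
      assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  assign
}
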