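#' Read transcript sequences from FASTA
#'
#' Reads a FASTA file of transcript sequences and normalizes them for
#' downstream window extraction: sequences are uppercased and DNA thymine is
#' mapped to RNA uridine. Any residue outside \code{A,C,G,U,N} is an error
#' rather than being silently masked, and duplicated record identifiers are
#' rejected.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one sequence per transcript, over the
#'   alphabet \code{A,C,G,U,N}.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">tx1", "acgt"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate transcript ID(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- normalize_rna(as.character(set))
  names(seqs) <- ids
  check_alphabet(seqs, where = paste0("FASTA '", path, "'"))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read a site table
#'
#' Site tables are tab-separated with a header line
#' \code{transcript_id<TAB>position<TAB>label}; positions are 1-based on the
#' transcript and labels are \code{positive} or \code{negative}. With
#' \code{bed = TRUE} a 3-column BED-like file (0-based start, start+1 end) is
#' accepted instead and converted to 1-based positions; such rows are labeled
#' \code{positive}.
#'
#' @param path Path to the TSV file.
#' @param bed Interpret the file as 3-column BED-like input (0-based).
#' @return A data.frame with columns \code{transcript_id}, \code{position}
#'   (integer, 1-based), \code{label} (\code{"positive"}/\code{"negative"}).
#' @export
read_sites <- function(path, bed = FALSE) {
  if (bed) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 3L) stop("BED-like input needs >= 3 columns")
    out <- data.frame(transcript_id = as.character(df[[1L]]),
                      position = as.integer(df[[2L]]) + 1L,
                      label = "positive", stringsAsFactors = FALSE)
    return(out)
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("transcript_id", "position", "label")
  if (!all(need %in% names(df)))
    stop("site table must have header columns: ", paste(need, collapse = ", "))
  df$position <- as.integer(df$position)
  if (!all(df$label %in% c("positive", "negative")))
    stop("site labels must be 'positive' or 'negative'")
  df[need]
}

#' Write a site table
#' @param sites Data.frame as returned by [read_sites()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites[c("transcript_id", "position", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a uridine-centered sequence window
#'
#' Extracts the window of \code{2*flank + 1} nucleotides centered on a
#' candidate uridine. Positions beyond the transcript ends are padded with
#' \code{N} so every site yields a window of identical length.
#'
#' @param transcript A single sequence string (RNA alphabet).
#' @param position 1-based position of the candidate uridine.
#' @param flank Number of nucleotides kept on each side (default 20, giving
#'   41-nt windows).
#' @return A window string of length \code{2*flank + 1} whose central
#'   character is \code{U}.
#' @examples
#' extract_window("AAUAA", 3, flank = 2)
#' extract_window("UA", 1, flank = 2)  # "NNUAN"
#' @export
extract_window <- function(transcript, position, flank = 20L) {
  stopifnot(length(transcript) == 1L, length(position) == 1L)
  n <- nchar(transcript)
  position <- as.integer(position)
  if (position < 1L || position > n)
    stop("position ", position, " out of range 1..", n)
  base <- substr(transcript, position, position)
  if (base != "U")
    stop("window center must be 'U'; found '", base, "' at position ", position)
  lo <- position - flank
  hi <- position + flank
  core <- substr(transcript, max(lo, 1L), min(hi, n))
  paste0(strrep("N", max(0L, 1L - lo)), core, strrep("N", max(0L, hi - n)))
}

#' Labeled window dataset
#'
#' Container binding extracted windows to their labels, provenance and an
#' optional train/test partition. This is the object the whole pipeline
#' consumes.
#'
#' @param windows Character vector of equal-length, odd-length windows with a
#'   central \code{U}.
#' @param labels Aligned 0/1 vector (1 = modified / positive class).
#' @param transcript_id,position Optional provenance (recycled NA otherwise).
#' @param partition Optional aligned vector of \code{"train"}/\code{"test"}.
#' @param seed Seed recorded for provenance.
#' @return An object of class \code{dhu_dataset}.
#' @export
dhu_dataset <- function(windows, labels, transcript_id = NA_character_,
                        position = NA_integer_, partition = NULL, seed = NA_integer_) {
  windows <- toupper(as.character(windows))
  n <- length(windows)
  labels <- check_binary_labels(labels, n)
  check_alphabet(windows, "window")
  L <- unique(nchar(windows))
  if (length(L) != 1L || L %% 2L == 0L)
    stop("windows must share one odd length; got ", paste(L, collapse = ","))
  center <- substr(windows, (L + 1L) %/% 2L, (L + 1L) %/% 2L)
  if (!all(center == "U"))
    stop("every window must have 'U' at its center; ",
         sum(center != "U"), " window(s) do not")
  if (!is.null(partition)) {
    if (length(partition) != n || !all(partition %in% c("train", "test")))
      stop("partition must align with windows and contain only 'train'/'test'")
  }
  structure(list(windows = windows,
                 labels = labels,
                 transcript_id = rep_len(transcript_id, n),
                 position = rep_len(as.integer(position), n),
                 partition = partition,
                 window_length = L,
                 seed = seed),
            class = "dhu_dataset")
}

#' @export
print.dhu_dataset <- function(x, ...) {
  cat("<dhu_dataset> ", length(x$windows), " windows of ", x$window_length,
      " nt (", sum(x$labels == 1L), " positive / ", sum(x$labels == 0L),
      " negative)\n", sep = "")
  if (!is.null(x$partition))
    cat("  partition: ", sum(x$partition == "train"), " train / ",
        sum(x$partition == "test"), " test\n", sep = "")
  invisible(x)
}

#' @export
length.dhu_dataset <- function(x) length(x$windows)

#' Subset a window dataset
#' @param x A \code{dhu_dataset}.
#' @param i Index vector.
#' @param ... Unused.
#' @return A \code{dhu_dataset} restricted to \code{i}.
#' @export
`[.dhu_dataset` <- function(x, i, ...) {
  dhu_dataset(x$windows[i], x$labels[i], x$transcript_id[i], x$position[i],
              partition = if (!is.null(x$partition)) x$partition[i],
              seed = x$seed)
}

#' Extract all windows for a site table
#'
#' @param transcriptome Named character vector from [read_fasta()].
#' @param sites Site table data.frame ([read_sites()]).
#' @param flank Flank size (default 20).
#' @param seed Seed recorded on the resulting dataset.
#' @return A [dhu_dataset()].
#' @export
extract_dataset <- function(transcriptome, sites, flank = 20L, seed = NA_integer_) {
  missing <- setdiff(unique(sites$transcript_id), names(transcriptome))
  if (length(missing))
    stop("site table references transcripts absent from FASTA: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  windows <- mapply(function(id, pos) extract_window(transcriptome[[id]], pos, flank),
                    sites$transcript_id, sites$position, USE.NAMES = FALSE)
  dhu_dataset(windows, as.integer(sites$label == "positive"),
              transcript_id = sites$transcript_id, position = sites$position,
              seed = seed)
}

#' Sample unmodified uridines as negative sites
#'
#' Draws unmodified uridine positions uniformly without replacement from the
#' transcriptome, disjoint from the positive sites, at \code{ratio} negatives
#' per positive (the framework default is a balanced 1:1 design). By default
#' the draw is restricted to transcripts that carry at least one positive
#' site; \code{scope = "all"} widens it to the whole transcriptome.
#'
#' @param transcriptome Named character vector from [read_fasta()].
#' @param positives Site table rows of positive sites.
#' @param ratio Negatives per positive (default 1).
#' @param seed Integer seed; the same seed reproduces the same draw.
#' @param scope \code{"positive_transcripts"} (default) or \code{"all"}.
#' @return Data.frame of sampled sites labeled \code{"negative"}.
#' @export
sample_negatives <- function(transcriptome, positives, ratio = 1.0, seed,
                             scope = c("positive_transcripts", "all")) {
  scope <- match.arg(scope)
  ids <- if (scope == "all") names(transcriptome)
         else intersect(names(transcriptome), unique(positives$transcript_id))
  pool <- do.call(rbind, lapply(ids, function(id) {
    pos <- which(strsplit(transcriptome[[id]], "", fixed = TRUE)[[1L]] == "U")
    if (!length(pos)) return(NULL)
    data.frame(transcript_id = id, position = pos, stringsAsFactors = FALSE)
  }))
  key <- function(d) paste(d$transcript_id, d$position)
  if (!is.null(pool)) pool <- pool[!(key(pool) %in% key(positives)), , drop = FALSE]
  n_needed <- round(ratio * nrow(positives))
  empty <- data.frame(transcript_id = character(0), position = integer(0),
                      label = character(0), stringsAsFactors = FALSE)
  if (n_needed == 0L) return(empty)
  n_avail <- if (is.null(pool)) 0L else nrow(pool)
  if (n_avail < n_needed)
    stop("not enough unmodified uridines to sample: need ", n_needed,
         ", available ", n_avail, " (shortfall ", n_needed - n_avail, ")")
  take <- with_seed(seed, sample.int(n_avail, n_needed))
  out <- pool[take, , drop = FALSE]
  out$label <- "negative"
  rownames(out) <- NULL
  out
}

#' Stratified train/test split
#'
#' Assigns each window to the training or independent-test partition,
#' stratified by class. Windows are put into a canonical order (by sequence,
#' then provenance) before shuffling, so the partition depends only on the
#' dataset content and the seed, not on input row order.
#'
#' @param dataset A [dhu_dataset()].
#' @param test_fraction Fraction per class held out for testing (default 0.2).
#' @param seed Integer seed.
#' @return The dataset with its \code{partition} populated.
#' @export
split_dataset <- function(dataset, test_fraction = 0.2, seed) {
  stopifnot(inherits(dataset, "dhu_dataset"))
  if (test_fraction < 0 || test_fraction >= 1)
    stop("test_fraction must be in [0, 1)")
  labels <- dataset$labels
  for (cl in c(0L, 1L)) {
    if (test_fraction > 0 && sum(labels == cl) < 5L)
      stop("need >= 5 samples per class to split; class ", cl, " has ",
           sum(labels == cl))
  }
  ord <- order(dataset$windows, dataset$transcript_id, dataset$position,
               method = "radix")
  part <- rep("train", length(labels))
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- ord[labels[ord] == cl]
      n_test <- round(test_fraction * length(idx))
      if (n_test > 0L) part[sample(idx, n_test)] <- "test"
    }
  })
  dataset$partition <- part
  dataset$seed <- seed
  dataset
}

#' Write dataset windows as FASTA
#'
#' Headers follow \code{transcriptID:position:label} so provenance survives a
#' round trip through FASTA.
#' @param dataset A [dhu_dataset()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_windows_fasta <- function(dataset, path) {
  id <- ifelse(is.na(dataset$transcript_id), "window", dataset$transcript_id)
  pos <- ifelse(is.na(dataset$position), seq_along(dataset$windows), dataset$position)
  lab <- ifelse(dataset$labels == 1L, "positive", "negative")
  seqs <- dataset$windows
  names(seqs) <- paste(id, pos, lab, sep = ":")
  write_fasta(seqs, path)
}

#' Read dataset windows from FASTA written by [write_windows_fasta()]
#' @param path FASTA path.
#' @return A [dhu_dataset()] (no partition).
#' @export
read_windows_fasta <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), ":", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop("window FASTA headers must be 'transcriptID:position:label'; bad header: ",
         names(seqs)[which(bad)[1L]])
  lab <- vapply(parts, function(p) p[[3L]], "")
  if (!all(lab %in% c("positive", "negative")))
    stop("window FASTA labels must be 'positive'/'negative'")
  dhu_dataset(unname(seqs), as.integer(lab == "positive"),
              transcript_id = vapply(parts, `[[`, "", 1L),
              position = as.integer(vapply(parts, `[[`, "", 2L)))
}
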