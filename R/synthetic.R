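# Synthetic motif-planted data: uridine-centered windows whose positive
# class carries a flanking motif of tunable strength, so every pipeline
# stage is testable (and its null behaviour checkable) without external
# sequencing data.

#' Configuration for the synthetic window generator
#'
#' Positives carry the motif with per-position probability
#' \code{motif_strength} (probabilistic planting makes classification
#' difficulty tunable); negatives are pure background. Both classes have a
#' central uridine, mirroring real candidate sites where the center carries
#' no information.
#'
#' @param n_positive,n_negative Class sizes (default 200 + 200).
#' @param window_length Odd window length (default 41).
#' @param motif Motif string over A, U, G, C (default \code{"GAGA"}, a
#'   GA-rich flank as seen around real dihydrouridine sites).
#' @param offset Start of the motif relative to the central uridine
#'   (0 = starts at the center; default -6).
#' @param motif_strength Per-position probability that the motif letter
#'   replaces background in a positive window (default 0.9).
#' @param background Length-4 nucleotide probability vector (A, U, G, C),
#'   summing to 1 (default uniform).
#' @param seed Integer seed; all generator randomness flows from it.
#' @return Object of class \code{dhu_syn_config}.
#' @export
synthetic_config <- function(n_positive = 200L, n_negative = 200L,
                             window_length = 41L, motif = "GAGA",
                             offset = -6L, motif_strength = 0.9,
                             background = c(0.25, 0.25, 0.25, 0.25),
                             seed = 1L) {
  window_length <- as.integer(window_length)
  if (window_length %% 2L == 0L || window_length < 3L)
    stop("window_length must be odd and >= 3")
  if (abs(sum(background) - 1) > 1e-8 || length(background) != 4L ||
      any(background < 0))
    stop("background must be 4 non-negative probabilities summing to 1")
  if (motif_strength < 0 || motif_strength > 1)
    stop("motif_strength must be in [0, 1]")
  letters_ <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
  if (!all(letters_ %in% RNA_BASES)) stop("motif must be over {A,U,G,C}")
  center <- (window_length + 1L) %/% 2L
  cols <- center + offset + seq_along(letters_) - 1L
  if (any(cols < 1L | cols > window_length))
    stop("motif at offset ", offset, " falls outside the window")
  if (any(cols == center & letters_ != "U"))
    stop("motif would overwrite the central U with '",
         letters_[cols == center], "'")
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 window_length = window_length, motif = letters_,
                 offset = as.integer(offset), motif_strength = motif_strength,
                 background = background / sum(background),
                 seed = as.integer(seed)),
            class = "dhu_syn_config")
}

#' Generate labeled synthetic windows
#'
#' @param config A [synthetic_config()].
#' @return A [dhu_dataset()] with positives first, reproducible under the
#'   config seed.
#' @export
generate_windows <- function(config) {
  stopifnot(inherits(config, "dhu_syn_config"))
  n <- config$n_positive + config$n_negative
  L <- config$window_length
  center <- (L + 1L) %/% 2L
  with_seed(config$seed, {
    m <- matrix(sample(RNA_BASES, n * L, replace = TRUE, prob = config$background),
                n, L)
    m[, center] <- "U"
    cols <- center + config$offset + seq_along(config$motif) - 1L
    for (j in seq_along(cols)) {
      plant <- stats::runif(config$n_positive) < config$motif_strength
      m[seq_len(config$n_positive)[plant], cols[j]] <- config$motif[j]
    }
    m[, center] <- "U"
    dhu_dataset(apply(m, 1L, paste, collapse = ""),
                rep(c(1L, 0L), c(config$n_positive, config$n_negative)),
                seed = config$seed)
  })
}

#' Generate a synthetic transcriptome with embedded positive sites
#'
#' Builds background transcripts and splices the positive windows of
#' [generate_windows()] into non-overlapping slots (round-robin across
#' transcripts), so the FASTA + site-table extraction path can be exercised
#' end to end: extracting the listed sites reproduces the planted windows
#' exactly.
#'
#' @param config A [synthetic_config()].
#' @param n_transcripts Number of transcripts (default 10).
#' @param transcript_length Length of each transcript (default 600).
#' @return List with \code{transcripts} (named character vector),
#'   \code{sites} (positive site table) and \code{windows} (the planted
#'   [dhu_dataset()] restricted to positives).
#' @export
generate_transcriptome <- function(config, n_transcripts = 10L,
                                   transcript_length = 600L) {
  stopifnot(inherits(config, "dhu_syn_config"))
  L <- config$window_length
  flank <- (L - 1L) %/% 2L
  slots_per_tx <- transcript_length %/% L
  capacity <- n_transcripts * slots_per_tx
  if (config$n_positive > capacity)
    stop("requested ", config$n_positive, " sites exceed capacity ",
         capacity, " (", n_transcripts, " transcripts x ", slots_per_tx,
         " slots); lengthen or add transcripts")
  ds <- generate_windows(config)
  pos <- ds[ds$labels == 1L]
  tx <- with_seed(config$seed + 1L, {
    vapply(seq_len(n_transcripts), function(i)
      paste(sample(RNA_BASES, transcript_length, replace = TRUE,
                   prob = config$background), collapse = ""), "")
  })
  names(tx) <- sprintf("syn_tx%02d", seq_len(n_transcripts))
  sites <- data.frame(transcript_id = character(0), position = integer(0),
                      label = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(config$n_positive)) {
    t_i <- (i - 1L) %% n_transcripts + 1L
    slot <- (i - 1L) %/% n_transcripts
    start <- slot * L + 1L
    substr(tx[t_i], start, start + L - 1L) <- pos$windows[i]
    sites <- rbind(sites, data.frame(transcript_id = names(tx)[t_i],
                                     position = start + flank,
                                     label = "positive",
                                     stringsAsFactors = FALSE))
  }
  list(transcripts = tx, sites = sites, windows = pos)
}
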