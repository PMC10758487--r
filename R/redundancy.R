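#' Ungapped pairwise sequence identity
#'
#' Fraction of positions at which two equal-length windows carry the same
#' nucleotide. Windows in this framework are fixed-length and aligned on
#' their central uridine, so no alignment step is needed. \code{N} (padding)
#' matches nothing, including another \code{N}, so heavily padded windows are
#' conservatively treated as dissimilar.
#'
#' @param a,b Equal-length sequence strings.
#' @return Identity fraction in \code{[0, 1]}.
#' @examples
#' pairwise_identity("AUGC", "AUGG")  # 0.75
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("sequences must have equal length (", nchar(a), " vs ", nchar(b), ")")
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  sum(ca == cb & ca != "N") / length(ca)
}

#' Greedy redundancy reduction at an identity threshold
#'
#' Removes near-duplicate windows the way CD-HIT prunes redundant sequences:
#' windows are scanned in input order; each window joins the first retained
#' representative it matches at \code{>= threshold} identity, otherwise it
#' becomes a new representative. Because all windows share one length, the
#' usual longest-first ordering reduces to input order. The retained set is
#' mutually non-redundant: no two representatives reach the threshold.
#'
#' @param windows Character vector of equal-length windows, or a
#'   [dhu_dataset()].
#' @param threshold Identity threshold in \code{(0, 1]}; the default 0.85
#'   mirrors the conventional 85\% redundancy cutoff.
#' @return An object of class \code{dhu_clusters}: list with
#'   \code{representatives} (indices into the input), \code{members} (named
#'   list mapping each representative to the indices it absorbed, itself
#'   included) and \code{threshold}.
#' @export
reduce_redundancy <- function(windows, threshold = 0.85) {
  if (inherits(windows, "dhu_dataset")) windows <- windows$windows
  if (length(windows) < 1L) stop("need at least one window")
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]; got ", threshold)
  mat <- seq_to_matrix(windows)
  L <- ncol(mat)
  reps <- integer(0)
  members <- list()
  for (i in seq_along(windows)) {
    hit <- 0L
    for (r in reps) {
      ident <- sum(mat[i, ] == mat[r, ] & mat[i, ] != "N") / L
      if (ident >= threshold) { hit <- r; break }
    }
    if (hit == 0L) {
      reps <- c(reps, i)
      members[[as.character(i)]] <- i
    } else {
      members[[as.character(hit)]] <- c(members[[as.character(hit)]], i)
    }
  }
  structure(list(representatives = reps, members = members,
                 threshold = threshold),
            class = "dhu_clusters")
}

#' @export
print.dhu_clusters <- function(x, ...) {
  n <- sum(lengths(x$members))
  cat("<dhu_clusters> ", length(x$representatives), " representatives from ",
      n, " windows at identity < ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Write a cluster map as TSV
#' @param clusters A \code{dhu_clusters} object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_cluster_map <- function(clusters, path) {
  df <- do.call(rbind, lapply(names(clusters$members), function(rep) {
    data.frame(representative = as.integer(rep),
               member = clusters$members[[rep]])
  }))
  utils::write.table(df[order(df$member), ], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
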