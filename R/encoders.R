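# Eight sequence-derived feature encoders. Every encoder is a pure function
# of the window string(s): it returns a numeric matrix with one row per
# window and descriptive column names prefixed by the encoder name, so the
# encoder of any feature column can be recovered after subsetting with
# feature_encoder(). Padding 'N' never fabricates signal: positional
# channels emit zeros and composition/covariance terms exclude N-containing
# (di)nucleotides from both numerator and denominator.

#' Names of the available feature encoders
#' @return Character vector of the eight encoder names in canonical order.
#' @export
dhu_encoders <- function() {
  c("ONE_HOT", "ChemProper", "EIIP", "CONPOSI", "Frequency",
    "autoCor", "crossCor", "PseKNC")
}

#' Encoder of each feature column
#' @param features Column names of a feature matrix (or the matrix itself).
#' @return Character vector of encoder names, one per column.
#' @export
feature_encoder <- function(features) {
  if (is.matrix(features)) features <- colnames(features)
  sub("\\..*$", "", features)
}

#' One-hot (binary) encoding
#'
#' Each position becomes a four-channel indicator in A, U, G, C order:
#' A = (1,0,0,0), U = (0,1,0,0), G = (0,0,1,0), C = (0,0,0,1); padding N is
#' all-zero.
#'
#' @param windows Character vector of equal-length windows.
#' @return Numeric matrix, \code{length(windows)} x \code{4 * L}.
#' @export
encode_one_hot <- function(windows) {
  m <- seq_to_matrix(windows)
  L <- ncol(m)
  out <- matrix(0, nrow(m), 4L * L)
  for (j in seq_len(L))
    for (ch in seq_along(RNA_BASES))
      out[, (j - 1L) * 4L + ch] <- as.numeric(m[, j] == RNA_BASES[ch])
  colnames(out) <- paste0("ONE_HOT.p", sprintf("%02d", rep(seq_len(L), each = 4L)),
                          ".", rep(RNA_BASES, L))
  out
}

# Chemical-property triples exactly as conventionally printed for RNA.
CHEMPROP_MAP <- rbind(A = c(1, 1, 1), U = c(0, 0, 1), G = c(0, 1, 0),
                      C = c(1, 0, 0), N = c(0, 0, 0))

#' Chemical-property encoding
#'
#' Each position becomes the three-channel chemical descriptor
#' A = (1,1,1), U = (0,0,1), G = (0,1,0), C = (1,0,0), reflecting ring
#' structure, functional group (amino vs keto) and hydrogen-bond class;
#' padding N is all-zero.
#'
#' @inheritParams encode_one_hot
#' @return Numeric matrix, \code{length(windows)} x \code{3 * L}.
#' @export
encode_chemprop <- function(windows) {
  m <- seq_to_matrix(windows)
  L <- ncol(m)
  out <- matrix(0, nrow(m), 3L * L)
  for (j in seq_len(L))
    out[, (j - 1L) * 3L + 1:3] <- CHEMPROP_MAP[m[, j], , drop = FALSE]
  colnames(out) <- paste0("ChemProper.p", sprintf("%02d", rep(seq_len(L), each = 3L)),
                          ".ch", rep(1:3, L))
  out
}

EIIP_VALUES <- c(A = 0.1260, U = 0.1335, G = 0.0806, C = 0.1340, N = 0)

#' Electron-ion interaction pseudopotential (EIIP) encoding
#'
#' Each position becomes the EIIP scalar of its base: A 0.1260, U 0.1335,
#' G 0.0806, C 0.1340; padding N is 0.
#'
#' @inheritParams encode_one_hot
#' @return Numeric matrix, \code{length(windows)} x \code{L}.
#' @export
encode_eiip <- function(windows) {
  m <- seq_to_matrix(windows)
  out <- matrix(EIIP_VALUES[m], nrow(m), ncol(m))
  colnames(out) <- paste0("EIIP.p", sprintf("%02d", seq_len(ncol(m))))
  out
}

#' Dinucleotide composition (CONPOSI)
#'
#' Frequencies of the 16 dinucleotides among the \code{L - 1} overlapping
#' dinucleotides of the window. Dinucleotides containing N are excluded from
#' both numerator and denominator, so the vector sums to 1 whenever any
#' valid dinucleotide exists (and is all-zero otherwise).
#'
#' @inheritParams encode_one_hot
#' @return Numeric matrix, \code{length(windows)} x 16.
#' @export
encode_conposi <- function(windows) {
  m <- seq_to_matrix(windows)
  if (ncol(m) < 2L) stop("windows must have length >= 2 for dinucleotides")
  out <- matrix(0, nrow(m), 16L, dimnames = list(NULL, paste0("CONPOSI.", DINUCLEOTIDES)))
  for (i in seq_len(nrow(m))) {
    di <- paste0(m[i, -ncol(m)], m[i, -1L])
    di <- di[!grepl("N", di, fixed = TRUE)]
    if (length(di))
      out[i, ] <- tabulate(factor(di, levels = DINUCLEOTIDES), 16L) / length(di)
  }
  out
}

#' Accumulated nucleotide frequency (Frequency / ANF)
#'
#' At position \code{i}, the count of occurrences of the nucleotide found at
#' \code{i} among positions 1..\code{i}, divided by \code{i} — a positional
#' encoding sensitive to nucleotide order. Padding N yields 0 and never
#' contributes to counts.
#'
#' @inheritParams encode_one_hot
#' @return Numeric matrix, \code{length(windows)} x \code{L}.
#' @examples
#' encode_anf("GACG")  # 1, 1/2, 1/3, 2/4
#' @export
encode_anf <- function(windows) {
  m <- seq_to_matrix(windows)
  L <- ncol(m)
  out <- matrix(0, nrow(m), L)
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(L)) {
      b <- m[i, j]
      if (b != "N") out[i, j] <- sum(m[i, seq_len(j)] == b) / j
    }
  }
  colnames(out) <- paste0("Frequency.p", sprintf("%02d", seq_len(L)))
  out
}

# Per-window series of a property over the L-1 overlapping dinucleotides;
# NA where the dinucleotide contains N.
property_series <- function(chars, props) {
  di <- paste0(chars[-length(chars)], chars[-1L])
  ok <- !grepl("N", di, fixed = TRUE)
  sapply(seq_len(nrow(props)), function(u) {
    v <- rep(NA_real_, length(di))
    v[ok] <- props[u, di[ok]]
    v
  })
}

#' Dinucleotide auto-covariance (autoCor)
#'
#' For each physicochemical property \code{u} and lag \code{g}, the average
#' product of the property's deviations from its window mean between
#' dinucleotides \code{g} apart:
#' \deqn{AC(u, g) = \frac{1}{L-1-g} \sum_{i=1}^{L-1-g}
#'   (P_u(d_i) - \bar P_u)(P_u(d_{i+g}) - \bar P_u)}
#' where \eqn{d_i} is the i-th overlapping dinucleotide and \eqn{\bar P_u}
#' the mean of the property over the window's valid dinucleotides. Pairs
#' involving an N-containing dinucleotide are excluded from both the sum and
#' its denominator.
#'
#' @inheritParams encode_one_hot
#' @param props Standardized property table from [dhu_properties()].
#' @param max_lag Largest lag evaluated (default 2).
#' @return Numeric matrix, \code{length(windows)} x \code{nrow(props) * max_lag}.
#' @export
encode_autocor <- function(windows, props = dhu_properties(), max_lag = 2L) {
  m <- seq_to_matrix(windows)
  nprop <- nrow(props)
  out <- matrix(NA_real_, nrow(m), nprop * max_lag)
  for (i in seq_len(nrow(m))) {
    P <- property_series(m[i, ], props)          # (L-1) x nprop, NA at N
    Pc <- sweep(P, 2L, colMeans(P, na.rm = TRUE))
    col <- 0L
    for (u in seq_len(nprop)) for (g in seq_len(max_lag)) {
      col <- col + 1L
      x <- Pc[seq_len(nrow(Pc) - g), u]
      y <- Pc[(1L + g):nrow(Pc), u]
      ok <- !is.na(x) & !is.na(y)
      if (!any(ok))
        stop("window ", i, " has too few consecutive non-N positions for lag ", g)
      out[i, col] <- sum(x[ok] * y[ok]) / sum(ok)
    }
  }
  colnames(out) <- as.vector(t(outer(rownames(props), seq_len(max_lag),
                                     function(u, g) paste0("autoCor.", u, ".lag", g))))
  out
}

#' Dinucleotide cross-covariance (crossCor)
#'
#' The two-property analogue of [encode_autocor()]: for each ordered pair of
#' distinct properties \code{(u1, u2)} and lag \code{g},
#' \deqn{CC(u_1, u_2, g) = \frac{1}{L-1-g} \sum_i
#'   (P_{u_1}(d_i) - \bar P_{u_1})(P_{u_2}(d_{i+g}) - \bar P_{u_2}).}
#'
#' @inheritParams encode_autocor
#' @return Numeric matrix, \code{length(windows)} x
#'   \code{nrow(props) * (nrow(props)-1) * max_lag}.
#' @export
encode_crosscor <- function(windows, props = dhu_properties(), max_lag = 2L) {
  m <- seq_to_matrix(windows)
  nprop <- nrow(props)
  pairs <- expand.grid(u2 = seq_len(nprop), u1 = seq_len(nprop))[, 2:1]
  pairs <- pairs[pairs$u1 != pairs$u2, ]
  out <- matrix(NA_real_, nrow(m), nrow(pairs) * max_lag)
  cn <- character(nrow(pairs) * max_lag)
  for (i in seq_len(nrow(m))) {
    P <- property_series(m[i, ], props)
    Pc <- sweep(P, 2L, colMeans(P, na.rm = TRUE))
    col <- 0L
    for (p in seq_len(nrow(pairs))) for (g in seq_len(max_lag)) {
      col <- col + 1L
      u1 <- pairs$u1[p]; u2 <- pairs$u2[p]
      x <- Pc[seq_len(nrow(Pc) - g), u1]
      y <- Pc[(1L + g):nrow(Pc), u2]
      ok <- !is.na(x) & !is.na(y)
      if (!any(ok))
        stop("window ", i, " has too few consecutive non-N positions for lag ", g)
      out[i, col] <- sum(x[ok] * y[ok]) / sum(ok)
      if (i == 1L)
        cn[col] <- paste0("crossCor.", rownames(props)[u1], ".",
                          rownames(props)[u2], ".lag", g)
    }
  }
  colnames(out) <- cn
  out
}

#' Pseudo k-tuple nucleotide composition (PseKNC, type 1)
#'
#' The first \code{4^k} entries are k-mer frequencies and the last
#' \code{lam} entries are sequence-order correlation factors, jointly
#' normalized: \deqn{d_v = f_v / (\sum f + w \sum \theta), \quad
#' d_{4^k + j} = w\,\theta_j / (\sum f + w \sum \theta)} where
#' \eqn{\theta_j} is the average over k-mer pairs \code{j} apart of the mean
#' squared property difference between the two k-mers. Correlation factors
#' use the dinucleotide property table, so they are defined for \code{k = 2}
#' (the default); other \code{k} require \code{lam = 0}.
#'
#' @inheritParams encode_autocor
#' @param k k-mer size (default 2).
#' @param lam Number of correlation tiers \eqn{\lambda} (default 3).
#' @param w Weight of the correlation tiers (default 0.1).
#' @return Numeric matrix, \code{length(windows)} x \code{4^k + lam}.
#' @export
encode_pseknc <- function(windows, k = 2L, lam = 3L, w = 0.1,
                          props = dhu_properties()) {
  if (k < 1L || k > 3L) stop("k must be 1, 2 or 3")
  if (lam > 0L && k != 2L)
    stop("correlation tiers (lam > 0) require k = 2 (dinucleotide property table)")
  if (w < 0) stop("w must be non-negative")
  m <- seq_to_matrix(windows)
  L <- ncol(m)
  if (L - k < lam + 1L)
    stop("lam = ", lam, " too large for window length ", L, " with k = ", k)
  kmers <- c("A", "C", "G", "U")
  for (j in seq_len(k - 1L))
    kmers <- as.vector(t(outer(kmers, c("A", "C", "G", "U"), paste0)))
  kmers <- sort(kmers)
  out <- matrix(0, nrow(m), 4^k + lam)
  for (i in seq_len(nrow(m))) {
    mers <- vapply(seq_len(L - k + 1L),
                   function(s) paste(m[i, s:(s + k - 1L)], collapse = ""), "")
    ok <- !grepl("N", mers, fixed = TRUE)
    f <- tabulate(factor(mers[ok], levels = kmers), length(kmers))
    f <- if (sum(f)) f / sum(f) else f
    theta <- numeric(lam)
    if (lam > 0L) {
      pv <- rep(NA_real_, length(mers))
      pv_ok <- ok
      for (j in seq_len(lam)) {
        idx <- seq_len(length(mers) - j)
        good <- pv_ok[idx] & pv_ok[idx + j]
        if (any(good)) {
          d2 <- vapply(which(good), function(s) {
            mean((props[, mers[s]] - props[, mers[s + j]])^2)
          }, 0)
          theta[j] <- mean(d2)
        }
      }
    }
    denom <- sum(f) + w * sum(theta)
    if (denom > 0)
      out[i, ] <- c(f, w * theta) / denom
  }
  colnames(out) <- c(paste0("PseKNC.", kmers),
                     if (lam > 0L) paste0("PseKNC.theta", seq_len(lam)))
  out
}

encoder_registry <- function(props, max_lag, k, lam, w) {
  list(ONE_HOT = encode_one_hot,
       ChemProper = encode_chemprop,
       EIIP = encode_eiip,
       CONPOSI = encode_conposi,
       Frequency = encode_anf,
       autoCor = function(x) encode_autocor(x, props, max_lag),
       crossCor = function(x) encode_crosscor(x, props, max_lag),
       PseKNC = function(x) encode_pseknc(x, k, lam, w, props))
}

#' Encode windows with one or more encoders
#'
#' Concatenates the requested encoders' columns in the requested order. The
#' result is a plain numeric matrix whose column names carry the encoder
#' prefix, recoverable with [feature_encoder()]. An empty window vector
#' yields a 0-row matrix with the full column set (the window length must
#' then be supplied).
#'
#' @param windows Character vector of windows or a [dhu_dataset()].
#' @param encoders Subset of [dhu_encoders()], no duplicates.
#' @param props Standardized property table ([dhu_properties()]).
#' @param max_lag Lag span for autoCor/crossCor.
#' @param k,lam,w PseKNC parameters.
#' @param window_length Required only when \code{windows} is empty.
#' @return Numeric matrix, samples x features.
#' @export
encode_windows <- function(windows, encoders = dhu_encoders(),
                           props = dhu_properties(), max_lag = 2L,
                           k = 2L, lam = 3L, w = 0.1, window_length = NULL) {
  if (inherits(windows, "dhu_dataset")) {
    if (is.null(window_length)) window_length <- windows$window_length
    windows <- windows$windows
  }
  if (anyDuplicated(encoders))
    stop("duplicate encoder requested: ",
         paste(unique(encoders[duplicated(encoders)]), collapse = ", "))
  unknown <- setdiff(encoders, dhu_encoders())
  if (length(unknown) || !length(encoders))
    stop("unknown or empty encoder request: ", paste(unknown, collapse = ", "))
  empty <- length(windows) == 0L
  if (empty) {
    if (is.null(window_length))
      stop("window_length required to encode an empty dataset")
    mid <- (window_length + 1L) %/% 2L
    windows <- paste0(strrep("A", mid - 1L), "U", strrep("A", window_length - mid))
  }
  reg <- encoder_registry(props, max_lag, k, lam, w)
  mat <- do.call(cbind, lapply(encoders, function(e) reg[[e]](windows)))
  if (empty) mat <- mat[0L, , drop = FALSE]
  mat
}

#' Write / read a feature matrix as TSV
#'
#' The TSV carries a two-line header: encoder name per column, then the full
#' descriptor, followed by the numeric rows.
#' @param x Feature matrix from [encode_windows()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_features <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(feature_encoder(x), collapse = "\t"), con)
  writeLines(paste(colnames(x), collapse = "\t"), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  hdr <- readLines(path, n = 2L)
  cn <- strsplit(hdr[2L], "\t", fixed = TRUE)[[1L]]
  dat <- utils::read.table(path, sep = "\t", skip = 2L)
  m <- as.matrix(dat)
  dimnames(m) <- list(NULL, cn)
  m
}
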