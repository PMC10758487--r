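# Independent brute-force oracles used to verify the package's metric and
# encoder implementations. These deliberately share no code with R/.

# AUROC as the pairwise probability over all positive x negative pairs.
brute_auroc <- function(labels, scores) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# F-score exactly as the printed two-class formula, one feature at a time.
brute_fscore <- function(v, labels) {
  xp <- v[labels == 1]; xn <- v[labels == 0]
  num <- (mean(xp) - mean(v))^2 + (mean(xn) - mean(v))^2
  den <- sum((xp - mean(xp))^2) / (length(xp) - 1) +
         sum((xn - mean(xn))^2) / (length(xn) - 1)
  if (den == 0) 0 else num / den
}

# Dinucleotide property series of one window (NA at N-containing steps).
oracle_series <- function(window, props) {
  ch <- strsplit(window, "")[[1]]
  di <- paste0(ch[-length(ch)], ch[-1])
  out <- matrix(NA_real_, length(di), nrow(props))
  for (i in seq_along(di))
    if (!grepl("N", di[i])) out[i, ] <- props[, di[i]]
  out
}

# Auto-covariance by an explicit double loop.
brute_autocor <- function(window, props, max_lag = 2) {
  P <- oracle_series(window, props)
  out <- c()
  for (u in seq_len(nrow(props))) for (g in seq_len(max_lag)) {
    pu <- P[, u]
    mu <- mean(pu, na.rm = TRUE)
    s <- 0; cnt <- 0
    for (i in seq_len(length(pu) - g)) {
      if (!is.na(pu[i]) && !is.na(pu[i + g])) {
        s <- s + (pu[i] - mu) * (pu[i + g] - mu)
        cnt <- cnt + 1
      }
    }
    out <- c(out, s / cnt)
  }
  out
}

# Cross-covariance by an explicit double loop (ordered property pairs).
brute_crosscor <- function(window, props, max_lag = 2) {
  P <- oracle_series(window, props)
  out <- c()
  for (u1 in seq_len(nrow(props))) for (u2 in seq_len(nrow(props))) {
    if (u1 == u2) next
    for (g in seq_len(max_lag)) {
      p1 <- P[, u1]; p2 <- P[, u2]
      m1 <- mean(p1, na.rm = TRUE); m2 <- mean(p2, na.rm = TRUE)
      s <- 0; cnt <- 0
      for (i in seq_len(length(p1) - g)) {
        if (!is.na(p1[i]) && !is.na(p2[i + g])) {
          s <- s + (p1[i] - m1) * (p2[i + g] - m2)
          cnt <- cnt + 1
        }
      }
      out <- c(out, s / cnt)
    }
  }
  out
}

# Random U-centered windows over the full alphabet.
random_windows <- function(n, L = 41, seed = 1, alphabet = c("A", "C", "G", "U")) {
  set.seed(seed)
  mid <- (L + 1) %/% 2
  vapply(seq_len(n), function(i) {
    ch <- sample(alphabet, L, replace = TRUE)
    ch[mid] <- "U"
    paste(ch, collapse = "")
  }, "")
}
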