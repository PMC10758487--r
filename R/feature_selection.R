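# Filter-style feature selection: F-score ranking, incremental feature
# selection (IFS) by cross-validated AUROC, and exhaustive search over
# encoder combinations.

#' Per-feature F-score
#'
#' The classical two-class F-score of a feature: squared deviations of the
#' class means from the overall mean, over the sum of the two unbiased
#' within-class variances,
#' \deqn{F_i = \frac{(\bar x_i^+ - \bar x_i)^2 + (\bar x_i^- - \bar x_i)^2}
#'   {\frac{1}{n_+-1}\sum_d (x_{d,i}^+ - \bar x_i^+)^2 +
#'    \frac{1}{n_--1}\sum_d (x_{d,i}^- - \bar x_i^-)^2}.}
#' Larger values mean stronger separation between modified and unmodified
#' windows. A feature with zero denominator (constant within both classes)
#' scores 0 by convention. The score is invariant to affine rescaling of
#' the feature.
#'
#' @param x Feature matrix (samples x features).
#' @param labels 0/1 vector; at least two samples per class.
#' @return Numeric vector of non-negative scores, named by feature.
#' @export
f_score <- function(x, labels) {
  labels <- check_binary_labels(labels, nrow(x))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 < 2L || n0 < 2L)
    stop("F-score needs >= 2 samples in each class")
  xp <- x[labels == 1L, , drop = FALSE]
  xn <- x[labels == 0L, , drop = FALSE]
  m <- colMeans(x); mp <- colMeans(xp); mn <- colMeans(xn)
  num <- (mp - m)^2 + (mn - m)^2
  den <- apply(xp, 2L, stats::var) + apply(xn, 2L, stats::var)
  out <- ifelse(den == 0, 0, num / den)
  names(out) <- colnames(x)
  out
}

# Default IFS evaluation grid: every prefix size up to 12 features, then a
# geometric ladder (factor 1.35), always ending at n_features. Keeps the
# curve dense where optima typically sit while bounding the number of
# cross-validation rounds on wide encoders; pass `stride` or an explicit
# `grid` for a step-1 scan.
ifs_default_grid <- function(n_features, stride = NULL) {
  if (!is.null(stride)) {
    g <- unique(c(seq(1L, n_features, by = stride), n_features))
  } else if (n_features <= 12L) {
    g <- seq_len(n_features)
  } else {
    g <- unique(c(1:12, round(12 * 1.35^seq_len(30)), n_features))
    g <- g[g <= n_features]
  }
  sort(unique(as.integer(g)))
}

#' Incremental feature selection
#'
#' Walks prefixes of the F-score ranking and scores each prefix by pooled
#' stratified k-fold cross-validated AUROC of the default-parameter
#' classifier. The same fold assignment is reused across all prefix sizes so
#' curve points are directly comparable. The chosen size is the first
#' maximum of the curve.
#'
#' @param x Feature matrix.
#' @param labels 0/1 vector.
#' @param ranking Optional permutation of column indices (decreasing
#'   importance); defaults to the [f_score()] ranking, ties broken by column
#'   order.
#' @param grid Prefix sizes to evaluate; \code{NULL} means every size up to
#'   12 then a geometric ladder to \code{ncol(x)}.
#' @param stride Convenience: evaluate every \code{stride}-th size instead
#'   (\code{stride = 1} forces the full step-1 scan).
#' @param spec Classifier used for scoring (default: SVM with libsvm
#'   defaults, C = 1, gamma = 1/n_features).
#' @param folds CV folds (default 5).
#' @param seed Fold-assignment seed.
#' @return Object of class \code{dhu_ifs}: \code{scores} (F-scores),
#'   \code{ranking}, \code{curve} (data.frame \code{n}, \code{cv_auroc}),
#'   \code{chosen_n}, \code{chosen} (column names of the selected subset).
#' @export
ifs <- function(x, labels, ranking = NULL, grid = NULL, stride = NULL,
                spec = model_spec("svm"), folds = 5L, seed = 1L) {
  labels <- check_binary_labels(labels, nrow(x))
  scores <- f_score(x, labels)
  if (is.null(ranking)) ranking <- order(scores, decreasing = TRUE)
  if (!identical(sort(ranking), seq_len(ncol(x))))
    stop("ranking must be a permutation of 1..n_features")
  if (is.null(grid)) grid <- ifs_default_grid(ncol(x), stride)
  if (any(grid < 1L | grid > ncol(x))) stop("grid sizes must be in 1..n_features")
  fold <- stratified_folds(labels, folds, seed)
  curve <- vapply(grid, function(n) {
    sub <- x[, ranking[seq_len(n)], drop = FALSE]
    auroc(labels, cv_scores(sub, labels, spec, fold, seed))
  }, 0)
  chosen_n <- grid[which.max(curve)]   # first maximum on ties
  structure(list(scores = scores, ranking = ranking,
                 curve = data.frame(n = grid, cv_auroc = curve),
                 chosen_n = chosen_n,
                 chosen = colnames(x)[ranking[seq_len(chosen_n)]],
                 folds = folds, seed = seed),
            class = "dhu_ifs")
}

#' @export
print.dhu_ifs <- function(x, ...) {
  cat("<dhu_ifs> ", length(x$scores), " features; chosen top ", x$chosen_n,
      sprintf(" (CV AUROC %.3f)\n", max(x$curve$cv_auroc)), sep = "")
  invisible(x)
}

#' @export
plot.dhu_ifs <- function(x, ...) {
  graphics::plot(x$curve$n, x$curve$cv_auroc, type = "b", pch = 20,
                 xlab = "top N features", ylab = "CV AUROC", ...)
  graphics::abline(v = x$chosen_n, lty = 2)
  invisible(x)
}

#' Exhaustive search over encoder combinations
#'
#' Concatenates the IFS-chosen feature subsets of every combination of
#' \code{arity} encoders and scores each combination by pooled k-fold CV
#' AUROC (shared fold assignment). Combining a small number of complementary
#' encoders guards against the redundancy that full concatenation invites on
#' small site collections.
#'
#' @param x Full feature matrix containing all candidate encoders' columns.
#' @param labels 0/1 vector.
#' @param selections Named list of [ifs()] results (or character vectors of
#'   chosen column names), one per encoder.
#' @param arity Number of encoders per combination (default 3).
#' @param spec,folds,seed As in [ifs()].
#' @return Object of class \code{dhu_combos}: data.frame \code{results}
#'   (\code{combo}, \code{encoders}, \code{n_features}, \code{cv_auroc})
#'   sorted by decreasing AUROC (ties: fewer features, then combo name), and
#'   \code{best}.
#' @export
combination_search <- function(x, labels, selections, arity = 3L,
                               spec = model_spec("svm"), folds = 5L, seed = 1L) {
  labels <- check_binary_labels(labels, nrow(x))
  if (length(selections) < arity)
    stop("arity (", arity, ") exceeds number of encoders (", length(selections), ")")
  chosen <- lapply(selections, function(s)
    if (inherits(s, "dhu_ifs")) s$chosen else as.character(s))
  fold <- stratified_folds(labels, folds, seed)
  combos <- utils::combn(names(chosen), arity, simplify = FALSE)
  rows <- lapply(combos, function(cb) {
    feats <- unlist(chosen[cb], use.names = FALSE)
    sub <- x[, feats, drop = FALSE]
    data.frame(combo = paste(cb, collapse = "+"),
               n_features = length(feats),
               cv_auroc = auroc(labels, cv_scores(sub, labels, spec, fold, seed)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$cv_auroc, res$n_features, res$combo), ]
  rownames(res) <- NULL
  structure(list(results = res,
                 best = strsplit(res$combo[1L], "+", fixed = TRUE)[[1L]],
                 arity = arity, folds = folds, seed = seed,
                 chosen = chosen),
            class = "dhu_combos")
}

#' @export
print.dhu_combos <- function(x, ...) {
  cat("<dhu_combos> ", nrow(x$results), " combinations of ", x$arity,
      " encoders; best: ", x$results$combo[1L],
      sprintf(" (CV AUROC %.3f, %d features)\n",
              x$results$cv_auroc[1L], x$results$n_features[1L]), sep = "")
  invisible(x)
}

#' Serialize a selection result as JSON
#' @param selection A \code{dhu_ifs} object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_selection <- function(selection, path) {
  jsonlite::write_json(list(scores = unname(selection$scores),
                            features = names(selection$scores),
                            ranking = selection$ranking,
                            curve = selection$curve,
                            chosen_n = selection$chosen_n,
                            chosen = selection$chosen),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
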