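# Rank-based evaluation: AUROC (Mann-Whitney form), step-wise AUPRC, and
# threshold metrics with explicit confusion counts.

#' Area under the ROC curve
#'
#' Computed in the Mann-Whitney form: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, counting ties as one half.
#' This is exactly the trapezoidal ROC area and is invariant under strictly
#' increasing transformations of the scores.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores Numeric scores, higher = more positive.
#' @return AUROC in \code{[0, 1]}.
#' @examples
#' auroc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2))  # 0.75
#' @export
auroc <- function(labels, scores) {
  labels <- check_binary_labels(labels, length(scores))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUROC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) area: thresholds sweep the distinct score
#' values from high to low and each recall increment contributes the
#' precision at that threshold. For random scores the value approaches the
#' positive prevalence.
#'
#' @inheritParams auroc
#' @return AUPRC in \code{(0, 1]}.
#' @export
auprc <- function(labels, scores) {
  labels <- check_binary_labels(labels, length(scores))
  P <- sum(labels == 1L)
  if (P == 0L) stop("AUPRC needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  grp <- cumsum(!duplicated(sc))           # threshold groups over tied scores
  tp <- cumsum(lab); fp <- cumsum(1 - lab)
  last <- !duplicated(grp, fromLast = TRUE)  # state after each full threshold
  tp <- tp[last]; fp <- fp[last]
  rec <- tp / P
  prec <- tp / (tp + fp)
  sum(diff(c(0, rec)) * prec)
}

#' Confusion counts and threshold metrics
#'
#' @param labels 0/1 truth vector with both classes present.
#' @param predicted 0/1 hard predictions aligned with \code{labels}.
#' @return List with \code{TP}, \code{FP}, \code{TN}, \code{FN} and
#'   \code{acc = (TP+TN)/n}, \code{sn = TP/(TP+FN)}, \code{sp = TN/(TN+FP)}.
#' @export
confusion_metrics <- function(labels, predicted) {
  labels <- check_binary_labels(labels, length(predicted))
  predicted <- check_binary_labels(predicted, length(labels))
  if (length(unique(labels)) < 2L)
    stop("confusion metrics need both classes in labels")
  TP <- sum(labels == 1L & predicted == 1L)
  FN <- sum(labels == 1L & predicted == 0L)
  TN <- sum(labels == 0L & predicted == 0L)
  FP <- sum(labels == 0L & predicted == 1L)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       acc = (TP + TN) / length(labels),
       sn = TP / (TP + FN),
       sp = TN / (TN + FP))
}

#' Full evaluation report for scored predictions
#'
#' @inheritParams auroc
#' @param threshold Hard-label threshold on the scores (default 0.5).
#' @param context Free-form provenance string stored in the report.
#' @return Object of class \code{dhu_report}: auroc, auprc, acc, sn, sp,
#'   confusion counts, threshold and context.
#' @export
evaluation_report <- function(labels, scores, threshold = 0.5, context = "") {
  cm <- confusion_metrics(labels, as.integer(scores >= threshold))
  structure(list(auroc = auroc(labels, scores),
                 auprc = auprc(labels, scores),
                 acc = cm$acc, sn = cm$sn, sp = cm$sp,
                 counts = cm[c("TP", "FP", "TN", "FN")],
                 threshold = threshold, n = length(labels),
                 context = context),
            class = "dhu_report")
}

#' @export
print.dhu_report <- function(x, ...) {
  cat("<dhu_report>", if (nzchar(x$context)) paste0(" [", x$context, "]"), "\n",
      sprintf("  AUROC %.3f  AUPRC %.3f  ACC %.3f  Sn %.3f  Sp %.3f  (n = %d)\n",
              x$auroc, x$auprc, x$acc, x$sn, x$sp, x$n), sep = "")
  invisible(x)
}

#' ROC and precision-recall curve points
#'
#' Threshold-wise curve coordinates suitable for plotting or TSV export:
#' one row per distinct score threshold (descending), plus the (0, 0) / (1, 1)
#' ROC anchors.
#'
#' @inheritParams auroc
#' @return For \code{roc_curve}: data.frame \code{threshold}, \code{fpr},
#'   \code{tpr}. For \code{pr_curve}: data.frame \code{threshold},
#'   \code{recall}, \code{precision}.
#' @export
roc_curve <- function(labels, scores) {
  labels <- check_binary_labels(labels, length(scores))
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  last <- !duplicated(cumsum(!duplicated(sc)), fromLast = TRUE)
  tp <- cumsum(lab)[last]; fp <- cumsum(1 - lab)[last]
  data.frame(threshold = c(Inf, sc[last]),
             fpr = c(0, fp / sum(labels == 0L)),
             tpr = c(0, tp / sum(labels == 1L)))
}

#' @rdname roc_curve
#' @export
pr_curve <- function(labels, scores) {
  labels <- check_binary_labels(labels, length(scores))
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  last <- !duplicated(cumsum(!duplicated(sc)), fromLast = TRUE)
  tp <- cumsum(lab)[last]; fp <- cumsum(1 - lab)[last]
  data.frame(threshold = sc[last],
             recall = tp / sum(labels == 1L),
             precision = tp / (tp + fp))
}

#' Youden-optimal hard-label threshold
#'
#' The score threshold maximizing Youden's J = sensitivity + specificity - 1
#' (first maximum on ties, scanning thresholds from high to low). Offered for
#' exploratory use; the package's reports default to the fixed 0.5 threshold.
#'
#' @inheritParams auroc
#' @return A single threshold value.
#' @export
youden_threshold <- function(labels, scores) {
  rc <- roc_curve(labels, scores)
  j <- rc$tpr - rc$fpr
  rc$threshold[which.max(j)]
}

#' Permutation null band for AUROC
#'
#' Central confidence band of the AUROC of uninformative scores for the
#' given class sizes, obtained by Monte-Carlo label permutation. With
#' \code{n_means > 1} the band describes the mean of that many independent
#' null AUROCs.
#'
#' @param n_pos,n_neg Class sizes.
#' @param level Central coverage (default 0.95).
#' @param n_perm Number of permutations (default 2000).
#' @param n_means Average this many independent null draws per sample.
#' @param seed RNG seed.
#' @return Numeric length-2 vector, lower and upper band limits.
#' @export
auroc_null_band <- function(n_pos, n_neg, level = 0.95, n_perm = 2000L,
                            n_means = 1L, seed = 1L) {
  labels <- rep(c(1L, 0L), c(n_pos, n_neg))
  draws <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      mean(vapply(seq_len(n_means),
                  function(j) auroc(labels, stats::runif(n_pos + n_neg)), 0))
    }, 0)
  })
  unname(stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Cross-validated evaluation of one model specification
#'
#' Stratified k-fold cross-validation: the model (including its
#' training-fold feature standardization) is refitted on each training fold
#' and scores the held-out fold; out-of-fold scores are pooled into a single
#' report, and per-fold reports are retained.
#'
#' @param x Feature matrix (samples x features).
#' @param labels 0/1 vector.
#' @param spec A [model_spec()].
#' @param folds Number of folds (default 5).
#' @param seed Seed driving the fold assignment and any model randomness.
#' @return List of class \code{dhu_cv_eval}: \code{pooled} (a
#'   \code{dhu_report}), \code{per_fold} (list of reports), \code{scores}
#'   (pooled out-of-fold scores), \code{fold} (assignment).
#' @export
cross_validate <- function(x, labels, spec = model_spec("svm"), folds = 5L,
                           seed = 1L) {
  labels <- check_binary_labels(labels, nrow(x))
  fold <- stratified_folds(labels, folds, seed)
  scores <- cv_scores(x, labels, spec, fold, seed)
  per_fold <- lapply(seq_len(folds), function(f) {
    idx <- fold == f
    evaluation_report(labels[idx], scores[idx], context = paste0("fold ", f))
  })
  structure(list(pooled = evaluation_report(labels, scores,
                                            context = paste0(folds, "-fold CV, pooled")),
                 per_fold = per_fold, scores = scores, fold = fold, seed = seed),
            class = "dhu_cv_eval")
}

#' @export
print.dhu_cv_eval <- function(x, ...) {
  print(x$pooled)
  invisible(x)
}

#' Cross-species transfer matrix
#'
#' Applies each species' frozen pipeline (its chosen features, tuned SVM and
#' training-set scaling — nothing is refitted) to every species' windows.
#' Off-diagonal cells use all of the target species' windows; diagonal cells
#' use only that species' independent test partition, since the model has
#' seen its own training windows.
#'
#' @param fits Named list of [dhu_fit()] objects, one per species.
#' @param datasets Named list of [dhu_dataset()] objects, aligned with
#'   \code{fits}.
#' @return Numeric matrix of AUROCs, training species in rows, target
#'   species in columns.
#' @export
cross_species <- function(fits, datasets) {
  stopifnot(length(fits) == length(datasets),
            identical(names(fits), names(datasets)))
  sp <- names(fits)
  out <- matrix(NA_real_, length(sp), length(sp), dimnames = list(train = sp, test = sp))
  for (a in sp) for (b in sp) {
    ds <- datasets[[b]]
    if (a == b) {
      if (is.null(ds$partition))
        stop("diagonal evaluation needs a test partition for species '", b, "'")
      ds <- ds[ds$partition == "test"]
    }
    sc <- predict(fits[[a]], ds, type = "score")
    out[a, b] <- auroc(ds$labels, sc)
  }
  out
}

#' Per-position nucleotide composition by class
#'
#' Descriptive positional A/U/G/C frequency tables for positive and negative
#' windows (a light-weight summary of positional enrichment; frequencies at
#' each position are over non-N counts and sum to 1).
#'
#' @param windows Character vector of windows or a [dhu_dataset()].
#' @param labels 0/1 vector (ignored when \code{windows} is a dataset).
#' @return List with elements \code{positive} and \code{negative}, each an
#'   L x 4 matrix of frequencies with columns A, U, G, C.
#' @export
positional_composition <- function(windows, labels = NULL) {
  if (inherits(windows, "dhu_dataset")) {
    labels <- windows$labels
    windows <- windows$windows
  }
  labels <- check_binary_labels(labels, length(windows))
  one <- function(w) {
    if (!length(w)) stop("positional composition needs >= 1 window per class")
    m <- seq_to_matrix(w)
    t(apply(m, 2L, function(col) {
      cnt <- vapply(RNA_BASES, function(b) sum(col == b), 0L)
      tot <- sum(cnt)
      if (tot == 0L) rep(0, 4L) else cnt / tot
    }))
  }
  list(positive = one(windows[labels == 1L]),
       negative = one(windows[labels == 0L]))
}
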