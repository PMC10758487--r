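# Classifier layer: RBF-SVM (libsvm via e1071) with a log-scale C/gamma
# grid, plus logistic GLM, random forest and Gaussian naive Bayes baselines.
# Every algorithm exposes the same probability-like score in [0,1] so one
# evaluation path serves them all.

#' Model specification
#'
#' @param algorithm One of \code{"svm"} (RBF kernel), \code{"glm"} (binomial
#'   logistic regression), \code{"rf"} (random forest), \code{"nb"}
#'   (Gaussian naive Bayes).
#' @param cost SVM regularization parameter C (default 1, the libsvm
#'   default).
#' @param gamma SVM kernel width; \code{NULL} means the libsvm default
#'   \code{1/n_features}, resolved at fit time.
#' @param ntree Random-forest tree count (default 500).
#' @return Object of class \code{dhu_model_spec}.
#' @export
model_spec <- function(algorithm = c("svm", "glm", "rf", "nb"),
                       cost = 1, gamma = NULL, ntree = 500L) {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm, cost = cost, gamma = gamma,
                 ntree = as.integer(ntree)),
            class = "dhu_model_spec")
}

# Decision values of a fitted e1071 RBF svm on raw (already standardized)
# rows, oriented so larger = class "1". Avoids predict() overhead in the
# selection and grid loops; equality with predict(..., decision.values) is
# asserted in the test suite.
svm_decision <- function(fit, newx) {
  sv <- fit$SV
  d2 <- outer(rowSums(newx^2), rowSums(sv^2), "+") - 2 * tcrossprod(newx, sv)
  d2[d2 < 0] <- 0
  dv <- drop(exp(-fit$gamma * d2) %*% fit$coefs) - fit$rho
  if (fit$levels[fit$labels[1L]] != "1") dv <- -dv
  dv
}

#' Train a classifier
#'
#' Features are standardized to zero mean / unit variance using
#' training-data statistics (random forest consumes raw features); the
#' standardization is stored with the model and applied to any new data, so
#' no test-set information leaks into scaling. Constant training features
#' are scaled to zero with a warning.
#'
#' @param x Training feature matrix (samples x features, named columns).
#' @param labels 0/1 vector, both classes present.
#' @param spec A [model_spec()].
#' @param seed Seed for algorithms with internal randomness.
#' @return Object of class \code{dhu_model}.
#' @export
train_model <- function(x, labels, spec = model_spec("svm"), seed = 1L) {
  labels <- check_binary_labels(labels, nrow(x))
  if (length(unique(labels)) < 2L)
    stop("training needs both classes present")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  scaled <- spec$algorithm != "rf"
  center <- scale <- NULL
  xs <- x
  if (scaled) {
    center <- colMeans(x)
    scale <- apply(x, 2L, stats::sd)
    if (any(scale == 0)) {
      warning(sum(scale == 0), " constant feature(s) scaled to zero")
      scale[scale == 0] <- 1
    }
    xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  }
  y <- factor(labels, levels = c("0", "1"))
  fit <- with_seed(seed, switch(spec$algorithm,
    svm = e1071::svm(xs, y, kernel = "radial", cost = spec$cost,
                     gamma = if (is.null(spec$gamma)) 1 / ncol(xs) else spec$gamma,
                     scale = FALSE),
    glm = {
      keep <- apply(xs, 2L, function(v) stats::sd(v) > 0)
      f <- suppressWarnings(stats::glm.fit(cbind(1, xs[, keep, drop = FALSE]),
                                           labels, family = stats::binomial()))
      list(coef = f$coefficients, keep = keep)
    },
    rf = randomForest::randomForest(xs, y, ntree = spec$ntree),
    nb = {
      keep <- apply(xs, 2L, function(v) stats::sd(v) > 0)
      list(fit = e1071::naiveBayes(xs[, keep, drop = FALSE], y), keep = keep)
    }))
  structure(list(spec = spec, fit = fit, center = center, scale = scale,
                 feature_names = colnames(x), seed = seed,
                 n_train = nrow(x)),
            class = "dhu_model")
}

#' @export
print.dhu_model <- function(x, ...) {
  cat("<dhu_model> ", x$spec$algorithm, " on ", length(x$feature_names),
      " features, ", x$n_train, " training samples\n", sep = "")
  invisible(x)
}

#' Predict scores or hard labels
#'
#' Scores are probability-like values in \code{[0, 1]}, monotone in the
#' classifier's confidence for the positive class; hard labels threshold the
#' score at 0.5. For the SVM the score is the logistic transform of the
#' decision value, so the 0.5 threshold coincides with the margin sign.
#'
#' @param object A \code{dhu_model}.
#' @param newdata Feature matrix whose columns match the training columns in
#'   name and order.
#' @param type \code{"score"} (default) or \code{"class"}.
#' @param ... Unused.
#' @return Numeric scores or integer 0/1 labels, one per row.
#' @export
predict.dhu_model <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  if (is.null(colnames(newdata)) ||
      !identical(colnames(newdata), object$feature_names)) {
    missing <- setdiff(object$feature_names, colnames(newdata))
    extra <- setdiff(colnames(newdata), object$feature_names)
    stop("feature columns do not match the fitted model",
         if (length(missing)) paste0("; missing: ", paste(utils::head(missing, 5L), collapse = ", ")),
         if (length(extra)) paste0("; extra: ", paste(utils::head(extra, 5L), collapse = ", ")),
         if (!length(missing) && !length(extra)) "; columns are out of order")
  }
  xs <- newdata
  if (!is.null(object$center))
    xs <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  score <- switch(object$spec$algorithm,
    svm = stats::plogis(svm_decision(object$fit, xs)),
    glm = {
      co <- object$fit$coef
      co[is.na(co)] <- 0
      drop(stats::plogis(cbind(1, xs[, object$fit$keep, drop = FALSE]) %*% co))
    },
    rf = unname(predict(object$fit, xs, type = "prob")[, "1"]),
    nb = unname(predict(object$fit$fit,
                        xs[, object$fit$keep, drop = FALSE],
                        type = "raw")[, "1"]))
  if (type == "class") as.integer(score >= 0.5) else score
}

# Pooled out-of-fold scores for a fixed fold assignment. The workhorse
# behind IFS, combination search, grid search and cross_validate.
cv_scores <- function(x, labels, spec, fold, seed = 1L) {
  scores <- numeric(length(labels))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    m <- suppressWarnings(train_model(x[tr, , drop = FALSE], labels[tr], spec,
                                      seed = seed))
    scores[!tr] <- predict(m, x[!tr, , drop = FALSE])
  }
  scores
}

#' Grid search over the SVM (C, gamma) log-grid
#'
#' Evaluates cross-validated AUROC and AUPRC at every point of the
#' exponent grid \code{C = 2^e, e = -5, -3, ..., 15} (11 values) and
#' \code{gamma = 2^e, e = -15, -14, ..., 5} (21 values) — 231 points under
#' the defaults — using one shared stratified fold assignment. The best pair
#' maximizes CV AUROC; ties break by higher AUPRC, then smaller C, then
#' smaller gamma.
#'
#' @param x Feature matrix (already restricted to the chosen features).
#' @param labels 0/1 vector.
#' @param folds CV folds (default 5).
#' @param seed Fold-assignment seed.
#' @param c_exponents,gamma_exponents Exponent vectors defining the grid.
#' @return Object of class \code{dhu_grid}: \code{grid} data.frame
#'   (\code{C}, \code{gamma}, \code{cv_auroc}, \code{cv_auprc}),
#'   \code{best} (list with \code{cost}, \code{gamma}), and
#'   \code{selection_rule}.
#' @export
grid_search_svm <- function(x, labels, folds = 5L, seed = 1L,
                            c_exponents = seq(-5L, 15L, by = 2L),
                            gamma_exponents = seq(-15L, 5L, by = 1L)) {
  labels <- check_binary_labels(labels, nrow(x))
  fold <- stratified_folds(labels, folds, seed)
  pts <- expand.grid(C = 2^c_exponents, gamma = 2^gamma_exponents,
                     KEEP.OUT.ATTRS = FALSE)
  res <- vapply(seq_len(nrow(pts)), function(i) {
    sc <- cv_scores(x, labels, model_spec("svm", cost = pts$C[i],
                                          gamma = pts$gamma[i]), fold, seed)
    c(auroc(labels, sc), auprc(labels, sc))
  }, numeric(2L))
  grid <- data.frame(C = pts$C, gamma = pts$gamma,
                     cv_auroc = res[1L, ], cv_auprc = res[2L, ])
  ord <- order(-grid$cv_auroc, -grid$cv_auprc, grid$C, grid$gamma)
  best <- grid[ord[1L], ]
  structure(list(grid = grid,
                 best = list(cost = best$C, gamma = best$gamma,
                             cv_auroc = best$cv_auroc, cv_auprc = best$cv_auprc),
                 selection_rule = "max cv_auroc; ties: max cv_auprc, min C, min gamma",
                 folds = folds, seed = seed),
            class = "dhu_grid")
}

#' @export
print.dhu_grid <- function(x, ...) {
  cat("<dhu_grid> ", nrow(x$grid), " (C, gamma) points, ", x$folds, "-fold CV\n",
      sprintf("  best: C = 2^%g, gamma = 2^%g, AUROC %.3f, AUPRC %.3f\n",
              log2(x$best$cost), log2(x$best$gamma),
              x$best$cv_auroc, x$best$cv_auprc), sep = "")
  invisible(x)
}

#' Write a grid result as TSV (for heatmap plotting)
#' @param grid A \code{dhu_grid}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_grid <- function(grid, path) {
  utils::write.table(grid$grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
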