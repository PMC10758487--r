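# Top-level modelling interface: dhu_fit() runs the whole training pipeline
# (encode -> per-encoder F-score + IFS -> encoder-combination search ->
# optional (C, gamma) grid search -> final SVM) and returns a classed object
# with predict/print/summary/plot methods. dhu_cv() wraps the pipeline in an
# outer cross-validation so its generalization (and null behaviour) can be
# measured without information leaking from selection into evaluation.

#' Fit the dihydrouridine site predictor
#'
#' Trains the full prediction pipeline on uridine-centered windows:
#' \enumerate{
#'   \item encode the training windows with all requested encoders;
#'   \item rank each encoder's features by [f_score()] and pick each
#'     encoder's best prefix by [ifs()];
#'   \item search all \code{arity}-encoder combinations of those subsets
#'     ([combination_search()]);
#'   \item optionally tune the RBF-SVM on the winning feature set over the
#'     (C, gamma) log-grid ([grid_search_svm()]);
#'   \item fit the final SVM on the full training partition.
#' }
#' All cross-validation inside the pipeline uses stratified folds derived
#' from \code{seed}.
#'
#' @param data A [dhu_dataset()] (its training partition is used when one is
#'   present, and the test partition is scored into \code{$test_report}) or
#'   a character vector of windows.
#' @param labels 0/1 vector; required when \code{data} is a plain vector.
#' @param encoders Encoders to consider (default all eight).
#' @param arity Encoders per combination (default 3).
#' @param folds Cross-validation folds used throughout (default 5).
#' @param tune Run the (C, gamma) grid search (default TRUE); otherwise the
#'   final SVM keeps libsvm defaults (C = 1, gamma = 1/n_features), the
#'   same defaults used while selecting features.
#' @param seed Integer seed for every fold assignment.
#' @param props,max_lag,k,lam,w Encoder parameters (see [encode_windows()]).
#' @param ifs_grid,ifs_stride Prefix-size grid for [ifs()].
#' @param c_exponents,gamma_exponents Grid-search exponents
#'   (see [grid_search_svm()]).
#' @return Object of class \code{dhu_fit}.
#' @export
dhu_fit <- function(data, labels = NULL, encoders = dhu_encoders(),
                    arity = 3L, folds = 5L, tune = TRUE, seed = 1L,
                    props = dhu_properties(), max_lag = 2L,
                    k = 2L, lam = 3L, w = 0.1,
                    ifs_grid = NULL, ifs_stride = NULL,
                    c_exponents = seq(-5L, 15L, by = 2L),
                    gamma_exponents = seq(-15L, 5L, by = 1L)) {
  test <- NULL
  if (inherits(data, "dhu_dataset")) {
    full <- data
    if (!is.null(full$partition)) {
      test <- full[full$partition == "test"]
      train <- full[full$partition == "train"]
    } else train <- full
    windows <- train$windows
    labels <- train$labels
    window_length <- train$window_length
  } else {
    if (is.null(labels)) stop("labels required when data is not a dhu_dataset")
    windows <- as.character(data)
    labels <- check_binary_labels(labels, length(windows))
    window_length <- unique(nchar(windows))
  }
  enc_cfg <- list(encoders = encoders, props = props, max_lag = max_lag,
                  k = k, lam = lam, w = w, window_length = window_length)
  x <- encode_windows(windows, encoders, props, max_lag, k, lam, w)
  enc_of <- feature_encoder(x)

  selections <- lapply(encoders, function(e) {
    ifs(x[, enc_of == e, drop = FALSE], labels, grid = ifs_grid,
        stride = ifs_stride, folds = folds, seed = seed)
  })
  names(selections) <- encoders

  combos <- combination_search(x, labels, selections, arity = arity,
                               folds = folds, seed = seed)
  features <- unlist(lapply(combos$best, function(e) selections[[e]]$chosen),
                     use.names = FALSE)
  xsel <- x[, features, drop = FALSE]

  grid <- NULL
  spec_final <- model_spec("svm")
  if (tune) {
    grid <- grid_search_svm(xsel, labels, folds = folds, seed = seed,
                            c_exponents = c_exponents,
                            gamma_exponents = gamma_exponents)
    spec_final <- model_spec("svm", cost = grid$best$cost,
                             gamma = grid$best$gamma)
  }
  model <- train_model(xsel, labels, spec_final, seed = seed)

  obj <- structure(list(model = model, selections = selections,
                        combos = combos, grid = grid,
                        features = features, encoder_config = enc_cfg,
                        n_train = length(windows), seed = seed,
                        test_report = NULL),
                   class = "dhu_fit")
  if (!is.null(test) && length(test) > 0L) {
    obj$test_report <- evaluation_report(test$labels, predict(obj, test),
                                         context = "independent test")
  }
  obj
}

# Encode new windows with the fitted configuration and restrict to the
# model's feature set.
encode_for_fit <- function(object, windows) {
  cfg <- object$encoder_config
  need <- unique(feature_encoder(object$features))
  x <- encode_windows(windows, need, cfg$props, cfg$max_lag,
                      cfg$k, cfg$lam, cfg$w, window_length = cfg$window_length)
  x[, object$features, drop = FALSE]
}

#' Predict dihydrouridine scores for new windows
#'
#' @param object A [dhu_fit()].
#' @param newdata A [dhu_dataset()] or character vector of windows with the
#'   fitted window length.
#' @param type \code{"score"} (default) or \code{"class"}.
#' @param ... Unused.
#' @return Numeric scores in \code{[0, 1]} or 0/1 labels.
#' @export
predict.dhu_fit <- function(object, newdata, type = c("score", "class"), ...) {
  if (inherits(newdata, "dhu_dataset")) newdata <- newdata$windows
  predict(object$model, encode_for_fit(object, newdata), type = match.arg(type))
}

#' @export
print.dhu_fit <- function(x, ...) {
  cat("<dhu_fit> trained on ", x$n_train, " windows\n",
      "  combination: ", x$combos$results$combo[1L], " (",
      length(x$features), " features, selection CV AUROC ",
      sprintf("%.3f", x$combos$results$cv_auroc[1L]), ")\n", sep = "")
  if (!is.null(x$grid))
    cat(sprintf("  tuned SVM: C = 2^%g, gamma = 2^%g (CV AUROC %.3f)\n",
                log2(x$grid$best$cost), log2(x$grid$best$gamma),
                x$grid$best$cv_auroc))
  else
    cat("  SVM with default parameters (C = 1, gamma = 1/n_features)\n")
  if (!is.null(x$test_report))
    cat(sprintf("  independent test: AUROC %.3f, ACC %.3f\n",
                x$test_report$auroc, x$test_report$acc))
  invisible(x)
}

#' @export
summary.dhu_fit <- function(object, ...) {
  sel <- data.frame(encoder = names(object$selections),
                    n_features = vapply(object$selections, function(s)
                      length(s$scores), 0L),
                    chosen_n = vapply(object$selections, function(s)
                      s$chosen_n, 0L),
                    cv_auroc = vapply(object$selections, function(s)
                      max(s$curve$cv_auroc), 0),
                    row.names = NULL)
  out <- list(selection = sel,
              combinations = utils::head(object$combos$results, 10L),
              grid_best = if (!is.null(object$grid)) object$grid$best,
              test_report = object$test_report)
  class(out) <- "summary.dhu_fit"
  out
}

#' @export
print.summary.dhu_fit <- function(x, ...) {
  cat("Per-encoder incremental feature selection:\n")
  print(x$selection, digits = 3)
  cat("\nTop encoder combinations (5-fold CV AUROC):\n")
  print(x$combinations, digits = 3)
  if (!is.null(x$grid_best))
    cat(sprintf("\nTuned SVM: C = 2^%g, gamma = 2^%g (CV AUROC %.3f, AUPRC %.3f)\n",
                log2(x$grid_best$cost), log2(x$grid_best$gamma),
                x$grid_best$cv_auroc, x$grid_best$cv_auprc))
  if (!is.null(x$test_report)) { cat("\nIndependent test: "); print(x$test_report) }
  invisible(x)
}

#' Plot a fitted pipeline
#'
#' Draws the per-encoder IFS curves and, when the model was tuned, the
#' (C, gamma) CV-AUROC heatmap.
#'
#' @param x A [dhu_fit()].
#' @param which \code{"ifs"}, \code{"grid"} or both.
#' @param ... Passed to the underlying plotting calls.
#' @return Invisibly, \code{x}.
#' @export
plot.dhu_fit <- function(x, which = c("ifs", "grid"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if ("ifs" %in% which) {
    cols <- grDevices::hcl.colors(length(x$selections), "Dark 3")
    rng <- range(unlist(lapply(x$selections, function(s) s$curve$cv_auroc)))
    graphics::plot(NA, xlim = c(1, max(vapply(x$selections, function(s)
      max(s$curve$n), 0))), ylim = rng, log = "x",
      xlab = "top N features", ylab = "CV AUROC", ...)
    for (i in seq_along(x$selections))
      graphics::lines(x$selections[[i]]$curve$n,
                      x$selections[[i]]$curve$cv_auroc, col = cols[i])
    graphics::legend("bottomright", names(x$selections), col = cols,
                     lty = 1, cex = 0.7, bty = "n")
  }
  if ("grid" %in% which && !is.null(x$grid)) {
    g <- x$grid$grid
    ce <- sort(unique(log2(g$C))); ge <- sort(unique(log2(g$gamma)))
    z <- matrix(NA_real_, length(ce), length(ge))
    z[cbind(match(log2(g$C), ce), match(log2(g$gamma), ge))] <- g$cv_auroc
    graphics::image(ce, ge, z, xlab = "log2 C", ylab = "log2 gamma",
                    col = grDevices::hcl.colors(25, "RdYlGn"), ...)
  }
  invisible(x)
}

#' Outer cross-validation of the whole pipeline
#'
#' Evaluates the pipeline as an honest procedure: within each of
#' \code{folds} outer stratified folds, feature selection and model fitting
#' run on the training folds only ([dhu_fit()]), and the held-out fold is
#' scored by the resulting model. Out-of-fold scores are pooled into one
#' AUROC. Because selection never sees the held-out windows, this estimate
#' is unbiased — on label-free (null) data it concentrates around 0.5.
#'
#' @param data A [dhu_dataset()] or character windows (any partition is
#'   ignored; all windows participate).
#' @param labels 0/1 vector when \code{data} is a plain vector.
#' @param folds Outer folds (default 5).
#' @param seed Seed for the outer assignment (inner seeds derive from it).
#' @param tune Tune (C, gamma) inside each outer fold (default FALSE: the
#'   inner pipeline keeps libsvm default parameters, the configuration used
#'   during feature optimization).
#' @param ... Passed to [dhu_fit()].
#' @return Object of class \code{dhu_pipeline_cv}: \code{pooled} report,
#'   \code{per_fold} reports, pooled \code{scores}, \code{fold} assignment
#'   and the per-fold winning combinations.
#' @export
dhu_cv <- function(data, labels = NULL, folds = 5L, seed = 1L, tune = FALSE, ...) {
  if (inherits(data, "dhu_dataset")) {
    windows <- data$windows; labels <- data$labels
  } else {
    windows <- as.character(data)
    if (is.null(labels)) stop("labels required when data is not a dhu_dataset")
  }
  labels <- check_binary_labels(labels, length(windows))
  fold <- stratified_folds(labels, folds, seed)
  scores <- numeric(length(labels))
  combos <- character(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- dhu_fit(windows[tr], labels[tr], tune = tune,
                   seed = seed + f, folds = folds, ...)
    scores[!tr] <- predict(fit, windows[!tr])
    combos[f] <- fit$combos$results$combo[1L]
  }
  per_fold <- lapply(seq_len(folds), function(f)
    evaluation_report(labels[fold == f], scores[fold == f],
                      context = paste0("outer fold ", f)))
  structure(list(pooled = evaluation_report(labels, scores,
                                            context = "pipeline outer CV, pooled"),
                 per_fold = per_fold, scores = scores, fold = fold,
                 fold_combos = combos, seed = seed),
            class = "dhu_pipeline_cv")
}

#' @export
print.dhu_pipeline_cv <- function(x, ...) {
  print(x$pooled)
  cat("  per-fold winning combinations: ",
      paste(unique(x$fold_combos), collapse = "; "), "\n", sep = "")
  invisible(x)
}
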