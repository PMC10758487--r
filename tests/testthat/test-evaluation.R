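test_that("confusion metrics follow the printed Sn/Sp/Acc formulas", {
  labels <- c(rep(1, 4), rep(0, 4))
  pred <- c(1, 1, 1, 0, 0, 0, 0, 0)   # TP 3, FN 1, TN 4, FP 0
  cm <- confusion_metrics(labels, pred)
  expect_identical(cm[c("TP", "FP", "TN", "FN")],
                   list(TP = 3L, FP = 0L, TN = 4L, FN = 1L))
  expect_equal(cm$sn, 0.75)
  expect_equal(cm$sp, 1.0)
  expect_equal(cm$acc, 0.875)

  same <- confusion_metrics(labels, labels)
  expect_equal(c(same$sn, same$sp, same$acc), c(1, 1, 1))
  inv <- confusion_metrics(labels, 1 - labels)
  expect_equal(c(inv$sn, inv$sp, inv$acc), c(0, 0, 0))
  expect_error(confusion_metrics(rep(1, 4), c(1, 0, 1, 0)), "both classes")
})

test_that("AUROC equals the pairwise-probability oracle to 1e-12", {
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(auroc(c(1, 1, 0, 0), rep(0.5, 4)), 0.5)
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2)), 0.75)
  expect_error(auroc(rep(1, 3), 1:3), "both classes")

  set.seed(41)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- if (i %% 3 == 0) sample(1:5, n, replace = TRUE) else rnorm(n)
    expect_equal(auroc(labels, scores), brute_auroc(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly increasing score transforms and matches pROC", {
  set.seed(42)
  labels <- rbinom(60, 1, 0.5); labels[1:2] <- c(0, 1)
  scores <- rnorm(60)
  a <- auroc(labels, scores)
  expect_equal(auroc(labels, exp(scores)), a, tolerance = 1e-12)
  expect_equal(auroc(labels, rank(scores)), a, tolerance = 1e-12)
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                 direction = "<"))),
               tolerance = 1e-12)
})

test_that("AUPRC follows the step-wise rule, checked by hand enumeration", {
  expect_equal(auprc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(auprc(c(0, 0, 1, 0), c(0.2, 0.1, 0.9, 0.3)), 1.0)  # lone positive first
  # thresholds at .8 (TP1 FP0), .7 (TP1 FP1), .6 (TP2 FP1), .5 (TP2 FP2):
  # area = 0.5*1 + 0*0.5 + 0.5*(2/3) = 5/6
  expect_equal(auprc(c(1, 0, 1, 0), c(0.8, 0.7, 0.6, 0.5)), 5 / 6)
  expect_error(auprc(rep(0, 4), 1:4), "positive")

  set.seed(43)
  labels <- rbinom(2000, 1, 0.3)
  expect_equal(auprc(labels, runif(2000)), mean(labels), tolerance = 0.08)
})

test_that("cross-validation pools out-of-fold scores and keeps per-fold reports", {
  set.seed(44)
  x <- rbind(matrix(rnorm(40, 2, 0.2), 20, 2), matrix(rnorm(40, -2, 0.2), 20, 2))
  colnames(x) <- c("f1", "f2")
  labels <- rep(c(1, 0), each = 20)
  cv <- cross_validate(x, labels, folds = 5, seed = 6)
  expect_equal(cv$pooled$auroc, 1.0)
  expect_length(cv$per_fold, 5L)
  expect_length(cv$scores, 40L)

  # boundary: leave-one-out per class (folds = class size)
  xs <- x[c(1:5, 21:25), ]
  ls <- labels[c(1:5, 21:25)]
  cv5 <- cross_validate(xs, ls, folds = 5, seed = 1)
  expect_length(cv5$scores, 10L)
  expect_error(cross_validate(xs, ls, folds = 6, seed = 1), "fold count")
})

test_that("positional composition recovers planted enrichment and normalizes rows", {
  pos <- rep("AGUAA", 10)          # G planted at offset -1 from center
  neg <- random_windows(50, L = 5, seed = 45)
  comp <- positional_composition(c(pos, neg), rep(c(1, 0), c(10, 50)))
  expect_equal(unname(comp$positive[2, "G"]), 1.0)
  expect_equal(unname(rowSums(comp$positive)), rep(1, 5))
  expect_equal(unname(rowSums(comp$negative)), rep(1, 5))
  expect_true(all(abs(comp$negative[-3, ] - 0.25) < 0.25))
  expect_error(positional_composition(pos, rep(1, 10)), ">= 1 window")
})

test_that("evaluation reports serialize the counts they were computed from", {
  set.seed(46)
  labels <- rep(c(1, 0), each = 15)
  scores <- plogis(labels + rnorm(30))
  rep_ <- evaluation_report(labels, scores, context = "unit")
  with(rep_$counts, {
    expect_identical(TP + FP + TN + FN, 30L)
  })
  expect_equal(rep_$sn, rep_$counts$TP / (rep_$counts$TP + rep_$counts$FN))
  expect_equal(rep_$sp, rep_$counts$TN / (rep_$counts$TN + rep_$counts$FP))
})

test_that("ROC/PR curve points integrate back to the scalar metrics", {
  set.seed(47)
  labels <- rbinom(40, 1, 0.5); labels[1:2] <- c(0, 1)
  scores <- round(runif(40), 2)    # force some ties
  rc <- roc_curve(labels, scores)
  expect_equal(sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2),
               auroc(labels, scores), tolerance = 1e-12)
  pc <- pr_curve(labels, scores)
  expect_equal(sum(diff(c(0, pc$recall)) * pc$precision),
               auprc(labels, scores), tolerance = 1e-12)
  # Youden threshold separates a separable score vector perfectly
  thr <- youden_threshold(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(thr, 0.8)
})
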