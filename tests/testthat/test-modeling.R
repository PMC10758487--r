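make_separable <- function() {
  x <- rbind(matrix(rnorm(8, mean = 3, sd = 0.1), 4, 2),
             matrix(rnorm(8, mean = -3, sd = 0.1), 4, 2))
  colnames(x) <- c("f.a", "f.b")
  list(x = x, labels = rep(c(1, 0), each = 4))
}

test_that("every algorithm separates a separable toy and exposes [0,1] scores", {
  set.seed(31)
  toy <- make_separable()
  for (alg in c("svm", "glm", "rf", "nb")) {
    m <- train_model(toy$x, toy$labels, model_spec(alg), seed = 2)
    sc <- predict(m, toy$x)
    expect_true(all(sc >= 0 & sc <= 1), info = alg)
    expect_equal(auroc(toy$labels, sc), 1.0, info = alg)
    expect_equal(predict(m, toy$x, type = "class"), toy$labels, info = alg)
  }
})

test_that("training and prediction are deterministic under a fixed seed", {
  set.seed(32)
  labels <- rep(c(1, 0), each = 20)
  x <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("f", 1:6)))
  for (alg in c("svm", "rf")) {
    m1 <- train_model(x, labels, model_spec(alg), seed = 9)
    m2 <- train_model(x, labels, model_spec(alg), seed = 9)
    expect_identical(predict(m1, x), predict(m2, x), info = alg)
  }
})

test_that("held-out performance on label-permuted data sits near chance", {
  set.seed(33)
  labels <- rep(c(1, 0), each = 40)
  x <- matrix(rnorm(80 * 10), 80, 10, dimnames = list(NULL, paste0("f", 1:10)))
  cv <- cross_validate(x, labels, model_spec("svm"), folds = 5, seed = 4)
  band <- auroc_null_band(40, 40, n_perm = 1000, seed = 5)
  expect_gt(cv$pooled$auroc, band[1] - 0.05)
  expect_lt(cv$pooled$auroc, band[2] + 0.05)
})

test_that("prediction validates feature columns by name and order", {
  toy <- make_separable()
  m <- train_model(toy$x, toy$labels, model_spec("svm"), seed = 1)
  expect_length(predict(m, toy$x), 8L)
  bad <- toy$x[, c(2, 1)]
  expect_error(predict(m, bad), "out of order")
  expect_error(predict(m, toy$x[, 1, drop = FALSE]), "missing: f.b")
  extra <- cbind(toy$x, f.c = 1)
  expect_error(predict(m, extra), "extra: f.c")
})

test_that("constant features are scaled to zero with a warning", {
  toy <- make_separable()
  x <- cbind(toy$x, f.const = 5)
  expect_warning(m <- train_model(x, toy$labels, model_spec("svm"), seed = 1),
                 "constant")
  expect_equal(auroc(toy$labels, predict(m, x)), 1.0)
})

test_that("the fast SVM decision path agrees with e1071's predict", {
  set.seed(34)
  for (rep in 1:10) {
    n <- sample(20:40, 1)
    d <- sample(2:8, 1)
    x <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("f", 1:d)))
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))     # both classes guaranteed
    if (rep %% 2 == 0) labels <- 1 - labels       # exercise both label orders
    m <- train_model(x, labels, model_spec("svm"), seed = 1)
    ours <- predict(m, x)
    xs <- sweep(sweep(x, 2, m$center), 2, m$scale, "/")
    ref <- attr(predict(m$fit, xs, decision.values = TRUE), "decision.values")
    sign_ref <- if (colnames(ref)[1] == "1/0") drop(ref) else -drop(ref)
    expect_equal(ours, unname(plogis(sign_ref)), tolerance = 1e-10)
  }
})

test_that("grid search bookkeeping: degenerate grid, argmax and tie rules", {
  set.seed(35)
  labels <- rep(c(1, 0), each = 15)
  x <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("f", 1:4)))
  x[, 1] <- labels + rnorm(30, sd = 0.3)

  g1 <- grid_search_svm(x, labels, seed = 2, c_exponents = 3, gamma_exponents = -2)
  expect_identical(nrow(g1$grid), 1L)
  expect_identical(g1$best$cost, 2^3)
  expect_identical(g1$best$gamma, 2^-2)

  g <- grid_search_svm(x, labels, seed = 2, c_exponents = c(-1, 1, 3),
                       gamma_exponents = c(-4, -2))
  expect_identical(nrow(g$grid), 6L)
  expect_true(all(g$grid$cv_auroc >= 0 & g$grid$cv_auroc <= 1))
  expect_true(all(g$grid$cv_auprc >= 0 & g$grid$cv_auprc <= 1))
  # brute-force scan of the serialized grid under the stated tie rule
  gg <- g$grid[order(-g$grid$cv_auroc, -g$grid$cv_auprc, g$grid$C, g$grid$gamma), ]
  expect_identical(g$best$cost, gg$C[1])
  expect_identical(g$best$gamma, gg$gamma[1])
  expect_equal(g$best$cv_auroc, max(g$grid$cv_auroc))

  tf <- tempfile(fileext = ".tsv")
  write_grid(g, tf)
  expect_identical(nrow(read.table(tf, header = TRUE)), 6L)
})
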