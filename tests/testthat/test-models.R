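# Linear models, CART and tree ensembles.

test_that("fixed-coefficient predictor applies the printed coefficients", {
  expect_equal(eq13_predict(c(estrada = 0, wiener = 0, gutman = 0)),
               -417.6882)
  # coefficient read-off by finite difference
  expect_equal(eq13_predict(c(estrada = 1, wiener = 0, gutman = 0)) -
                 eq13_predict(c(estrada = 0, wiener = 0, gutman = 0)), 90)
  # benzene worked example (indices of the explicit-H graph)
  expect_equal(eq13_predict(c(estrada = 28.7159, wiener = 174,
                              gutman = 570)), 2139.8682,
               tolerance = 1e-9)
  # data.frame input vectorizes
  df <- data.frame(estrada = c(0, 1), wiener = 0, gutman = 0)
  expect_equal(eq13_predict(df), c(-417.6882, -327.6882))
})

test_that("OLS recovers exact and noiseless relationships", {
  m <- ols_fit(data.frame(x = c(0, 1)), c(0, 1))
  expect_equal(unname(coef(m)), c(0, 1))
  tab <- descriptor_table(series_smiles("n-alkane", 1:12)$smiles)
  y <- 90 * tab$estrada - 417.6882
  fit <- ols_fit(tab[, "estrada", drop = FALSE], y)
  expect_equal(unname(coef(fit)), c(-417.6882, 90), tolerance = 1e-8)
  # rank deficiency is reported
  expect_error(ols_fit(data.frame(a = 1:5, b = 2 * (1:5)), rnorm(5)),
               "rank-deficien")
})

test_that("ridge shrinks toward zero and meets OLS at alpha = 0", {
  set.seed(12)
  x <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- 3 * x[, 1] - x[, 2] + rnorm(30, 0, 0.1)
  r0 <- ridge_fit(x, y, alpha = 0)
  o <- ols_fit(x, y)
  expect_equal(coef(r0), coef(o), tolerance = 1e-10)
  rbig <- ridge_fit(x, y, alpha = 1e8)
  expect_lt(sum(abs(rbig$coefficients)), 1e-3)
  expect_equal(rbig$intercept, mean(y), tolerance = 1e-3)
})

test_that("Huber matches OLS on clean data and resists gross outliers", {
  set.seed(9)
  x <- data.frame(x = 1:20)
  y_clean <- 2 * x$x + 1 + rnorm(20, 0, 0.1)
  h <- huber_fit(x, y_clean, epsilon = 10, alpha = 0)
  o <- ols_fit(x, y_clean)
  expect_equal(coef(h), coef(o), tolerance = 1e-6)
  # one gross outlier: Huber slope closer to truth than OLS slope
  y_out <- y_clean
  y_out[20] <- y_out[20] + 200
  h2 <- huber_fit(x, y_out, epsilon = 1.35, alpha = 0)
  o2 <- ols_fit(x, y_out)
  expect_lt(abs(coef(h2)[["x"]] - 2), abs(coef(o2)[["x"]] - 2))
  # heavy penalty shrinks coefficients toward zero
  h3 <- huber_fit(x, y_clean, epsilon = 10, alpha = 1e8)
  expect_lt(abs(h3$coefficients[["x"]]), 1e-3)
  skip_if_not_installed("MASS")
  rlm_fit <- MASS::rlm(y_out ~ x$x, psi = MASS::psi.huber, k = 1.35)
  expect_equal(unname(coef(h2)[["x"]]), unname(coef(rlm_fit)[2]),
               tolerance = 0.05)
})

test_that("CART finds the optimal split and respects stopping rules", {
  # constant response: single leaf
  t0 <- tree_fit(data.frame(x = 1:6), rep(4, 6))
  expect_true(t0$root$leaf)
  expect_equal(t0$root$value, 4)
  # step function: split at the midpoint 5.5
  t1 <- tree_fit(data.frame(x = 1:10), c(rep(0, 5), rep(1, 5)),
                 max_depth = 1)
  expect_equal(t1$root$threshold, 5.5)
  expect_equal(sort(c(t1$root$left$value, t1$root$right$value)), c(0, 1))
  # predictions are the leaf means
  expect_equal(predict(t1, data.frame(x = c(2, 9))), c(0, 1))
})

test_that("CART splits agree with exhaustive (j, s) enumeration", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    x <- matrix(round(rnorm(2 * n), 2), n, 2,
                dimnames = list(NULL, c("a", "b")))
    y <- round(rnorm(n), 2)
    oracle <- brute_force_split(x, y)
    if (is.null(oracle)) next
    fit <- tree_fit(x, y, max_depth = 1)
    expect_false(fit$root$leaf)
    expect_equal(fit$root$feature, oracle$feature)
    expect_equal(fit$root$threshold, oracle$threshold)
  }
})

test_that("forests collapse to a single tree and stay in the target range", {
  set.seed(5)
  x <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- 5 * x[, 1] + rnorm(40)
  f1 <- forest_fit(x, y, "rf", n_estimators = 1, bootstrap = FALSE,
                   seed = 1)
  t1 <- tree_fit(x, y)
  grid <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict(f1, grid), predict(t1, grid))
  # constant y
  fc <- forest_fit(x, rep(2, 40), "rf", n_estimators = 5, seed = 1)
  expect_equal(predict(fc, grid), rep(2, 10))
  # mean-of-leaf-means bound
  f <- forest_fit(x, y, "rf", n_estimators = 20, seed = 3)
  p <- predict(f, matrix(rnorm(40, sd = 4), 20, 2,
                         dimnames = list(NULL, c("a", "b"))))
  expect_true(all(p >= min(y) & p <= max(y)))
})

test_that("identical seeds give bit-identical forests; ET differs from RF", {
  set.seed(8)
  x <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- x[, 1] - 2 * x[, 2] + rnorm(30, 0, 0.2)
  fa <- forest_fit(x, y, "rf", n_estimators = 10, seed = 11)
  fb <- forest_fit(x, y, "rf", n_estimators = 10, seed = 11)
  expect_identical(predict(fa, x), predict(fb, x))
  fe <- forest_fit(x, y, "et", n_estimators = 10, seed = 11)
  expect_false(identical(predict(fa, x), predict(fe, x)))
  p <- predict(fe, x)
  expect_true(all(p >= min(y) & p <= max(y)))
})

test_that("forest averaging reduces test error relative to one tree", {
  set.seed(21)
  n <- 120
  x <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- x[, 1]^2 + x[, 2] + rnorm(n, 0, 0.5)
  tr <- 1:80; te <- 81:n
  single <- tree_fit(x[tr, ], y[tr])
  forest <- forest_fit(x[tr, ], y[tr], "rf", n_estimators = 100, seed = 4)
  mse <- function(p) mean((y[te] - p)^2)
  expect_lte(mse(predict(forest, x[te, ])), mse(predict(single, x[te, ])))
})

test_that("impurity importance identifies the dominant feature", {
  set.seed(14)
  n <- 100
  x <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  y1 <- 4 * x[, 1]                     # only x1 matters
  f1 <- forest_fit(x, y1, "rf", n_estimators = 20, seed = 2)
  imp1 <- impurity_importance(f1)
  expect_equal(sum(imp1), 1, tolerance = 1e-9)
  expect_gt(imp1[["x1"]], 0.95)
  y2 <- 5 * x[, 1] + x[, 2] + rnorm(n, 0, 0.3)
  f2 <- forest_fit(x, y2, "rf", n_estimators = 20, seed = 2)
  imp2 <- impurity_importance(f2)
  expect_gt(imp2[["x1"]], imp2[["x2"]])
  expect_error(impurity_importance(list()), "not a fitted")
})
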