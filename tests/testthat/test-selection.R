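# Scaling, hold-out, cross-validation, random search, nested CV,
# learning curves.

test_that("z-score scaling centers to zero mean and unit population sd", {
  sc <- zscore_fit(data.frame(a = c(1, 2, 3)))
  z <- zscore_apply(sc, data.frame(a = c(1, 2, 3)))
  expect_equal(unname(z[, 1]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  # idempotence on standardized input
  z2 <- zscore_apply(zscore_fit(z), z)
  expect_equal(z2, z, tolerance = 1e-12)
  # constant columns map to zero with a warning
  expect_warning(scc <- zscore_fit(data.frame(a = 1:4, b = rep(7, 4))),
                 "constant")
  expect_equal(unname(zscore_apply(scc, data.frame(a = 1:4,
                                                   b = rep(7, 4)))[, 2]),
               rep(0, 4))
})

test_that("hold-out splits partition at the rounded fraction", {
  s <- holdout_split(10, 0.7, seed = 1)
  expect_equal(length(s$train), 7L)
  expect_equal(length(s$test), 3L)
  expect_equal(sort(c(s$train, s$test)), 1:10)
  expect_identical(holdout_split(50, 0.7, seed = 9),
                   holdout_split(50, 0.7, seed = 9))
  big <- holdout_split(3477, 0.7, seed = 2)
  expect_equal(length(big$train), 2434L)
  expect_equal(length(big$test), 1043L)
  expect_error(holdout_split(100, 1.2), "fraction")
})

test_that("k-fold CV validates every sample exactly once", {
  set.seed(3)
  n <- 24
  fold_ids <- qsprgraph:::.fold_assign(n, 5L, seed = 7)
  expect_equal(sort(unique(fold_ids)), 1:5)
  expect_equal(length(fold_ids), n)
  expect_true(max(table(fold_ids)) - min(table(fold_ids)) <= 1)
})

test_that("noiseless linear data gives perfect CV metrics", {
  tab <- descriptor_table(series_smiles("n-alkane", 1:20)$smiles)
  y <- 90 * tab$estrada - 400
  rep5 <- kfold_evaluate(model_spec("ols"), tab[, "estrada", drop = FALSE],
                         y, k = 5, seed = 1)
  expect_lt(rep5$mean[["mae"]], 1e-6)
  expect_equal(rep5$mean[["r2"]], 1, tolerance = 1e-9)
  # reported mean equals the arithmetic mean of fold values
  expect_equal(rep5$mean[["mae"]], mean(rep5$folds[, "mae"]),
               tolerance = 1e-12)
  # leave-one-out shape is allowed
  loo <- kfold_evaluate(model_spec("ols"), tab[, "estrada", drop = FALSE],
                        y, k = 20, seed = 1)
  expect_equal(nrow(loo$folds), 20L)
})

test_that("validation folds never leak into fitting", {
  set.seed(4)
  x <- data.frame(x = rnorm(30))
  y <- 2 * x$x + rnorm(30, 0, 0.1)
  fold <- qsprgraph:::.fold_assign(30, 5L, seed = 2)
  # corrupt the targets of fold 1 and refit on folds 2..5 only: the
  # fitted coefficients must not change
  spec <- model_spec("ols")
  tr <- fold != 1L
  m1 <- qsprgraph:::.fit_spec(spec, as.matrix(x)[tr, , drop = FALSE], y[tr])
  y_bad <- y
  y_bad[!tr] <- 1e6
  m2 <- qsprgraph:::.fit_spec(spec, as.matrix(x)[tr, , drop = FALSE],
                              y_bad[tr])
  expect_identical(coef(m1), coef(m2))
})

test_that("random search returns the best configuration on clean data", {
  tab <- descriptor_table(series_smiles("n-alkane", 1:15)$smiles)
  y <- 90 * tab$estrada - 400
  # alpha = 0 is exactly right for noiseless data; large alpha is not
  rs <- random_search("ridge", list(alpha = c(0, 10, 1000)),
                      tab[, "estrada", drop = FALSE], y,
                      n_iter = 12, cv = 3, seed = 5)
  expect_equal(rs$best_params$alpha, 0)
  expect_lt(rs$best_score, 1e-6)
  # single-draw search returns that draw
  rs1 <- random_search("ridge", list(alpha = c(0.5)),
                       tab[, "estrada", drop = FALSE], y,
                       n_iter = 1, cv = 3, seed = 5)
  expect_equal(rs1$best_params$alpha, 0.5)
  # seeded repeatability of the sampled sequence
  rs2 <- random_search("ridge", list(alpha = c(0, 10, 1000)),
                       tab[, "estrada", drop = FALSE], y,
                       n_iter = 12, cv = 3, seed = 5)
  expect_equal(rs$trace, rs2$trace)
  expect_error(random_search("ridge", list(), tab, y), "non-empty")
})

test_that("nested CV partitions outer folds and bounds noisy error", {
  tab <- descriptor_table(series_smiles("n-alkane", 1:40)$smiles)
  tab2 <- descriptor_table(series_smiles("monocarboxylic-acid", 1:40)$smiles)
  X <- rbind(tab, tab2)[, "estrada", drop = FALSE]
  sigma <- 10
  set.seed(6)
  y <- pmax(90 * rbind(tab, tab2)$estrada - 300 + rnorm(80, 0, sigma), 1)
  ncvr <- nested_cv("ridge", list(alpha = c(0, 0.001, 0.01)), X, y,
                    outer = 5, inner = 3, n_iter = 4, seed = 3)
  expect_equal(nrow(ncvr$folds), 5L)
  expect_lt(ncvr$mean[["mae"]], 3 * sigma)
  expect_length(ncvr$per_fold_params, 5L)
  # noiseless single-predictor family: all outer folds perfect
  y0 <- 90 * tab$estrada + 100
  ncv0 <- nested_cv("ridge", list(alpha = c(0)), tab[, "estrada",
                                                     drop = FALSE],
                    y0, outer = 5, inner = 3, n_iter = 1, seed = 3)
  expect_true(all(abs(ncv0$folds[, "r2"] - 1) < 1e-9))
})

test_that("learning curves meet k-fold CV at fraction 1", {
  set.seed(10)
  x <- data.frame(x = rnorm(60))
  y <- pmax(3 + 2 * x$x + rnorm(60, 0, 0.5), 0.1)
  spec <- model_spec("ols")
  lc <- learning_curve(spec, x, y, fractions = c(0.5, 1), k = 5, seed = 2)
  full <- kfold_evaluate(spec, x, y, k = 5, seed = 2)
  expect_equal(lc$validation[2], full$mean[["rmse"]])
  # train error does not exceed validation error under noise
  expect_true(all(lc$train <= lc$validation))
  expect_error(learning_curve(spec, x, y, fractions = c(0.9, 0.5)),
               "increasing")
})

test_that("CV reports serialize as metric -> {mean, std, folds}", {
  set.seed(2)
  x <- data.frame(x = rnorm(30))
  y <- pmax(5 + x$x + rnorm(30, 0, 0.2), 0.5)
  r <- kfold_evaluate(model_spec("ols"), x, y, k = 3, seed = 1)
  parsed <- jsonlite::fromJSON(cv_report_json(r))
  expect_named(parsed, c("r2", "mae", "mape", "rmse", "rmsle"))
  expect_named(parsed$rmse, c("mean", "std", "folds"))
  expect_length(parsed$rmse$folds, 3L)
  expect_equal(parsed$rmse$mean, mean(parsed$rmse$folds))
})
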