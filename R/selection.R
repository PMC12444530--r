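# Evaluation protocols: z-score scaling, hold-out split, k-fold CV,
# random hyperparameter search, nested CV, learning curves.
#
# Scaling is always refit inside each training fold so no statistic of a
# validation fold leaks into the fit.

#' Fit a z-score scaler on training rows
#'
#' Centers to zero mean and scales to unit *population* standard
#' deviation per column.  Constant columns are mapped to zero (scale 1)
#' with a warning.
#'
#' @param X numeric matrix or data.frame (training rows only)
#' @return object of class \code{zscaler}.
#' @export
zscore_fit <- function(X) {
  x <- as.matrix(as.data.frame(X))
  mu <- colMeans(x)
  n <- nrow(x)
  sdev <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  if (any(sdev == 0)) {
    warning(sprintf("constant column(s) map to zero after scaling: %s",
                    paste(colnames(x)[sdev == 0], collapse = ", ")),
            call. = FALSE)
    sdev[sdev == 0] <- 1
  }
  structure(list(mean = mu, sd = sdev), class = "zscaler")
}

#' @rdname zscore_fit
#' @param scaler a fitted \code{zscaler}
#' @return \code{zscore_apply()} returns the transformed matrix.
#' @export
zscore_apply <- function(scaler, X) {
  stopifnot(inherits(scaler, "zscaler"))
  x <- as.matrix(as.data.frame(X))
  sweep(sweep(x[, names(scaler$mean), drop = FALSE], 2L, scaler$mean),
        2L, scaler$sd, "/")
}

#' Random hold-out split plan
#'
#' Uniform random permutation split; \code{|train| = round(fraction * n)}.
#'
#' @param n number of samples
#' @param fraction training fraction in (0, 1); default 0.7
#' @param seed RNG seed
#' @return list with \code{train}, \code{test} index vectors,
#'   \code{fraction}, \code{seed}.
#' @export
holdout_split <- function(n, fraction = 0.7, seed = 42L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  stopifnot(n >= 10L)
  set.seed(seed)
  perm <- sample.int(n)
  ntr <- round(fraction * n)
  list(train = sort(perm[seq_len(ntr)]), test = sort(perm[-seq_len(ntr)]),
       fraction = fraction, seed = seed)
}

#' Model specification for the evaluation protocols
#'
#' Bundles a fitting function and its hyperparameters under a short name
#' so CV drivers can re-fit the model inside every fold.  Built-in names:
#' \code{"ols"}, \code{"ridge"}, \code{"huber"}, \code{"tree"},
#' \code{"rf"}, \code{"et"}, \code{"eq13"}.
#'
#' @param name built-in model name, or a fitting function
#'   \code{function(X, y, ...) model} whose result has a `predict` method
#' @param ... hyperparameters forwarded to the fitting function
#' @param scale z-score predictors inside each training fold (default
#'   TRUE; ignored by \code{"eq13"}, which uses raw indices)
#' @return object of class \code{model_spec}.
#' @export
model_spec <- function(name, ..., scale = TRUE) {
  params <- list(...)
  if (is.function(name)) {
    fit <- name; label <- "custom"
  } else {
    label <- match.arg(name, c("ols", "ridge", "huber", "tree", "rf",
                               "et", "eq13"))
    fit <- switch(label,
      ols = ols_fit, ridge = ridge_fit, huber = huber_fit,
      tree = tree_fit,
      rf = function(X, y, ...) forest_fit(X, y, kind = "rf", ...),
      et = function(X, y, ...) forest_fit(X, y, kind = "et", ...),
      eq13 = function(X, y, ...) eq13_model())
    if (label == "eq13") scale <- FALSE
  }
  structure(list(label = label, fit = fit, params = params, scale = scale),
            class = "model_spec")
}

.fit_spec <- function(spec, X, y) {
  do.call(spec$fit, c(list(X, y), spec$params))
}

# k near-equal folds over a seeded permutation
.fold_assign <- function(n, k, seed) {
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  rep(seq_len(k), times = sizes)[order(perm)]
}

.metric_names <- c("r2", "mae", "mape", "rmse", "rmsle")

.report_from_folds <- function(folds_mat, k, seed) {
  means <- colMeans(folds_mat)
  sds <- apply(folds_mat, 2L, stats::sd)   # sample sd (ddof = 1)
  structure(list(mean = means, sd = sds, folds = folds_mat, k = k,
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 4, ...) {
  cat(sprintf("%d-fold cross-validation (seed %s)\n", x$k, x$seed))
  for (m in colnames(x$folds))
    cat(sprintf("  %-6s %.*f +/- %.*f\n", toupper(m), digits, x$mean[[m]],
                digits, x$sd[[m]]))
  invisible(x)
}

#' Serialize a CV report to JSON
#'
#' Layout mirrors the mean-and-standard-deviation reporting of the
#' validation tables: \code{metric -> \{mean, std, folds\}}.
#'
#' @param x a \code{cv_report}
#' @return JSON string.
#' @export
cv_report_json <- function(x) {
  stopifnot(inherits(x, "cv_report"))
  out <- lapply(colnames(x$folds), function(m)
    list(mean = x$mean[[m]], std = x$sd[[m]], folds = unname(x$folds[, m])))
  names(out) <- colnames(x$folds)
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
}

#' k-fold cross-validation of a model specification
#'
#' The model (and, when requested, the z-score scaler) is refit on each
#' set of k-1 training folds and evaluated on the held-out fold; every
#' sample is validated exactly once.
#'
#' @param spec a [model_spec()]
#' @param X predictors
#' @param y numeric response
#' @param k number of folds (default 10)
#' @param seed RNG seed controlling the fold assignment
#' @param return_train also compute metrics on each fold's training part
#' @return a \code{cv_report}; with \code{return_train = TRUE} the report
#'   gains a \code{train} element of the same shape.
#' @export
kfold_evaluate <- function(spec, X, y, k = 10L, seed = 42L,
                           return_train = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(as.data.frame(X)); y <- as.numeric(y)
  n <- nrow(x)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k cannot exceed the number of samples", call. = FALSE)
  fold <- .fold_assign(n, k, seed)
  val <- matrix(NA_real_, k, length(.metric_names),
                dimnames = list(NULL, .metric_names))
  trn <- val
  for (f in seq_len(k)) {
    tr <- fold != f
    xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
    xte <- x[!tr, , drop = FALSE]; yte <- y[!tr]
    if (spec$scale) {
      sc <- zscore_fit(xtr)
      xtr <- zscore_apply(sc, xtr); xte <- zscore_apply(sc, xte)
    }
    m <- .fit_spec(spec, xtr, ytr)
    pe <- .safe_eval(yte, predict(m, xte))
    val[f, ] <- unlist(pe[.metric_names])
    if (return_train) {
      pt <- .safe_eval(ytr, predict(m, xtr))
      trn[f, ] <- unlist(pt[.metric_names])
    }
  }
  rep <- .report_from_folds(val, k, seed)
  if (return_train) rep$train <- .report_from_folds(trn, k, seed)
  rep
}

# fold-level evaluation tolerant of degenerate cases: single-observation
# folds make R2 undefined, and a linear fit can emit slightly negative
# predictions that take RMSLE out of its domain; such entries become NA
# rather than aborting the protocol
.safe_eval <- function(y, yhat) {
  res <- y - yhat
  list(mae = mean(abs(res)), rmse = sqrt(mean(res^2)),
       mape = if (any(y == 0)) NA_real_ else mean(abs(res) / abs(y)),
       rmsle = if (any(y < 0) || any(yhat < 0)) NA_real_ else
         sqrt(mean((log1p(yhat) - log1p(y))^2)),
       r2 = if (length(y) >= 2L)
         1 - sum(res^2) / sum((y - mean(y))^2) else NA_real_,
       n = length(y))
}

#' Random hyperparameter search with inner cross-validation
#'
#' Samples \code{n_iter} configurations uniformly from a finite grid and
#' scores each by the inner-CV mean of \code{metric}; the configuration
#' minimizing it wins (R2 is maximized).
#'
#' @param name built-in model name passed to [model_spec()]
#' @param space named list of candidate value vectors
#' @param X,y data
#' @param n_iter number of sampled configurations
#' @param cv number of inner folds (default 5)
#' @param seed RNG seed (sampling and fold assignment)
#' @param metric selection metric, one of \code{"rmse"}, \code{"mae"},
#'   \code{"mape"}, \code{"rmsle"}, \code{"r2"}
#' @param scale z-score inside folds
#' @return list with \code{best_params}, \code{best_score},
#'   \code{report} (the winner's \code{cv_report}) and the full
#'   \code{trace} data.frame.
#' @export
random_search <- function(name, space, X, y, n_iter = 10L, cv = 5L,
                          seed = 42L, metric = "rmse", scale = TRUE) {
  if (!is.list(space) || length(space) == 0L || is.null(names(space)))
    stop("`space` must be a non-empty named list", call. = FALSE)
  stopifnot(n_iter >= 1L)
  metric <- match.arg(metric, .metric_names)
  set.seed(seed)
  configs <- lapply(seq_len(n_iter), function(i)
    lapply(space, function(v) v[[sample.int(length(v), 1L)]]))
  scores <- numeric(n_iter)
  reports <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    spec <- do.call(model_spec, c(list(name), configs[[i]],
                                  list(scale = scale)))
    reports[[i]] <- kfold_evaluate(spec, X, y, k = cv, seed = seed)
    scores[i] <- reports[[i]]$mean[[metric]]
  }
  best <- if (metric == "r2") which.max(scores) else which.min(scores)
  trace <- cbind(do.call(rbind, lapply(configs, as.data.frame)),
                 score = scores)
  list(best_params = configs[[best]], best_score = scores[best],
       report = reports[[best]], metric = metric, trace = trace)
}

#' Nested cross-validation
#'
#' Hyperparameters are selected by [random_search()] on the inner folds
#' of each outer-training set only; outer test folds never influence
#' selection.  Reported as mean and standard deviation over outer folds.
#'
#' @inheritParams random_search
#' @param outer,inner numbers of outer and inner folds (default 5 and 3)
#' @return a \code{cv_report} over the outer folds, with
#'   \code{per_fold_params} listing each fold's selected configuration.
#' @export
nested_cv <- function(name, space, X, y, outer = 5L, inner = 3L,
                      n_iter = 10L, seed = 42L, metric = "rmse",
                      scale = TRUE) {
  x <- as.matrix(as.data.frame(X)); y <- as.numeric(y)
  n <- nrow(x)
  if (n < 2L * outer) stop("need at least 2 samples per outer fold",
                           call. = FALSE)
  fold <- .fold_assign(n, outer, seed)
  val <- matrix(NA_real_, outer, length(.metric_names),
                dimnames = list(NULL, .metric_names))
  chosen <- vector("list", outer)
  for (f in seq_len(outer)) {
    tr <- fold != f
    xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
    xte <- x[!tr, , drop = FALSE]; yte <- y[!tr]
    rs <- random_search(name, space, xtr, ytr, n_iter = n_iter, cv = inner,
                        seed = seed + f, metric = metric, scale = scale)
    chosen[[f]] <- rs$best_params
    spec <- do.call(model_spec, c(list(name), rs$best_params,
                                  list(scale = scale)))
    if (spec$scale) {
      sc <- zscore_fit(xtr)
      xtr2 <- zscore_apply(sc, xtr); xte2 <- zscore_apply(sc, xte)
    } else { xtr2 <- xtr; xte2 <- xte }
    m <- .fit_spec(spec, xtr2, ytr)
    val[f, ] <- unlist(.safe_eval(yte, predict(m, xte2))[.metric_names])
  }
  rep <- .report_from_folds(val, outer, seed)
  rep$per_fold_params <- chosen
  rep
}

#' Learning curve
#'
#' For each training-set fraction, runs k-fold CV on a seeded random
#' subsample of that size and records train and validation metrics.
#'
#' @param spec a [model_spec()]
#' @param X,y data
#' @param fractions increasing vector of fractions in (0, 1]
#' @param k folds per point (default 5)
#' @param seed RNG seed
#' @param metric metric column reported (default \code{"rmse"})
#' @return data.frame with columns \code{fraction}, \code{n},
#'   \code{train}, \code{validation} (mean metric values).
#' @export
learning_curve <- function(spec, X, y, fractions = c(0.25, 0.5, 0.75, 1),
                           k = 5L, seed = 42L, metric = "rmse") {
  if (is.unsorted(fractions, strictly = TRUE) ||
      any(fractions <= 0) || any(fractions > 1))
    stop("`fractions` must be strictly increasing within (0, 1]",
         call. = FALSE)
  metric <- match.arg(metric, .metric_names)
  x <- as.matrix(as.data.frame(X)); y <- as.numeric(y)
  n <- nrow(x)
  set.seed(seed)
  perm <- sample.int(n)
  rows <- lapply(fractions, function(f) {
    m <- if (f == 1) n else max(2L * k, round(f * n))
    idx <- if (f == 1) seq_len(n) else perm[seq_len(m)]
    rep <- kfold_evaluate(spec, x[idx, , drop = FALSE], y[idx], k = k,
                          seed = seed, return_train = TRUE)
    data.frame(fraction = f, n = length(idx),
               train = rep$train$mean[[metric]],
               validation = rep$mean[[metric]])
  })
  do.call(rbind, rows)
}
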