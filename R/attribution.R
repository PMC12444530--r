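# Model-agnostic additive feature attribution via Monte-Carlo
# permutation-sampled Shapley values (Strumbelj-Kononenko estimator).
#
# For each sampled feature ordering, the instance's features replace a
# random background row one at a time; the per-feature marginal change in
# the model output, averaged over orderings, estimates its Shapley value.
# baseline + sum(contributions) equals the prediction up to Monte-Carlo
# error.

#' Monte-Carlo Shapley attribution for one instance
#'
#' @param predict_fn function mapping a feature matrix (one row per
#'   instance) to numeric predictions, e.g.
#'   \code{function(x) predict(model, x)}
#' @param background matrix/data.frame of background rows (typically a
#'   seeded subsample of the training set, capped at ~200 rows)
#' @param instance named numeric vector (or one-row data.frame) to explain
#' @param n_perm number of sampled permutations (>= 50; default 200)
#' @param seed RNG seed
#' @return object of class \code{shapley_attribution}: per-feature
#'   \code{contribution}, Monte-Carlo standard errors \code{se},
#'   \code{baseline} (mean model output on the background), and the
#'   instance \code{prediction}.
#' @export
mc_shapley <- function(predict_fn, background, instance, n_perm = 200L,
                       seed = 42L) {
  bg <- as.matrix(as.data.frame(background))
  if (nrow(bg) == 0L) stop("background set is empty", call. = FALSE)
  if (n_perm < 50L) stop("n_perm must be at least 50", call. = FALSE)
  if (is.data.frame(instance)) instance <- unlist(instance[1L, ])
  inst <- as.numeric(instance)[match(colnames(bg), names(instance))]
  if (anyNA(inst)) {
    if (is.null(names(instance)) && length(instance) == ncol(bg))
      inst <- as.numeric(instance)
    else stop("instance lacks background feature(s)", call. = FALSE)
  }
  p <- ncol(bg)
  set.seed(seed)
  # assemble all evaluation points, then one predict_fn call
  deltas <- matrix(NA_real_, n_perm, p)
  pts <- matrix(NA_real_, n_perm * (p + 1L), p,
                dimnames = list(NULL, colnames(bg)))
  orders <- vector("list", n_perm)
  for (m in seq_len(n_perm)) {
    z <- bg[sample.int(nrow(bg), 1L), ]
    ord <- sample.int(p)
    orders[[m]] <- ord
    row0 <- (m - 1L) * (p + 1L) + 1L
    pts[row0, ] <- z
    for (s in seq_len(p)) {
      z[ord[s]] <- inst[ord[s]]
      pts[row0 + s, ] <- z
    }
  }
  fx <- tryCatch(as.numeric(predict_fn(pts)),
                 error = function(e)
                   stop(sprintf("prediction failed during attribution: %s",
                                conditionMessage(e)), call. = FALSE))
  for (m in seq_len(n_perm)) {
    row0 <- (m - 1L) * (p + 1L) + 1L
    vals <- fx[row0:(row0 + p)]
    deltas[m, orders[[m]]] <- diff(vals)
  }
  contribution <- colMeans(deltas)
  se <- apply(deltas, 2L, stats::sd) / sqrt(n_perm)
  baseline <- mean(as.numeric(predict_fn(bg)))
  pred <- as.numeric(predict_fn(matrix(inst, nrow = 1L,
                                       dimnames = list(NULL, colnames(bg)))))
  structure(list(contribution = stats::setNames(contribution, colnames(bg)),
                 se = stats::setNames(se, colnames(bg)),
                 baseline = baseline, prediction = pred,
                 n_perm = n_perm, seed = seed),
            class = "shapley_attribution")
}

#' @export
print.shapley_attribution <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Monte-Carlo Shapley attribution (%d permutations)\n  baseline %.6g, prediction %.6g\n",
    x$n_perm, x$baseline, x$prediction))
  for (nm in names(x$contribution))
    cat(sprintf("  %-12s %+.*f (se %.2g)\n", nm, digits,
                x$contribution[[nm]], x$se[[nm]]))
  invisible(x)
}

#' Rank features by mean absolute attribution
#'
#' Summarizes a set of per-instance attributions the way a SHAP summary
#' plot orders its features: descending mean |contribution|.
#'
#' @param attributions list of \code{shapley_attribution} objects
#' @return data.frame with columns \code{feature},
#'   \code{mean_abs_contribution}, sorted descending.
#' @export
rank_features <- function(attributions) {
  if (inherits(attributions, "shapley_attribution"))
    attributions <- list(attributions)
  if (length(attributions) == 0L)
    stop("need at least one attributed instance", call. = FALSE)
  mat <- do.call(rbind, lapply(attributions, function(a)
    abs(a$contribution)))
  m <- colMeans(mat)
  out <- data.frame(feature = names(m), mean_abs_contribution = unname(m),
                    stringsAsFactors = FALSE)
  out[order(-out$mean_abs_contribution), , drop = FALSE]
}

#' Export attributions as a CSV-ready table
#'
#' @param attributions list of \code{shapley_attribution} objects
#' @param ids optional instance identifiers
#' @return data.frame: one row per instance with per-feature
#'   contributions, \code{baseline} and \code{prediction} columns.
#' @export
attribution_table <- function(attributions, ids = NULL) {
  if (inherits(attributions, "shapley_attribution"))
    attributions <- list(attributions)
  if (is.null(ids)) ids <- seq_along(attributions)
  rows <- lapply(seq_along(attributions), function(i) {
    a <- attributions[[i]]
    cbind(data.frame(id = ids[i]),
          as.data.frame(as.list(a$contribution)),
          data.frame(baseline = a$baseline, prediction = a$prediction))
  })
  do.call(rbind, rows)
}
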