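# Regression trees and tree ensembles.
#
# A split at node S minimizes the weighted child MSE
#   (|S_L|/|S|) MSE(S_L) + (|S_R|/|S|) MSE(S_R),
# equivalently the summed child SSE; leaves predict the mean target of
# their subset.  Candidate thresholds sit at midpoints of consecutive
# sorted unique feature values; ties are broken by lowest feature index,
# then lowest threshold, so fits are reproducible.  The extra-trees
# variant draws one uniform random threshold per candidate feature inside
# the node's value range and keeps the best of those.

# best split for one node; returns NULL if no admissible split exists
.best_split <- function(x, y, feats, min_leaf, random_threshold) {
  n <- length(y)
  best <- NULL
  best_score <- Inf
  # mathematically tied scores can differ by floating-point noise between
  # candidate orderings; requiring improvement beyond this tolerance keeps
  # the documented tie-break (lowest feature index, then lowest threshold)
  tie_tol <- 1e-9 * (1 + sum(y^2))
  for (j in sort(feats)) {
    xs <- x[, j]
    ord <- order(xs)
    xo <- xs[ord]; yo <- y[ord]
    if (xo[1L] == xo[n]) next
    if (random_threshold) {
      thr <- stats::runif(1L, xo[1L], xo[n])
      nl <- sum(xo <= thr)
      if (nl < min_leaf || n - nl < min_leaf) next
      yl <- yo[seq_len(nl)]; yr <- yo[(nl + 1L):n]
      score <- sum((yl - mean(yl))^2) + sum((yr - mean(yr))^2)
      if (score < best_score - tie_tol) {
        best_score <- score
        best <- list(feature = j, threshold = thr, nl = nl, score = score)
      }
    } else {
      # prefix sums over the sorted order; candidate cuts at value changes
      cs <- cumsum(yo); cs2 <- cumsum(yo^2)
      tot <- cs[n]; tot2 <- cs2[n]
      cut_pos <- which(diff(xo) > 0)          # left part has 1..k elements
      for (k in cut_pos) {
        nr <- n - k
        if (k < min_leaf || nr < min_leaf) next
        sse_l <- cs2[k] - cs[k]^2 / k
        sse_r <- (tot2 - cs2[k]) - (tot - cs[k])^2 / nr
        score <- sse_l + sse_r
        if (score < best_score - tie_tol) {
          best_score <- score
          best <- list(feature = j,
                       threshold = (xo[k] + xo[k + 1L]) / 2,
                       nl = k, score = score)
        }
      }
    }
  }
  best
}

.grow_tree <- function(x, y, depth, max_depth, min_leaf, min_split,
                       mtry, random_threshold) {
  n <- length(y)
  node_mean <- mean(y)
  node_sse <- sum((y - node_mean)^2)
  if (n < min_split || depth >= max_depth || node_sse <= 0)
    return(list(leaf = TRUE, value = node_mean, n = n))
  p <- ncol(x)
  feats <- if (mtry >= p) seq_len(p) else sample.int(p, mtry)
  sp <- .best_split(x, y, feats, min_leaf, random_threshold)
  if (is.null(sp) || sp$score >= node_sse)
    return(list(leaf = TRUE, value = node_mean, n = n))
  left <- x[, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       n = n, decrease = node_sse - sp$score,
       left = .grow_tree(x[left, , drop = FALSE], y[left], depth + 1L,
                         max_depth, min_leaf, min_split, mtry,
                         random_threshold),
       right = .grow_tree(x[!left, , drop = FALSE], y[!left], depth + 1L,
                          max_depth, min_leaf, min_split, mtry,
                          random_threshold))
}

#' Fit a CART regression tree
#'
#' @param X numeric matrix or data.frame of predictors
#' @param y numeric response
#' @param max_depth maximum tree depth (root = depth 0)
#' @param min_leaf minimum samples in each child
#' @param min_split minimum samples required to attempt a split
#' @param mtry number of candidate features per split (default: all)
#' @param random_threshold draw one uniform random threshold per feature
#'   instead of searching midpoints (the extra-trees split rule)
#' @return object of class \code{qspr_tree}.
#' @export
tree_fit <- function(X, y, max_depth = Inf, min_leaf = 1L, min_split = 2L,
                     mtry = NULL, random_threshold = FALSE) {
  d <- .as_xy(X, y)
  if (length(d$y) == 0L) stop("empty training data", call. = FALSE)
  p <- ncol(d$x)
  if (is.null(mtry)) mtry <- p
  stopifnot(mtry >= 1L, mtry <= p)
  root <- .grow_tree(d$x, d$y, 0L, max_depth, min_leaf,
                     max(min_split, 2L * min_leaf), mtry, random_threshold)
  structure(list(root = root, features = colnames(d$x),
                 y_range = range(d$y)),
            class = "qspr_tree")
}

.tree_predict_rows <- function(node, x) {
  n <- nrow(x)
  out <- numeric(n)
  rec <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (isTRUE(node$leaf)) { out[idx] <<- node$value; return() }
    left <- x[idx, node$feature] <= node$threshold
    rec(node$left, idx[left])
    rec(node$right, idx[!left])
  }
  rec(node, seq_len(n))
  out
}

#' @export
predict.qspr_tree <- function(object, newdata, ...) {
  x <- .model_matrix(newdata, object$features)
  .tree_predict_rows(object$root, x)
}

#' @export
print.qspr_tree <- function(x, ...) {
  count <- function(nd) if (isTRUE(nd$leaf)) c(1L, 0L) else
    c(0L, 1L) + count(nd$left) + count(nd$right)
  ct <- count(x$root)
  cat(sprintf("QSPR regression tree: %d leaves, %d internal nodes\n",
              ct[1L], ct[2L]))
  invisible(x)
}

#' Fit a tree ensemble (random forest or extra trees)
#'
#' Random forest: each tree sees a bootstrap resample (when
#' \code{bootstrap = TRUE}) and searches optimal thresholds over
#' \code{mtry} sampled features per node.  Extra trees: thresholds are
#' drawn uniformly at random inside each sampled feature's node range and
#' the best random split is kept; bootstrap defaults to TRUE here to
#' match the reference configuration, though the canonical extra-trees
#' algorithm uses the full sample (set \code{bootstrap = FALSE}).
#' Predictions average the per-tree predictions.
#'
#' @inheritParams tree_fit
#' @param kind \code{"rf"} or \code{"et"}
#' @param n_estimators number of trees (default 100)
#' @param bootstrap resample with replacement per tree (default TRUE)
#' @param seed integer RNG seed; identical seeds give bit-identical models
#' @return object of class \code{qspr_forest} with per-tree out-of-bag
#'   index sets when bootstrapping.
#' @export
forest_fit <- function(X, y, kind = c("rf", "et"), n_estimators = 100L,
                       bootstrap = TRUE, mtry = NULL, min_leaf = 1L,
                       min_split = 2L, max_depth = Inf, seed = 42L) {
  kind <- match.arg(kind)
  stopifnot(n_estimators >= 1L)
  d <- .as_xy(X, y)
  n <- length(d$y); p <- ncol(d$x)
  if (is.null(mtry)) mtry <- p
  stopifnot(mtry >= 1L, mtry <= p)
  set.seed(seed)
  trees <- vector("list", n_estimators)
  oob <- vector("list", n_estimators)
  for (t in seq_len(n_estimators)) {
    idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    oob[[t]] <- if (bootstrap) setdiff(seq_len(n), idx) else integer(0)
    trees[[t]] <- .grow_tree(d$x[idx, , drop = FALSE], d$y[idx], 0L,
                             max_depth, min_leaf,
                             max(min_split, 2L * min_leaf), mtry,
                             random_threshold = (kind == "et"))
  }
  structure(list(trees = trees, features = colnames(d$x), kind = kind,
                 config = list(n_estimators = n_estimators,
                               bootstrap = bootstrap, mtry = mtry,
                               min_leaf = min_leaf, min_split = min_split,
                               max_depth = max_depth, seed = seed),
                 oob = oob, y_range = range(d$y)),
            class = "qspr_forest")
}

#' @export
predict.qspr_forest <- function(object, newdata, ...) {
  x <- .model_matrix(newdata, object$features)
  preds <- vapply(object$trees, .tree_predict_rows, numeric(nrow(x)), x = x)
  if (nrow(x) == 1L) mean(preds) else rowMeans(matrix(preds, nrow = nrow(x)))
}

#' @export
print.qspr_forest <- function(x, ...) {
  cat(sprintf(
    "QSPR %s ensemble: %d trees, mtry = %d, bootstrap = %s\n",
    if (x$kind == "rf") "random-forest" else "extra-trees",
    length(x$trees), x$config$mtry, x$config$bootstrap))
  invisible(x)
}

#' Impurity-based feature importance
#'
#' Total SSE decrease attributed to each feature's splits, averaged over
#' trees and normalized to sum 1.
#'
#' @param m a \code{qspr_forest} or \code{qspr_tree}
#' @return named numeric vector of importances summing to 1.
#' @export
impurity_importance <- function(m) {
  if (inherits(m, "qspr_tree")) {
    trees <- list(m$root); features <- m$features
  } else if (inherits(m, "qspr_forest")) {
    trees <- m$trees; features <- m$features
  } else stop("not a fitted tree or forest model", call. = FALSE)
  p <- length(features)
  acc <- function(node, v) {
    if (isTRUE(node$leaf)) return(v)
    v[node$feature] <- v[node$feature] + node$decrease
    acc(node$right, acc(node$left, v))
  }
  per_tree <- vapply(trees, acc, numeric(p), v = numeric(p))
  imp <- rowMeans(matrix(per_tree, nrow = p))
  if (sum(imp) == 0) imp <- rep(1 / p, p)   # all-leaf ensemble: uninformative
  else imp <- imp / sum(imp)
  stats::setNames(imp, features)
}
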