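# Clustering of the topological chemical space: k-means++ with Lloyd
# iterations, elbow scan, DBSCAN comparison, and cluster validity
# (silhouette, Davies-Bouldin).

.as_points <- function(X) {
  x <- as.matrix(as.data.frame(X))
  storage.mode(x) <- "double"
  x
}

# squared Euclidean distances from each row of x to each row of centers;
# clamped at zero against floating-point cancellation
.sq_dist <- function(x, centers) {
  pmax(outer(rowSums(x^2), rowSums(centers^2), "+") -
         2 * tcrossprod(x, centers), 0)
}

#' K-means clustering with k-means++ seeding
#'
#' k-means++ initialization followed by Lloyd iterations to an assignment
#' fixpoint (at most \code{max_iter}); with \code{n_init > 1} the run
#' with the lowest inertia wins.  Empty clusters are reseeded at the
#' point farthest from its assigned centroid.  Standardize the index
#' features first (see [zscore_fit()]) unless raw-space clustering is
#' intended.
#'
#' @param X numeric matrix or data.frame of points
#' @param k number of clusters (at most the number of distinct rows)
#' @param n_init number of independent initializations (default 1)
#' @param seed RNG seed
#' @param max_iter Lloyd iteration cap (default 300)
#' @return object of class \code{qspr_kmeans}: \code{labels} (1..k),
#'   \code{centers}, \code{inertia}, \code{iterations}, \code{seed}.
#' @export
kmeans_fit <- function(X, k, n_init = 1L, seed = 42L, max_iter = 300L) {
  x <- .as_points(X)
  n <- nrow(x)
  ndistinct <- nrow(unique(x))
  if (k > ndistinct)
    stop(sprintf("k = %d exceeds the %d distinct rows", k, ndistinct),
         call. = FALSE)
  stopifnot(k >= 1L, n_init >= 1L)
  set.seed(seed)
  best <- NULL
  for (run in seq_len(n_init)) {
    centers <- .kmeanspp_init(x, k)
    res <- .lloyd(x, centers, max_iter)
    if (is.null(best) || res$inertia < best$inertia) best <- res
  }
  structure(c(best, list(k = k, seed = seed)), class = "qspr_kmeans")
}

.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) for (c in 2L:k) {
    d2 <- apply(.sq_dist(x, centers[seq_len(c - 1L), , drop = FALSE]),
                1L, min)
    if (sum(d2) == 0) {
      centers[c, ] <- x[sample.int(n, 1L), ]
    } else {
      centers[c, ] <- x[sample.int(n, 1L, prob = d2 / sum(d2)), ]
    }
  }
  centers
}

.lloyd <- function(x, centers, max_iter) {
  n <- nrow(x); k <- nrow(centers)
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- .sq_dist(x, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    for (c in seq_len(k)) {
      if (!any(new_labels == c)) {
        # reseed the empty centroid at the point farthest from its centroid
        far <- which.max(d2[cbind(seq_len(n), new_labels)])
        centers[c, ] <- x[far, ]
        new_labels[far] <- c
      }
    }
    if (it > 1L && all(new_labels == labels)) break
    labels <- new_labels
    for (c in seq_len(k))
      centers[c, ] <- colMeans(x[labels == c, , drop = FALSE])
  }
  d2 <- .sq_dist(x, centers)
  inertia <- sum(d2[cbind(seq_len(n), labels)])
  list(labels = labels, centers = centers, inertia = inertia,
       iterations = it)
}

#' @export
print.qspr_kmeans <- function(x, ...) {
  cat(sprintf("k-means (k = %d): inertia %.6g after %d iterations\n",
              x$k, x$inertia, x$iterations))
  cat("  cluster sizes:", paste(tabulate(x$labels, x$k), collapse = " "),
      "\n")
  invisible(x)
}

#' Elbow scan over cluster counts
#'
#' Runs [kmeans_fit()] for each k with the same seeding policy and
#' reports the inertia (sum of squared distances to the nearest
#' centroid).
#'
#' @inheritParams kmeans_fit
#' @param ks integer vector of cluster counts
#' @return data.frame with columns \code{k} and \code{inertia}.
#' @export
elbow_scan <- function(X, ks, n_init = 1L, seed = 42L) {
  stopifnot(length(ks) >= 1L, all(ks >= 1L))
  data.frame(k = ks,
             inertia = vapply(ks, function(k)
               kmeans_fit(X, k, n_init = n_init, seed = seed)$inertia,
               numeric(1L)))
}

#' DBSCAN density-based clustering
#'
#' Standard DBSCAN with Euclidean distances; noise points are labeled
#' \code{-1}, clusters \code{1, 2, ...} in discovery order.
#'
#' @param X numeric matrix or data.frame of points
#' @param eps neighborhood radius (default 0.1, suited to standardized
#'   features)
#' @param min_samples core-point threshold, the point itself included
#'   (default 20)
#' @return integer vector of labels.
#' @export
dbscan_fit <- function(X, eps = 0.1, min_samples = 20L) {
  stopifnot(eps > 0, min_samples >= 1L)
  x <- .as_points(X)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  neighbors <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(neighbors, length, integer(1L)) >= min_samples
  labels <- rep(0L, n)   # 0 = unvisited
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(neighbors[[i]], i)
    while (length(queue) > 0L) {
      q <- queue[1L]; queue <- queue[-1L]
      if (labels[q] == -1L) labels[q] <- cl        # border previously noise
      if (labels[q] != 0L) next
      labels[q] <- cl
      if (core[q]) queue <- c(queue, setdiff(neighbors[[q]],
                                             which(labels != 0L)))
    }
  }
  labels[labels == 0L] <- -1L
  labels
}

#' Cluster validity: silhouette and Davies-Bouldin
#'
#' Mean and per-sample silhouette coefficients (a point's cohesion vs
#' its nearest other cluster; singleton clusters score 0) and the
#' Davies-Bouldin score (mean over clusters of the worst
#' \eqn{(S_i + S_j) / M_{ij}} ratio, with \eqn{S} the mean distance of
#' members to their centroid and \eqn{M} the centroid distance).  Noise
#' points (label -1) are excluded.
#'
#' @param X numeric matrix or data.frame of points
#' @param labels integer cluster labels (-1 = noise)
#' @return list with \code{silhouette} (mean), \code{silhouettes}
#'   (per sample), \code{davies_bouldin}.
#' @export
cluster_validity <- function(X, labels) {
  x <- .as_points(X)
  keep <- labels != -1L
  x <- x[keep, , drop = FALSE]
  labels <- labels[keep]
  cl <- sort(unique(labels))
  if (length(cl) < 2L)
    stop("validity undefined for fewer than 2 clusters", call. = FALSE)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { sil[i] <- 0; next }
    a <- sum(d[i, own]) / (sum(own) - 1L)
    b <- min(vapply(cl[cl != labels[i]], function(c)
      mean(d[i, labels == c]), numeric(1L)))
    sil[i] <- (b - a) / max(a, b)
  }
  centers <- matrix(NA_real_, length(cl), ncol(x))
  for (ci in seq_along(cl))
    centers[ci, ] <- colMeans(x[labels == cl[ci], , drop = FALSE])
  s <- vapply(seq_along(cl), function(ci) {
    member <- x[labels == cl[ci], , drop = FALSE]
    mean(sqrt(rowSums(sweep(member, 2L, centers[ci, ])^2)))
  }, numeric(1L))
  k <- length(cl)
  db <- mean(vapply(seq_len(k), function(i)
    max(vapply(setdiff(seq_len(k), i), function(j)
      (s[i] + s[j]) / sqrt(sum((centers[i, ] - centers[j, ])^2)),
      numeric(1L))), numeric(1L)))
  list(silhouette = mean(sil), silhouettes = sil, davies_bouldin = db)
}

#' Per-cluster descriptive statistics
#'
#' Mean, standard deviation and normal-theory confidence intervals of
#' each feature within each cluster.
#'
#' @param X numeric matrix or data.frame of features
#' @param labels cluster labels (-1 = noise, excluded)
#' @param level confidence level (default 0.95)
#' @return data.frame with one row per cluster and feature.
#' @export
cluster_summary <- function(X, labels, level = 0.95) {
  x <- .as_points(X)
  keep <- labels != -1L
  x <- x[keep, , drop = FALSE]; labels <- labels[keep]
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- lapply(sort(unique(labels)), function(c) {
    sub <- x[labels == c, , drop = FALSE]
    mu <- colMeans(sub)
    se <- apply(sub, 2L, stats::sd) / sqrt(nrow(sub))
    data.frame(cluster = c, feature = colnames(x), n = nrow(sub),
               mean = unname(mu), sd = unname(apply(sub, 2L, stats::sd)),
               ci_lower = unname(mu - z * se),
               ci_upper = unname(mu + z * se),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
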