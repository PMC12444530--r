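# Independent oracles used across the suite.  These deliberately avoid
# the code paths of the package implementation (igraph BFS, prefix-sum
# split search, closed-form ridge) so agreement is evidence, not
# tautology.

# Floyd-Warshall all-pairs shortest paths on a 0/1 adjacency matrix
fw_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

wiener_oracle <- function(a) {
  d <- fw_distances(a)
  sum(d[upper.tri(d)])
}

gutman_oracle <- function(a) {
  d <- fw_distances(a)
  deg <- rowSums(a)
  s <- 0
  n <- nrow(a)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      s <- s + d[i, j] * deg[i] * deg[j]
  s
}

# random connected simple graph: random spanning tree plus extra edges
random_connected_adjacency <- function(n, extra = 2L) {
  a <- matrix(0L, n, n)
  for (v in 2:n) {
    u <- sample.int(v - 1L, 1L)
    a[u, v] <- a[v, u] <- 1L
  }
  for (e in seq_len(extra)) {
    pair <- sample.int(n, 2L)
    a[pair[1L], pair[2L]] <- a[pair[2L], pair[1L]] <- 1L
  }
  diag(a) <- 0L
  a
}

# exhaustive CART split search: every feature, every midpoint threshold;
# ties resolved by lowest feature index then lowest threshold
brute_force_split <- function(x, y, min_leaf = 1L) {
  n <- length(y)
  best <- NULL
  tie_tol <- 1e-9 * (1 + sum(y^2))
  for (j in seq_len(ncol(x))) {
    u <- sort(unique(x[, j]))
    if (length(u) < 2L) next
    for (s in (u[-1L] + u[-length(u)]) / 2) {
      left <- x[, j] <= s
      nl <- sum(left); nr <- n - nl
      if (nl < min_leaf || nr < min_leaf) next
      yl <- y[left]; yr <- y[!left]
      score <- sum((yl - mean(yl))^2) + sum((yr - mean(yr))^2)
      if (is.null(best) || score < best$score - tie_tol)
        best <- list(feature = j, threshold = s, score = score)
    }
  }
  best
}

# seeded Gaussian blobs in `dim` dimensions with centers far apart
make_blobs <- function(k, n_per = 30L, dim = 3L, spread = 1, sep = 20) {
  centers <- matrix(sep * seq_len(k), k, dim)
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n_per * dim, mean = centers[i, 1L], sd = spread),
           ncol = dim)))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

# molecular formula string C<n>H<m>... for comparison with closed forms
formula_string <- function(g) {
  f <- molecular_formula(g)
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}
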