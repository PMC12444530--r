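# Node centralities, topological indices and per-molecule feature vectors.
#
# All indices are computed on the explicit-hydrogen, unweighted simple
# graph: this is the convention under which benzene has Estrada index
# 28.7159 and Gutman index 570.

as_adjacency <- function(x) {
  if (inherits(x, "molgraph")) return(adjacency_matrix(x))
  x <- as.matrix(x)
  if (nrow(x) != ncol(x) || any(x != t(x)) || any(diag(x) != 0) ||
      !all(x %in% c(0, 1)))
    stop("adjacency matrix must be symmetric 0/1 with zero diagonal",
         call. = FALSE)
  x
}

#' All-pairs shortest-path distance matrix
#'
#' Unweighted shortest-path (edge-count) distances via breadth-first
#' search, as used by the Wiener and Gutman indices.
#'
#' @param x a \code{molgraph} or a symmetric 0/1 adjacency matrix
#' @return symmetric integer matrix of distances with zero diagonal.
#' @export
distance_matrix <- function(x) {
  a <- as_adjacency(x)
  n <- nrow(a)
  if (n == 1L) return(matrix(0L, 1L, 1L))
  ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  d <- igraph::distances(ig)
  if (any(is.infinite(d)))
    stop("graph is disconnected: infinite shortest-path distances",
         call. = FALSE)
  storage.mode(d) <- "integer"
  dimnames(d) <- NULL
  d
}

#' Adjacency spectrum
#'
#' Eigenvalues of the adjacency matrix in descending order.
#'
#' @param x a \code{molgraph} or adjacency matrix
#' @return numeric vector of eigenvalues.
#' @export
graph_spectrum <- function(x) {
  a <- as_adjacency(x)
  eigen(a, symmetric = TRUE, only.values = TRUE)$values
}

#' Node centralities of a molecular graph
#'
#' Degree (edge incidence count), betweenness (geodesic count over
#' unordered source-target pairs, endpoints excluded, unnormalized),
#' closeness as the plain reciprocal \eqn{1 / \sum_{t \ne v} d(v,t)}
#' (no \eqn{(n-1)} factor), and eigenvector centrality as the principal
#' eigenvector of the adjacency matrix, nonnegative with unit Euclidean
#' norm (power iteration, tolerance 1e-10, at most 1000 iterations).
#'
#' @param g a connected \code{molgraph} with at least 2 nodes
#' @return data.frame with columns \code{degree}, \code{betweenness},
#'   \code{closeness}, \code{eigenvector}, one row per node.
#' @export
centralities <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  n <- n_atoms(g)
  if (n < 2L) stop("centralities need at least 2 nodes", call. = FALSE)
  a <- adjacency_matrix(g)
  d <- distance_matrix(a)
  ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  degree <- as.integer(rowSums(a))
  btw <- as.numeric(igraph::betweenness(ig, directed = FALSE,
                                        normalized = FALSE))
  clo <- 1 / rowSums(d)
  ev <- power_iteration(a)
  data.frame(degree = degree, betweenness = btw, closeness = clo,
             eigenvector = ev)
}

# principal eigenvector of a symmetric nonnegative matrix; unit Euclidean
# norm, nonnegative orientation.  Computed by full symmetric
# eigendecomposition (the same route as the Estrada index): long-chain
# molecular graphs have a vanishing spectral gap, where power iteration
# at any practical tolerance stalls, while the direct decomposition is
# exact and deterministic.  The convergence check guards the degenerate
# case of a tied principal eigenvalue.
power_iteration <- function(a, tol = 1e-10, max_iter = 1000L) {
  e <- eigen(a, symmetric = TRUE)
  v <- e$vectors[, 1L]
  if (nrow(a) > 1L && e$values[1L] == e$values[2L])
    stop("eigenvector centrality undefined: tied principal eigenvalue",
         call. = FALSE)
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  v / sqrt(sum(v^2))
}

#' Estrada index
#'
#' \eqn{EE = \sum_i e^{\lambda_i}} over the adjacency eigenvalues: a
#' spectral measure of overall subgraph centrality.
#'
#' @param x a \code{molgraph}, an adjacency matrix, or a numeric vector of
#'   eigenvalues
#' @return the Estrada index (numeric scalar).
#' @examples
#' estrada_index(hydrogenate(parse_smiles("c1ccccc1")))  # 28.7159
#' @export
estrada_index <- function(x) {
  lambda <- if (is.numeric(x) && is.null(dim(x))) x else graph_spectrum(x)
  sum(exp(lambda))
}

#' Wiener index
#'
#' \eqn{W = \sum_{i<j} d(i,j)}: the sum of shortest-path distances over all
#' unordered atom pairs; a measure of molecular compactness.
#'
#' @param x a \code{molgraph}, adjacency matrix, or precomputed distance
#'   matrix (square symmetric integer matrix)
#' @return exact integer (returned as numeric to avoid overflow on large
#'   graphs).
#' @export
wiener_index <- function(x) {
  d <- if (is.matrix(x) && isTRUE(all.equal(diag(x), rep(0, nrow(x)))) &&
           !all(x %in% c(0, 1))) x else distance_matrix(x)
  sum(d[upper.tri(d)])
}

#' Gutman index
#'
#' \eqn{\sum_{i<j} d(i,j)\,\deg(i)\deg(j)}: shortest-path distances
#' weighted by the product of endpoint degrees.
#'
#' @param x a \code{molgraph} or adjacency matrix
#' @return exact integer value (numeric scalar).
#' @examples
#' gutman_index(hydrogenate(parse_smiles("c1ccccc1")))  # 570
#' @export
gutman_index <- function(x) {
  a <- as_adjacency(x)
  d <- distance_matrix(a)
  deg <- rowSums(a)
  as.numeric(deg %*% d %*% deg) / 2
}

.FEATURE_ORDER <- c("estrada", "wiener", "gutman", "degree", "betweenness",
                    "closeness", "eigenvector")

#' Per-molecule descriptor vector
#'
#' The seven features used throughout the package, in fixed order:
#' Estrada, Wiener and Gutman indices, then the node-level degree,
#' betweenness, closeness and eigenvector centralities aggregated to the
#' molecule level (arithmetic mean by default).
#'
#' @param g a connected, hydrogenated \code{molgraph}
#' @param aggregation how node centralities are pooled: "mean", "sum" or
#'   "max"
#' @return named numeric vector of length 7 with attribute
#'   \code{aggregation}.
#' @export
featurize <- function(g, aggregation = c("mean", "sum", "max")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(g, "molgraph"))
  agg <- switch(aggregation, mean = mean, sum = sum, max = max)
  a <- adjacency_matrix(g)
  d <- distance_matrix(a)
  cent <- centralities(g)
  deg <- rowSums(a)
  v <- c(estrada = estrada_index(graph_spectrum(a)),
         wiener = sum(d[upper.tri(d)]),
         gutman = as.numeric(deg %*% d %*% deg) / 2,
         degree = agg(cent$degree),
         betweenness = agg(cent$betweenness),
         closeness = agg(cent$closeness),
         eigenvector = agg(cent$eigenvector))
  attr(v, "aggregation") <- aggregation
  v
}

#' Descriptor table for a set of SMILES
#'
#' Parses, hydrogenates and featurizes each molecule; the result matches
#' the package's feature-table CSV schema
#' (\code{name,smiles,estrada,wiener,gutman,degree,betweenness,closeness,eigenvector}).
#'
#' @param smiles character vector of SMILES strings
#' @param names optional molecule names (recycled NA otherwise)
#' @param aggregation centrality aggregation passed to [featurize()]
#' @return data.frame, one row per molecule.
#' @export
descriptor_table <- function(smiles, names = NULL,
                             aggregation = c("mean", "sum", "max")) {
  aggregation <- match.arg(aggregation)
  if (is.null(names)) names <- rep(NA_character_, length(smiles))
  rows <- lapply(seq_along(smiles), function(i) {
    g <- hydrogenate(parse_smiles(smiles[i], name = names[i]))
    as.data.frame(as.list(featurize(g, aggregation)))
  })
  out <- cbind(data.frame(name = names, smiles = smiles,
                          stringsAsFactors = FALSE),
               do.call(rbind, rows))
  attr(out, "aggregation") <- aggregation
  out
}

#' Pearson correlation matrix
#'
#' @param table data.frame or matrix of numeric columns (>= 2 rows)
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(table) {
  x <- as.matrix(as.data.frame(table))
  if (!is.numeric(x)) stop("all columns must be numeric", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 rows", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop(sprintf("undefined correlation: constant column '%s'",
                 colnames(x)[which(sds == 0)[1L]]), call. = FALSE)
  stats::cor(x)
}

#' Strongest correlation pairs
#'
#' Lists the top-k off-diagonal entries of a correlation matrix by
#' absolute value, strongest first.
#'
#' @param pm a correlation matrix from [pearson_matrix()]
#' @param k number of pairs to report
#' @return data.frame with columns \code{var1}, \code{var2}, \code{r}.
#' @export
top_correlations <- function(pm, k = 10L) {
  idx <- which(upper.tri(pm), arr.ind = TRUE)
  r <- pm[idx]
  ord <- order(abs(r), decreasing = TRUE)
  take <- head(ord, k)
  data.frame(var1 = rownames(pm)[idx[take, 1L]],
             var2 = colnames(pm)[idx[take, 2L]],
             r = r[take], stringsAsFactors = FALSE)
}
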