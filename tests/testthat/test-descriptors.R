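# Centralities, topological indices and correlation tables.

p3 <- function() parse_smiles("CCC")   # heavy path on 3 nodes

test_that("distance matrices are BFS-exact", {
  expect_identical(distance_matrix(parse_smiles("CC")),
                   matrix(c(0L, 1L, 1L, 0L), 2L))
  d3 <- distance_matrix(p3())
  expect_equal(sort(d3[upper.tri(d3)]), c(1L, 1L, 2L))
  benz <- hydrogenate(parse_smiles("c1ccccc1"))
  db <- distance_matrix(benz)
  expect_equal(max(db), 5L)
  expect_equal(db, fw_distances(adjacency_matrix(benz)),
               ignore_attr = TRUE)
  # disconnected input is rejected
  expect_error(distance_matrix(matrix(0L, 2L, 2L)), "disconnected")
})

test_that("centralities follow their defining formulas", {
  cent <- centralities(p3())
  expect_equal(cent$degree, c(1L, 2L, 1L))
  expect_equal(cent$betweenness, c(0, 1, 0))
  expect_equal(cent$closeness, c(1 / 3, 1 / 2, 1 / 3))
  # 6-cycle: symmetry forces equal eigenvector centralities of 1/sqrt(6)
  ring <- parse_smiles("C1CCCCC1")
  cent_ring <- centralities(ring)
  expect_equal(cent_ring$eigenvector, rep(1 / sqrt(6), 6), tolerance = 1e-8)
  expect_equal(sum(cent_ring$degree), 2L * n_bonds(ring))
  # leaves never lie on geodesics between others
  g <- hydrogenate(parse_smiles("CC(C)CC"))
  cc <- centralities(g)
  expect_true(all(cc$betweenness[rowSums(adjacency_matrix(g)) == 1] == 0))
  expect_equal(sum(cc$eigenvector^2), 1, tolerance = 1e-9)
})

test_that("Estrada index matches the matrix-exponential trace oracle", {
  skip_if_not_installed("Matrix")
  expect_equal(estrada_index(numeric(1)), 1.0)            # single node
  expect_equal(estrada_index(parse_smiles("CC")), 2 * cosh(1),
               tolerance = 1e-12)
  set.seed(101)
  for (rep in 1:50) {
    a <- random_connected_adjacency(sample(4:12, 1L))
    ee <- estrada_index(a)
    tr <- sum(diag(as.matrix(Matrix::expm(Matrix::Matrix(a)))))
    expect_equal(ee, tr, tolerance = 1e-8)
    expect_gte(ee, nrow(a))  # EE >= n, equality only for edgeless graphs
  }
})

test_that("Wiener and Gutman indices agree exactly with Floyd-Warshall", {
  expect_equal(wiener_index(parse_smiles("CC")), 1)
  expect_equal(gutman_index(parse_smiles("CC")), 1)
  expect_equal(gutman_index(p3()), 6)
  expect_equal(wiener_index(hydrogenate(parse_smiles("CC"))), 58)
  set.seed(202)
  for (rep in 1:50) {
    a <- random_connected_adjacency(sample(4:12, 1L))
    expect_equal(wiener_index(a), wiener_oracle(a))
    expect_equal(gutman_index(a), gutman_oracle(a))
  }
})

test_that("Gutman equals d^2 * Wiener on d-regular graphs", {
  for (n in 3:10) {
    ring <- parse_smiles(paste0("C1", paste(rep("C", n - 1L),
                                            collapse = ""), "1"))
    expect_equal(gutman_index(ring), 4 * wiener_index(ring))
  }
})

test_that("heavy-atom paths obey the Wiener closed form n(n^2-1)/6", {
  for (n in c(2L, 3L, 5L, 9L, 14L)) {
    g <- parse_smiles(paste(rep("C", n), collapse = ""))
    expect_equal(wiener_index(g), n * (n^2 - 1) / 6)
  }
})

test_that("feature vectors are isomorphism-invariant", {
  g <- hydrogenate(parse_smiles("CCc1ccccc1"))
  a <- adjacency_matrix(g)
  base <- featurize(g)
  set.seed(7)
  for (rep in 1:5) {
    perm <- sample.int(nrow(a))
    ap <- a[perm, perm]
    v <- c(estrada = estrada_index(ap), wiener = wiener_index(ap),
           gutman = gutman_index(ap))
    expect_equal(v, base[c("estrada", "wiener", "gutman")],
                 tolerance = 1e-9)
  }
})

test_that("featurize aggregates centralities as requested", {
  benz <- hydrogenate(parse_smiles("c1ccccc1"))
  v <- featurize(benz, "mean")
  expect_equal(unname(v["estrada"]), 28.7159, tolerance = 1e-3)
  expect_equal(unname(v["gutman"]), 570)
  expect_equal(unname(v["degree"]), 2)      # 2|E|/n = 24/12
  vs <- featurize(benz, "sum")
  expect_equal(unname(vs["degree"]), 24)
  vm <- featurize(benz, "max")
  expect_equal(unname(vm["degree"]), 3)
  expect_equal(names(v), c("estrada", "wiener", "gutman", "degree",
                           "betweenness", "closeness", "eigenvector"))
})

test_that("indices increase strictly along the n-alkane series", {
  tab <- descriptor_table(series_smiles("n-alkane", 1:30)$smiles)
  expect_true(all(diff(tab$estrada) > 0))
  expect_true(all(diff(tab$wiener) > 0))
  expect_true(all(diff(tab$gutman) > 0))
})

test_that("Pearson matrices are exact on degenerate cases and null data", {
  x <- 1:20
  pm <- pearson_matrix(data.frame(x = x, y = 2 * x))
  expect_equal(pm["x", "y"], 1)
  expect_equal(diag(pm), c(x = 1, y = 1))
  expect_equal(pearson_matrix(data.frame(x = x, y = -x))["x", "y"], -1)
  expect_error(pearson_matrix(data.frame(x = x, z = rep(1, 20))),
               "constant column 'z'")
  set.seed(11)
  x <- rnorm(1000)
  pm2 <- pearson_matrix(data.frame(a = x, b = sample(x)))
  expect_lt(abs(pm2["a", "b"]), 0.1)
  top <- top_correlations(pm, k = 1)
  expect_equal(top$r, 1)
})
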