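test_that("population preprocessing bins, binarizes and filters", {
  # counts [[0,2],[1,0]] at 100 ms: unit 1 spikes twice in bin 2,
  # unit 2 once in bin 1
  ses <- manual_session(list(c(0.15, 0.17), 0.05), duration_s = 60)
  bpm <- preprocess_population(ses, min_active = 1L)
  expect_equal(bpm$matrix[, 1:2], matrix(c(0L, 1L, 1L, 0L), 2),
               ignore_attr = TRUE)
  expect_equal(bpm$kept_time_index[1:2], c(1L, 2L))
  # impossible filter flags the session
  bpm2 <- preprocess_population(ses, min_active = 3L)
  expect_equal(ncol(bpm2$matrix), 0L)
  expect_false(bpm2$full_scale)
})

test_that("mutual kNN graphs obey their definition", {
  # three pairwise-equidistant binary points, k = 2 -> complete triangle
  pts <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  g <- mutual_knn_graph(pts, metric = "hamming", k = 2L)
  expect_equal(as.matrix(g$W), matrix(1, 3, 3) - diag(3),
               ignore_attr = TRUE)
  # two well-separated clusters stay disconnected at small k
  set.seed(3)
  a <- matrix(rbinom(20 * 30, 1, 0.1), 20)
  b <- matrix(rbinom(20 * 30, 1, 0.9), 20)
  g2 <- mutual_knn_graph(rbind(a, b), metric = "hamming", k = 3L)
  W <- as.matrix(g2$W)
  expect_true(all(W[1:20, 21:40] == 0))
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(g2$W, "undirected"))
  expect_gte(comp$no, 2L)
  # mutual graph is a subgraph of the directed kNN graph
  expect_lte(sum(W) / 2, 40 * 3)
  # symmetry, zero diagonal, zero Laplacian row sums
  expect_equal(W, t(W))
  expect_true(all(diag(W) == 0))
  L <- diag(g2$degree) - W
  expect_equal(rowSums(L), rep(0, 40), ignore_attr = TRUE)
})

test_that("spectral embedding matches the dense generalized eigensolver", {
  set.seed(7)
  n <- 120L
  pts <- cbind(seq_len(n) / n + rnorm(n, 0, 0.02), rnorm(n, 0, 0.05))
  g <- mutual_knn_graph(pts, metric = "euclidean", k = 6L)
  emb_arpack <- spectral_embed(g, d = 4L, dense_limit = 0L)
  emb_dense <- spectral_embed(g, d = 4L, dense_limit = 10000L)
  # dense generalized eigenproblem oracle: L v = lambda D v
  gi <- igraph::graph_from_adjacency_matrix(g$W, "undirected")
  keep <- which(igraph::components(gi)$membership ==
                  which.max(igraph::components(gi)$csize))
  W <- as.matrix(g$W)[keep, keep]
  deg <- rowSums(W)
  M <- diag(1 / sqrt(deg)) %*% (diag(deg) - W) %*% diag(1 / sqrt(deg))
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam_oracle <- sort(e$values)[2:5]
  expect_equal(emb_arpack$eigenvalues, lam_oracle, tolerance = 1e-8)
  expect_equal(emb_dense$eigenvalues, lam_oracle, tolerance = 1e-8)
  for (j in 1:4) {
    v_o <- (e$vectors / sqrt(deg))[, order(e$values)[j + 1]]
    v_o <- v_o / sqrt(sum(v_o^2))
    err <- min(max(abs(emb_arpack$coords[, j] - v_o)),
               max(abs(emb_arpack$coords[, j] + v_o)))
    expect_lt(err, 1e-7)
    # arpack and dense paths agree up to sign convention (identical here)
    expect_equal(emb_arpack$coords[, j], emb_dense$coords[, j],
                 tolerance = 1e-7)
  }
  # Laplacian spectrum is non-negative and ascending
  expect_true(all(emb_arpack$eigenvalues >= -1e-10))
  expect_true(!is.unsorted(emb_arpack$eigenvalues))
})

test_that("the Fiedler vector is monotone along a path graph", {
  W <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(2, 3, 4), x = 1,
                            dims = c(4, 4), symmetric = TRUE)
  g <- structure(list(W = as(W, "generalMatrix"),
                      degree = Matrix::rowSums(W), k = 1L,
                      metric = "euclidean"), class = "cd_graph")
  emb <- spectral_embed(g, d = 2L)
  f <- emb$coords[, 1]
  expect_true(all(diff(f) > 0) || all(diff(f) < 0))
})

test_that("disconnected graphs are restricted to the largest component", {
  set.seed(31)
  pts <- rbind(matrix(0, 6, 4), matrix(1, 4, 4)) +
    matrix(rnorm(40, 0, 0.01), 10)
  g <- mutual_knn_graph(pts, metric = "euclidean", k = 3L)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(g$W, "undirected"))
  expect_warning(emb <- spectral_embed(g, d = 2L), "dropped")
  expect_equal(nrow(emb$coords), max(comp$csize))
  # the larger cluster survives; indices map back to the original points
  expect_true(all(emb$kept_time_index %in% 1:6))
})

test_that("the LEM pipeline is invariant to unit reordering", {
  ses <- small_session()
  bpm <- preprocess_population(ses, min_active = 5L)
  e1 <- suppressMessages(lem_pipeline(bpm, d = 5L))
  bpm2 <- bpm
  perm <- rev(seq_len(nrow(bpm$matrix)))
  bpm2$matrix <- bpm$matrix[perm, ]
  e2 <- suppressMessages(lem_pipeline(bpm2, d = 5L))
  expect_equal(e1$coords, e2$coords, tolerance = 1e-10)
  expect_identical(e1$kept_time_index, e2$kept_time_index)
})

test_that("control transforms preserve the documented marginals", {
  set.seed(5)
  m <- matrix(rbinom(300, 1, 0.3), 10)
  ts <- control_transforms(m, "time_shuffle", seed = 2L)
  expect_equal(rowSums(ts), rowSums(m))
  expect_equal(sort(colSums(ts)), sort(colSums(m)))
  ns <- control_transforms(m, "neuron_shuffle", seed = 2L)
  expect_equal(rowSums(ns), rowSums(m))
  tf <- control_transforms(m, "time_shift", seed = 2L)
  expect_equal(rowSums(tf), rowSums(m))
  for (i in 1:10) expect_true(any(sapply(0:29, function(s)
    all(tf[i, ] == m[i, ((seq_len(30) - 1 + s) %% 30) + 1]))))
  expect_identical(control_transforms(m, "time_shift", seed = 2L), tf)
})

test_that("dimensionality estimates recover known manifolds", {
  set.seed(5)
  rot <- qr.Q(qr(matrix(rnorm(400), 20)))
  th <- runif(1200, 0, 2 * pi); ph <- runif(1200, 0, 2 * pi)
  torus <- cbind(cos(th), sin(th), 0.5 * cos(ph), 0.5 * sin(ph)) %*%
    t(rot[, 1:4])
  d_torus <- estimate_dimensionality(torus)
  expect_lt(abs(d_torus - 2), 0.5)
  tt <- seq(0, 1, length.out = 1000)
  curve <- cbind(cos(4 * tt), sin(3 * tt), tt) %*% t(rot[, 1:3])
  expect_lt(abs(estimate_dimensionality(curve) - 1), 0.5)
  # scale invariance
  expect_equal(estimate_dimensionality(2 * torus), d_torus, tolerance = 1e-10)
})
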