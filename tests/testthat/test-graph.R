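test_that("weight-to-length mapping is reciprocal with Inf for absent edges", {
  W <- matrix(c(0, 1, 0.5, 0,
                1, 0, 0, 0,
                0.5, 0, 0, 0,
                0, 0, 0, 0), 4, 4)
  L <- weight_to_length(W)
  expect_equal(L[1, 2], 1)
  expect_equal(L[1, 3], 2)
  expect_identical(L[1, 4], Inf)
  expect_equal(unname(diag(L)), rep(0, 4))
  expect_error(weight_to_length(-W), "non-negative")
})

test_that("hand-enumerated 3-node path fixture", {
  # A - B - C with unit lengths: d(A,C) = 2
  W <- matrix(c(0, 1, 0,
                1, 0, 1,
                0, 1, 0), 3, 3)
  D <- shortest_path_distances(weight_to_length(W))
  expect_equal(D, matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3))
  # ordered pairs: four at d = 1, two at d = 2
  expect_equal(global_efficiency(D), 5 / 6)
  expect_equal(as.numeric(characteristic_path_length(D)), 4 / 3)
  expect_equal(unname(nodal_efficiency(D)), c(0.75, 1, 0.75))
  expect_equal(unname(degree_centrality(W)), c(1, 2, 1))
})

test_that("complete, edgeless and partially disconnected graphs", {
  ones <- matrix(1, 3, 3); diag(ones) <- 0
  D <- shortest_path_distances(weight_to_length(ones))
  expect_equal(global_efficiency(D), 1)
  expect_equal(as.numeric(characteristic_path_length(D)), 1)

  empty <- matrix(0, 3, 3)
  De <- shortest_path_distances(weight_to_length(empty))
  expect_equal(global_efficiency(De), 0)
  expect_equal(unname(nodal_efficiency(De)), rep(0, 3))
  expect_error(characteristic_path_length(De), "disconnected")

  # isolated node: its distances are Inf, efficiency 0, and finite-pair
  # path length is unchanged by adding it
  W4 <- rbind(cbind(ones, 0), 0)
  D4 <- shortest_path_distances(weight_to_length(W4))
  expect_true(all(is.infinite(D4[4, -4])))
  expect_equal(nodal_efficiency(D4, 4), 0)
  cpl <- characteristic_path_length(D4)
  expect_equal(as.numeric(cpl), 1)
  expect_identical(attr(cpl, "n_infinite_pairs"), 6L)
  expect_equal(degree_centrality(W4, 4), 0)
})

test_that("Dijkstra matches Floyd-Warshall on 100 random weighted graphs", {
  set.seed(1234)
  for (rep in 1:100) {
    W <- random_weight_matrix(14)
    L <- weight_to_length(W)
    expect_equal(shortest_path_distances(L), oracle_floyd_warshall(L),
                 tolerance = 1e-10)
  }
})

test_that("binary graphs reduce to BFS distances and integer degrees", {
  set.seed(77)
  for (rep in 1:50) {
    adj <- matrix(rbinom(10 * 10, 1, 0.35), 10, 10)
    adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
    diag(adj) <- 0
    D <- shortest_path_distances(weight_to_length(adj))
    Db <- oracle_bfs_distances(adj)
    expect_equal(D, Db)
    expect_equal(unname(degree_centrality(adj)), rowSums(adj))
    inv <- 1 / Db; diag(inv) <- 0
    expect_equal(global_efficiency(D), sum(inv) / (10 * 9))
    expect_equal(unname(nodal_efficiency(D)), rowSums(inv) / 9)
    if (any(is.finite(Db[row(Db) != col(Db)]))) {
      off <- Db[row(Db) != col(Db)]
      expect_equal(as.numeric(characteristic_path_length(D)),
                   mean(off[is.finite(off)]))
    }
  }
})

test_that("metric invariants: mean-nodal identity, monotonicity, relabelling", {
  set.seed(55)
  for (rep in 1:20) {
    W <- random_weight_matrix(14)
    D <- shortest_path_distances(weight_to_length(W))
    expect_equal(global_efficiency(D), mean(nodal_efficiency(D)))
    # triangle inequality over finite triples
    for (k in sample(14, 3)) {
      expect_true(all(D <= outer(D[, k], D[k, ], "+") + 1e-12))
    }
    # raising one weight never lowers efficiency / raises distances
    idx <- which(upper.tri(W) & W > 0 & W < 0.9)[1]
    if (!is.na(idx)) {
      W2 <- W
      ij <- arrayInd(idx, dim(W))
      W2[ij] <- W2[ij[, 2:1]] <- min(1, W[idx] + 0.5)
      D2 <- shortest_path_distances(weight_to_length(W2))
      expect_gte(global_efficiency(D2), global_efficiency(D) - 1e-12)
      fin <- is.finite(D)
      expect_true(all(D2[fin] <= D[fin] + 1e-12))
    }
    # node relabelling permutes nodal metrics, preserves global ones
    perm <- sample(14)
    Wp <- W[perm, perm]
    Dp <- shortest_path_distances(weight_to_length(Wp))
    expect_equal(global_efficiency(Dp), global_efficiency(D), tolerance = 1e-12)
    expect_equal(unname(nodal_efficiency(Dp)),
                 unname(nodal_efficiency(D))[perm], tolerance = 1e-12)
    expect_equal(unname(degree_centrality(Wp)),
                 unname(degree_centrality(W))[perm], tolerance = 1e-12)
  }
})

test_that("graph_metrics report is internally consistent and writable", {
  net <- intersubject_correlation(make_cohort(12, seed = 8))
  rep <- graph_metrics(net)
  expect_s3_class(rep, "graph_metrics_report")
  expect_equal(rep$global_efficiency, mean(rep$nodal_efficiency))
  expect_true(all(rep$nodal_efficiency >= 0 & rep$nodal_efficiency <= 1))
  expect_named(rep$degree_centrality, voi_columns(make_cohort(3)))
  dir <- tempfile()
  paths <- write_graph_metrics(rep, dir)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[1], simplifyVector = TRUE)
  expect_equal(js$global_efficiency, rep$global_efficiency, tolerance = 1e-12)
})
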