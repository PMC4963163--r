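test_that("degree and strength follow their row-sum definitions", {
  # path graph A - B - C
  cn <- conn_from_edges(3, rbind(c(1, 2), c(2, 3)), c(1, 1),
                        labels = c("A", "B", "C"))
  expect_equal(unname(node_degree(cn)), c(1, 2, 1))

  # single weighted edge
  cn <- conn_from_edges(4, rbind(c(1, 2)), 0.5)
  expect_equal(unname(node_strength(cn)), c(0.5, 0.5, 0, 0))

  # uniform weights: strength equals degree
  cn <- random_connectome(10, 0.5, seed = 2)
  cn$weights[cn$weights > 0] <- 1
  expect_equal(node_strength(cn), node_degree(cn) + 0)

  # symmetry: row sums equal column sums
  cn <- random_connectome(12, 0.4, seed = 3)
  expect_equal(unname(node_degree(cn)), unname(colSums(cn$weights > 0)))
})

test_that("complementary cumulative distribution is right shaped", {
  cd <- cumulative_distribution(c(1, 2, 3))
  expect_equal(cd$value, c(1, 2, 3))
  expect_equal(cd$fraction, c(1, 2 / 3, 1 / 3))

  cd <- cumulative_distribution(rep(7, 5))
  expect_equal(nrow(cd), 1)
  expect_equal(cd$fraction, 1)

  set.seed(8)
  cd <- cumulative_distribution(rnorm(200))
  expect_equal(cd$fraction[1], 1)
  expect_true(all(diff(cd$fraction) < 0))
})

test_that("binary geodesics equal the matrix-power oracle", {
  # path graph and complete graph
  cn <- conn_from_edges(3, rbind(c(1, 2), c(2, 3)), c(1, 1),
                        labels = c("A", "B", "C"))
  d <- binary_geodesics(cn)$values
  expect_equal(d["A", "C"], 2)
  k6 <- connectome(matrix(1, 6, 6) - diag(6))
  expect_true(all(binary_geodesics(k6)$values[upper.tri(diag(6))] == 1))

  for (s in 1:10) {
    cn <- random_connectome(20, 0.15, seed = s + 100)
    a <- (cn$weights > 0) + 0
    expect_equal(unname(binary_geodesics(cn)$values), oracle_hops(a))
  }
})

test_that("weighted geodesics prefer fewest hops, then strongest sum", {
  # direct weak edge beats the stronger two-hop detour
  tri <- conn_from_edges(3, rbind(c(1, 2), c(1, 3), c(2, 3)),
                         c(0.1, 0.6, 0.6))
  dw <- weighted_geodesics(tri)$values
  expect_equal(dw[1, 2], 0.1)

  # among equal-hop paths the strongest sum wins
  g4 <- conn_from_edges(4, rbind(c(1, 2), c(2, 4), c(1, 3), c(3, 4)),
                        c(0.1, 0.9, 0.4, 0.5))
  dw <- weighted_geodesics(g4)$values
  expect_equal(dw[1, 4], 1.0)   # 1-2-4 over 1-3-4 (0.9)

  # uniform weights reduce to hop counts
  cn <- random_connectome(15, 0.25, seed = 11)
  cn$weights[cn$weights > 0] <- 1
  expect_equal(weighted_geodesics(cn)$values, binary_geodesics(cn)$values)
})

test_that("weighted geodesics equal exhaustive path enumeration", {
  for (s in 1:40) {
    cn <- random_connectome(n = 4 + s %% 5, p = 0.45, seed = s,
                            counts = FALSE)
    got <- weighted_geodesics(cn)$values
    expect_equal(unname(got), oracle_minhop_maxweight(cn), tolerance = 1e-12)
  }
})

test_that("unreachable pairs are NA and mean_geodesic refuses them", {
  cn <- conn_from_edges(4, rbind(c(1, 2), c(3, 4)), c(1, 1))
  d <- binary_geodesics(cn)$values
  expect_true(is.na(d[1, 3]))
  dw <- weighted_geodesics(cn)$values
  expect_true(is.na(dw[1, 3]))
  expect_error(mean_geodesic(binary_geodesics(cn)), "disconnected")
  # restricting to the largest component makes it well defined
  expect_silent(mean_geodesic(binary_geodesics(largest_component(cn))))
})

test_that("mean geodesic averages each node's row", {
  cn <- conn_from_edges(3, rbind(c(1, 2), c(2, 3)), c(1, 1),
                        labels = c("A", "B", "C"))
  p <- binary_geodesics(cn)
  expect_equal(unname(mean_geodesic(p, "A")), 1.5)
  expect_equal(unname(mean_geodesic(p)), c(1.5, 1, 1.5))
  k6 <- connectome(matrix(1, 6, 6) - diag(6))
  expect_equal(unname(mean_geodesic(binary_geodesics(k6))), rep(1, 6))

  cn <- random_connectome(15, 0.5, seed = 12)
  p <- weighted_geodesics(cn)
  for (i in c(1, 7, 15)) {
    expect_equal(unname(mean_geodesic(p, cn$labels[i])),
                 mean(p$values[i, -i]))
  }
})

test_that("weight scaling normalizes by the network maximum", {
  cn <- conn_from_edges(3, rbind(c(1, 2), c(2, 3)), c(0.02, 0.01))
  sw <- scale_weights(cn)
  expect_equal(sw[1, 2], 1.0)
  expect_equal(sw[2, 3], 0.5)

  cn$weights[cn$weights > 0] <- 0.3
  expect_true(all(scale_weights(cn)[cn$weights > 0] == 1))

  cn <- random_connectome(10, 0.5, seed = 13)
  expect_equal(max(scale_weights(cn)), 1)
  expect_error(scale_weights(connectome(matrix(0, 3, 3))), "edgeless")
})

test_that("clustering coefficients match hand values and conventions", {
  tri <- conn_from_edges(3, rbind(c(1, 2), c(1, 3), c(2, 3)), c(1, 1, 1))
  expect_equal(unname(clustering_binary(tri)), rep(1, 3))
  expect_equal(unname(clustering_onnela(tri)), rep(1, 3))
  expect_equal(unname(clustering_zhang(tri)), rep(1, 3))

  # star center has no closed triangles; leaves have degree 1 -> 0
  star <- conn_from_edges(5, cbind(1, 2:5), rep(1, 4))
  expect_equal(unname(clustering_binary(star)), rep(0, 5))
  expect_equal(unname(clustering_onnela(star)), rep(0, 5))
  expect_equal(unname(clustering_zhang(star)), rep(0, 5))

  # weighted triangle, hand evaluated at node 1
  wtri <- conn_from_edges(3, rbind(c(1, 2), c(1, 3), c(2, 3)),
                          c(1, 0.5, 0.5))
  expect_equal(unname(clustering_onnela(wtri, "n1")), 0.25^(1 / 3))
  expect_equal(unname(clustering_zhang(wtri, "n1")), 0.5 / 1.0)
})

test_that("clustering equals the triple-loop oracles on random graphs", {
  for (s in 1:8) {
    cn <- random_connectome(15, 0.35, seed = s + 30, counts = FALSE)
    a <- (cn$weights > 0) + 0
    expect_equal(unname(clustering_binary(cn)), oracle_clustering_binary(a))
    expect_equal(unname(clustering_onnela(cn)),
                 oracle_clustering_weighted(cn$weights, "onnela"))
    expect_equal(unname(clustering_zhang(cn)),
                 oracle_clustering_weighted(cn$weights, "zhang"))
    # cross-check the binary coefficient against igraph
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    ig <- unname(igraph::transitivity(g, type = "local", isolates = "zero"))
    deg1 <- rowSums(a) == 1
    ig[deg1] <- 0  # same k <= 1 convention
    expect_equal(unname(clustering_binary(cn)), ig)
  }
})

test_that("all clustering variants stay in [0, 1] on heavy-tailed graphs", {
  for (s in 1:6) {
    cn <- random_connectome(20, 0.5, seed = s, heavy_tail = TRUE)
    for (f in list(clustering_binary, clustering_onnela, clustering_zhang)) {
      v <- f(cn)
      expect_true(all(v >= 0 & v <= 1 + 1e-12))
    }
  }
})

test_that("binary limit: equal weights collapse weighted onto binary metrics", {
  for (s in 1:10) {
    cn <- random_connectome(12, 0.45, seed = s + 60)
    cn$weights[cn$weights > 0] <- 0.37
    cb <- clustering_binary(cn)
    expect_equal(clustering_onnela(cn), cb, tolerance = 1e-12)
    expect_equal(clustering_zhang(cn), cb, tolerance = 1e-12)
    dw <- weighted_geodesics(cn)$values / 0.37
    expect_equal(dw, binary_geodesics(cn)$values, tolerance = 1e-12)
  }
})

test_that("raising the count threshold never shortens binary paths", {
  for (s in 1:5) {
    cn <- random_connectome(20, 0.7, seed = s + 200)
    prev <- NULL
    for (t in c(0, 40, 90)) {
      ct <- threshold_counts(cn, t)
      if (anyNA(binary_geodesics(ct)$values)) break
      cur <- mean_geodesic(binary_geodesics(ct))
      if (!is.null(prev)) expect_true(all(cur >= prev - 1e-12))
      prev <- cur
    }
  }
})
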