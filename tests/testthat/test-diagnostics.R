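test_that("closed-form values hold for complete graphs, cycles, stars, paths", {
  K5 <- graph_complete(5)
  m <- basic_metrics(K5)
  expect_equal(m$path_length, 1)
  expect_equal(m$clustering, 1)
  expect_equal(m$global_efficiency, 1)
  expect_equal(m$local_efficiency, 1)
  expect_equal(m$betweenness, 0)
  expect_true(is.na(m$assortativity))  # zero degree variance, flagged
  expect_equal(synchronizability(graph_complete(7)), 1)  # lambda2 = lambdamax
  expect_equal(modularity_greedy(K5), 0, tolerance = 1e-12)

  C6 <- graph_cycle(6)
  mc <- basic_metrics(C6)
  expect_equal(mc$path_length, 1.8)
  expect_equal(mc$clustering, 0)
  expect_equal(mc$global_efficiency, oracle_global_efficiency(C6))

  S6 <- graph_star(6)
  ms <- basic_metrics(S6)
  expect_equal(ms$betweenness_nodes[1], 1)   # hub carries every pair
  expect_equal(ms$assortativity, -1)
  # targeted attack on the star: hub first, then isolated leaves
  expect_equal(robustness(S6, "targeted"), (1 + 5 * (1 / 6)) / 6)

  P4 <- graph_path(4)
  # Laplacian spectrum {0, 2 - sqrt(2), 2, 2 + sqrt(2)}
  expect_equal(synchronizability(P4), (2 - sqrt(2)) / (2 + sqrt(2)),
               tolerance = 1e-12)
  expect_equal(synchronizability(P4, reciprocal = TRUE),
               (2 + sqrt(2)) / (2 - sqrt(2)), tolerance = 1e-12)
})

test_that("complete-graph robustness equals the analytic shrinking-clique AUC", {
  for (n in c(4, 7)) {
    A <- graph_complete(n)
    expected <- sum((1:n) / n) / n
    expect_equal(robustness(A, "targeted"), expected)
    expect_equal(robustness(A, "random", n_orders = 3), expected)
  }
  # same seed reproduces random-attack AUC exactly
  set.seed(1)
  A <- random_connected_graph(12)
  expect_identical(robustness(A, "random", seed = 9),
                   robustness(A, "random", seed = 9))
})

test_that("modularity matches exhaustive partition search on two bridged cliques", {
  A <- matrix(0L, 8, 8)
  A[1:4, 1:4] <- 1L
  A[5:8, 5:8] <- 1L
  diag(A) <- 0L
  A[4, 5] <- A[5, 4] <- 1L
  expect_equal(modularity_greedy(A), oracle_modularity_exhaustive(A),
               tolerance = 1e-12)
  # invariance under node relabeling
  p <- sample(8)
  expect_equal(modularity_greedy(A[p, p]), modularity_greedy(A),
               tolerance = 1e-12)
})

test_that("hierarchy exponent fits log C(k) on log k and degenerates to NA", {
  # K4 and K5 as disjoint components: degree classes {3, 4}, both C = 1
  A <- matrix(0L, 9, 9)
  A[1:4, 1:4] <- 1L
  A[5:9, 5:9] <- 1L
  diag(A) <- 0L
  expect_equal(hierarchy_exponent(A), 0, tolerance = 1e-12)
  # duplicating a graph as two disconnected copies leaves beta unchanged
  set.seed(2)
  G <- random_connected_graph(8)
  b1 <- hierarchy_exponent(G)
  GG <- rbind(cbind(G, matrix(0L, 8, 8)), cbind(matrix(0L, 8, 8), G))
  expect_equal(hierarchy_exponent(GG), b1, tolerance = 1e-12)
  # single degree class -> missing
  expect_true(is.na(hierarchy_exponent(graph_complete(5))))
  # oracle: least-squares on the (k, mean C(k)) profile
  cl <- oracle_clustering_nodes(G)
  deg <- rowSums(G)
  keep <- deg >= 2
  prof <- tapply(cl[keep], deg[keep], mean)
  prof <- prof[prof > 0]
  if (length(prof) >= 2) {
    fit <- lm(log(prof) ~ log(as.numeric(names(prof))))
    expect_equal(b1, -unname(coef(fit)[2]), tolerance = 1e-10)
  }
})

test_that("cost-efficiency maximizes efficiency minus cost with smallest-kappa ties", {
  kap <- c(0.1, 0.3, 0.5)
  r <- cost_efficiency(c(0.2, 0.5, 0.6), kap)
  expect_equal(r$ce, 0.2)
  expect_equal(r$kappa_star, 0.3)
  # identity curve -> CE = 0
  expect_equal(cost_efficiency(kap, kap)$ce, 0)
  # order-free
  o <- c(3, 1, 2)
  expect_equal(cost_efficiency(c(0.2, 0.5, 0.6)[o], kap[o])$ce, 0.2)
  # ties -> smallest kappa
  expect_equal(cost_efficiency(c(0.3, 0.5), c(0.1, 0.3))$kappa_star, 0.1)
  expect_true(is.na(cost_efficiency(c(NA, NA), c(0.1, 0.2))$ce))
})

test_that("mean connection distance responds to edge geometry", {
  lay <- generate_layout(8, seed = 1)
  co <- layout_coords(lay)
  D <- as.matrix(dist(co))
  A <- matrix(0L, 8, 8)
  A[1, 2] <- A[2, 1] <- 1L
  expect_equal(mean_connection_distance(A, lay), D[1, 2])
  # complete graph -> mean pairwise layout distance
  expect_equal(mean_connection_distance(graph_complete(8), lay),
               mean(D[upper.tri(D)]))
  # adding a longer-than-average edge strictly increases MCD
  base <- mean_connection_distance(A, lay)
  far <- which(D == max(D), arr.ind = TRUE)[1, ]
  stopifnot(D[far[1], far[2]] > base)
  A2 <- A
  A2[far[1], far[2]] <- A2[far[2], far[1]] <- 1L
  expect_gt(mean_connection_distance(A2, lay), base)
})

test_that("diagnostic sweeps produce nested-monotone curves with NA for undefined", {
  W <- random_weight_matrix(14, seed = 5)
  lay <- generate_layout(14, seed = 5)
  sw <- diagnostic_sweep(W, lay, kappas = seq(0.05, 0.5, 0.05),
                         rent_boxes = 1500)
  expect_equal(dim(sw), c(10, 13))
  eg <- sw[, "global_efficiency"]
  expect_true(all(diff(eg[is.finite(eg)]) >= -1e-12))  # non-decreasing
  # sparse low-density graphs leave spectral/scaling diagnostics missing
  sparse <- diagnostic_sweep(W, lay, kappas = 0.02, rent_boxes = 1500)
  expect_true(is.na(sparse[1, "rent_exponent"]))  # < 8 edges
  # single-graph wrappers agree with the sweep at matched density
  A <- cumulative_threshold(W, 0.3)
  sw3 <- diagnostic_sweep(W, lay, kappas = 0.3, rent_boxes = 1500, seed = 2)
  m <- basic_metrics(A)
  expect_equal(sw3[1, "path_length"], unname(m$path_length))
  expect_equal(sw3[1, "clustering"], unname(m$clustering))
  expect_equal(sw3[1, "betweenness"], unname(m$betweenness))
  expect_equal(sw3[1, "synchronizability"], synchronizability(A))
  expect_equal(sw3[1, "hierarchy"], hierarchy_exponent(A))
  expect_equal(sw3[1, "mean_connection_distance"],
               mean_connection_distance(A, lay))
})

test_that("trial-averaged curves propagate missing values, never zeros", {
  Ws <- lapply(1:4, function(i) random_weight_matrix(10, seed = i))
  cur <- diagnostic_curves(Ws, layout = generate_layout(10, seed = 1),
                           kappas = c(0.05, 0.2, 0.4), rent_boxes = 1500)
  expect_equal(dim(cur$mean), c(3, 13))
  expect_equal(dim(cur$per_trial), c(3, 13, 4))
  # at kappa = 0.05 a 10-node graph has 2 edges: Rent undefined in all trials
  expect_true(is.na(cur$mean[1, "rent_exponent"]))
  expect_false(any(cur$per_trial[1, "rent_exponent", ] == 0, na.rm = TRUE))
})

test_that("ER null curves sit inside bands from an independent regeneration", {
  kap <- c(0.2, 0.4)
  c1 <- er_null_curves(12, kappas = kap, n_graphs = 40, seed = 1,
                       rand_orders = 3)
  c2 <- er_null_curves(12, kappas = kap, n_graphs = 40, seed = 2,
                       rand_orders = 3)
  for (d in c("clustering", "global_efficiency", "path_length")) {
    expect_equal(c1[, d], c2[, d], tolerance = 0.15)
  }
})
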