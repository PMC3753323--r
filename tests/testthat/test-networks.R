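test_that("cumulative thresholding keeps the strongest edges at the target count", {
  W <- random_weight_matrix(12, seed = 1)
  m <- 12 * 11 / 2
  expect_equal(sum(cumulative_threshold(W, 0)) / 2, 0)      # empty at cost 0
  expect_equal(sum(cumulative_threshold(W, 1)) / 2, m)      # complete at 1
  for (k in c(0.1, 0.25, 0.5)) {
    A <- cumulative_threshold(W, k)
    expect_equal(sum(A) / 2, floor(k * m))
    expect_equal(unclass(A), t(unclass(A)))
    expect_true(all(diag(A) == 0))
    # retained edges are exactly the strongest ones
    thr <- sort(W[upper.tri(W)], decreasing = TRUE)[floor(k * m)]
    expect_true(all(W[A == 1] >= thr))
  }
})

test_that("all-equal weights break ties lexicographically", {
  W <- matrix(1, 6, 6)
  diag(W) <- 0
  A <- cumulative_threshold(W, 0.5)
  expect_equal(sum(A) / 2, floor(6 * 5 / 4))  # floor(N(N-1)/4) edges
  # documented tie rule: first pairs in (i, j) lexicographic order
  pairs <- do.call(rbind, lapply(1:5, function(i)
    cbind(i, (i + 1):6)))          # (1,2), (1,3), ..., (2,3), ...
  expected <- matrix(0L, 6, 6)
  expected[pairs[1:7, ]] <- 1L
  expected <- expected + t(expected)
  expect_equal(unclass(A), expected, ignore_attr = TRUE)
})

test_that("threshold sweeps are nested with one-edge density accuracy", {
  W <- random_weight_matrix(14, seed = 2)
  ens <- threshold_sweep(W)
  expect_length(ens, 50)  # grid 0.01..0.50 step 0.01
  m <- 14 * 13 / 2
  prev <- NULL
  for (i in seq_along(ens)) {
    A <- ens[[i]]
    k <- attr(A, "cost")
    expect_lte(abs(sum(A) / 2 - k * m), 1)  # one-edge resolution
    if (!is.null(prev)) expect_true(all(A[prev == 1] == 1))  # nesting
    prev <- A
  }
})

test_that("binary networks are blind to positive rescaling of weights", {
  W <- random_weight_matrix(10, seed = 3)
  for (k in c(0.1, 0.3)) {
    expect_identical(unclass(cumulative_threshold(W, k)),
                     unclass(cumulative_threshold(37.5 * W, k)))
  }
})

test_that("ER ensembles have exact edge counts and are seed-deterministic", {
  g <- er_random_graphs(10, 0.2, n_graphs = 66, seed = 4)
  expect_length(g, 66)
  for (A in g[1:10]) {
    expect_equal(sum(A) / 2, 9)  # floor(0.2 * 45)
    expect_equal(unclass(A), t(unclass(A)))
    expect_true(all(diag(A) == 0))
  }
  g2 <- er_random_graphs(10, 0.2, n_graphs = 66, seed = 4)
  expect_identical(lapply(g, unclass), lapply(g2, unclass))
  g3 <- er_random_graphs(10, 0.2, n_graphs = 66, seed = 5)
  expect_false(identical(lapply(g, unclass), lapply(g3, unclass)))
})
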