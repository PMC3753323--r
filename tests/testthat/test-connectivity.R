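test_that("histogram MI matches a contingency-table oracle and self-information", {
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(216)
    y <- 0.5 * x + rnorm(216)
    est <- histogram_mi(x, y)
    ix <- megnets:::bin_indices(x, 8, "width")
    iy <- megnets:::bin_indices(y, 8, "width")
    expect_equal(est$mi, oracle_mi_bits(ix, iy), tolerance = 1e-12)
    # self-information: I(x, x) = H(x)
    self <- histogram_mi(x, x)
    expect_equal(self$mi, self$hx, tolerance = 1e-12)
    expect_equal(normalized_mi(x, x), 1)
  }
})

test_that("constant series yield zero MI with a degenerate flag", {
  x <- rnorm(64)
  expect_warning(est <- histogram_mi(x, rep(1, 64)), "constant")
  expect_equal(est$mi, 0)
  expect_true(est$degenerate)
  expect_warning(expect_equal(normalized_mi(x, rep(1, 64)), 0))
})

test_that("NMI is bounded in [0, 1] and small for independent noise", {
  set.seed(5)
  vals <- replicate(60, {
    normalized_mi(rnorm(216), rnorm(216))
  })
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(vals < 0.15))  # estimator bias bound at n = 216, 8 bins
})

test_that("independent-noise MI stays below its permutation null", {
  set.seed(6)
  below <- replicate(100, {
    x <- runif(216)
    y <- runif(216)
    obs <- histogram_mi(x, y)$mi
    null <- replicate(49, histogram_mi(x, sample(y))$mi)
    obs <= quantile(null, 0.95)
  })
  expect_gte(mean(below), 0.80)
})

test_that("quantile binning makes MI invariant to monotone transforms", {
  set.seed(7)
  x <- rnorm(216)
  y <- rnorm(216) + x
  a <- histogram_mi(x, y, binning = "quantile")$mi
  b <- histogram_mi(exp(x), y, binning = "quantile")$mi  # strictly monotone
  expect_lt(abs(a - b), 1e-9)
})

test_that("C++ pairwise kernels agree with the R estimator", {
  set.seed(8)
  X <- matrix(rnorm(216 * 9), 216, 9)
  Y <- matrix(rnorm(216 * 9), 216, 9)
  BX <- megnets:::cpp_bin_columns(X, 8L)
  BY <- megnets:::cpp_bin_columns(Y, 8L)
  # binning equivalence with the R path
  for (j in 1:9)
    expect_equal(BX[, j], megnets:::bin_indices(X[, j], 8, "width"))
  W <- megnets:::cpp_nmi_allpairs(BX, 8L)
  R <- megnets:::cpp_nmi_cross(BX, BY, 8L)
  for (i in 1:4) for (j in 5:9) {
    expect_equal(W[i, j], normalized_mi(X[, i], X[, j]), tolerance = 1e-12)
    expect_equal(R[i, j], normalized_mi(X[, i], Y[, j]), tolerance = 1e-12)
  }
})

test_that("intra matrices are symmetric, unit-diagonal-free and in [0, 1]", {
  fx <- band_decomposition_for(tiny_cohort_config(), group_params(), seed = 9)
  W <- build_intra_matrix(fx$decomp, "theta", 1)
  expect_equal(unclass(W), t(unclass(W)))
  expect_true(all(diag(W) == 0))
  expect_true(all(W >= 0 & W <= 1))
  # duplicated sensor signals give weight 1
  dup <- fx$decomp
  dup$bands$theta[2, , ] <- dup$bands$theta[1, , ]
  W2 <- build_intra_matrix(dup, "theta", 1)
  expect_equal(W2[1, 2], 1)
})

test_that("the stack has 4 intra + 6 inter kinds; inter matrices symmetrized", {
  fx <- band_decomposition_for(tiny_cohort_config(), group_params(), seed = 9)
  expect_length(network_kinds(), 10)
  mats <- connectivity_stack(fx$decomp, 1)
  expect_named(mats, network_kinds())
  Wi <- mats$gamma_low_theta
  expect_equal(unclass(Wi), t(unclass(Wi)))
  raw <- attr(Wi, "raw")
  expect_false(isTRUE(all.equal(raw, t(raw))))  # raw cross matrix asymmetric
  expect_equal(unclass(Wi), {
    s <- (raw + t(raw)) / 2
    diag(s) <- 0
    s
  }, ignore_attr = TRUE)
  expect_error(build_inter_matrix(fx$decomp, "theta", "theta", 1), "differ")
  # per-trial count: 10 kinds x trials
  n_trials <- dim(fx$decomp$bands[[1]])[2]
  expect_equal(length(mats) * n_trials, 10 * n_trials)
})

test_that("strength follows the hand-computed means and equivariance", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.2
  W[1, 3] <- W[3, 1] <- 0.4
  W[2, 3] <- W[3, 2] <- 0.6
  st <- strength(W)
  expect_equal(st$sensor_strength, c(0.3, 0.4, 0.5))
  expect_equal(st$network_strength, 0.4)
  # constant weights -> every sensor strength equals the weight
  Wc <- matrix(0.37, 4, 4)
  diag(Wc) <- 0
  expect_equal(strength(Wc)$sensor_strength, rep(0.37, 4))
  # permutation equivariance
  p <- c(3, 1, 2)
  expect_equal(strength(W[p, p])$sensor_strength,
               st$sensor_strength[p])
  expect_error(strength(matrix(0, 1, 1)), "at least 2")
})
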