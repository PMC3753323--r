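test_that("permutation test respects the add-one convention and symmetry", {
  a <- c(1, 2, 3, 4)
  # identical samples -> p = 1
  expect_equal(permutation_test(a, a, n_perm = 199, seed = 1), 1)
  # widely separated groups at n = 14 per group reach the minimum
  # attainable p: the chance of redrawing the original split is ~2/C(28,14)
  set.seed(2)
  x <- rnorm(14)
  y <- rnorm(14) + 10
  expect_equal(permutation_test(x, y, n_perm = 999, seed = 3), 1 / 1000)
  expect_equal(permutation_test(x, y, n_perm = 9999, seed = 3), 1 / 10000)
  # exhaustive check at n = 4 per group: exactly the 2 original labelings
  # (identity and complement) attain the observed gap, so the sampled
  # p-value concentrates near (1 + 2 n_perm / 70) / (n_perm + 1)
  a4 <- c(0, 0.1, -0.1, 0.05)
  b4 <- a4 + 50
  combs <- combn(8, 4)
  pooled <- c(a4, b4)
  obs <- abs(mean(a4) - mean(b4))
  stats <- apply(combs, 2, function(i) abs(mean(pooled[i]) - mean(pooled[-i])))
  expect_equal(sum(stats >= obs), 2)
  p4 <- permutation_test(a4, b4, n_perm = 1999, seed = 4)
  expect_gt(p4, 0.005)
  expect_lt(p4, 0.08)  # 2/70 = 0.0286 +/- sampling noise
  # label-swap symmetry under a common seed
  expect_equal(permutation_test(x, y, n_perm = 199, seed = 5),
               permutation_test(y, x, n_perm = 199, seed = 5))
  expect_equal(permutation_test(a4, b4, n_perm = 199, seed = 6),
               permutation_test(b4, a4, n_perm = 199, seed = 6))
})

test_that("Holm and BH match brute-force definitional computation", {
  expect_equal(holm_bonferroni(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_bonferroni(0.3), 0.3)
  expect_equal(holm_bonferroni(rep(1, 5)), rep(1, 5))
  expect_error(holm_bonferroni(c(0.5, 0)), "0, 1")
  brute_holm <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    run <- 0
    for (i in seq_len(m)) {
      run <- max(run, min(1, (m - i + 1) * p[o[i]]))
      adj[o[i]] <- run
    }
    adj
  }
  brute_bh <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    k <- which(ps <= seq_len(m) * q / m)
    flags <- rep(FALSE, m)
    if (length(k)) flags[o[seq_len(max(k))]] <- TRUE
    flags
  }
  set.seed(6)
  for (i in 1:20) {
    p <- runif(6)^2
    expect_equal(holm_bonferroni(p), brute_holm(p), tolerance = 1e-12)
    expect_equal(benjamini_hochberg(p, q = 0.1), brute_bh(p, 0.1))
  }
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), q = 0.05),
               rep(TRUE, 4))
  expect_equal(benjamini_hochberg(c(0.9, 0.95), q = 0.05), rep(FALSE, 2))
  expect_length(benjamini_hochberg(numeric(0)), 0)
})

test_that("FDA curve test is calibrated under the null and detects offsets", {
  # type I: identical generating process for both groups
  set.seed(7)
  rej <- replicate(200, {
    a <- matrix(rnorm(8 * 10), 8)
    b <- matrix(rnorm(8 * 10), 8)
    fda_permutation_test(a, b, n_perm = 99, seed = sample.int(1e6, 1)) <= 0.05
  })
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 200)
  expect_gte(mean(rej), ci[1] - 1e-9)
  expect_lte(mean(rej), ci[2] + 1e-9)
  # power: constant offset of twice the between-subject SD at n = 14
  set.seed(8)
  hits <- replicate(100, {
    a <- matrix(rnorm(14 * 10), 14)
    b <- matrix(rnorm(14 * 10), 14) + 2
    fda_permutation_test(a, b, n_perm = 199, seed = sample.int(1e6, 1)) <= 0.05
  })
  expect_gte(mean(hits), 0.8)
  # label-swap symmetry with a common seed
  a <- matrix(rnorm(6 * 8), 6)
  b <- matrix(rnorm(6 * 8), 6)
  expect_equal(fda_permutation_test(a, b, n_perm = 99, seed = 9),
               fda_permutation_test(b, a, n_perm = 99, seed = 9))
  # sup statistic is a selectable alternative
  expect_true(is.numeric(fda_permutation_test(a, b, n_perm = 49, seed = 1,
                                              statistic = "sup")))
})

test_that("coefficient of variation is the sample-SD/mean with scale invariance", {
  expect_equal(coefficient_of_variation(c(3, 3, 3)), 0)
  expect_equal(coefficient_of_variation(c(2, 4)), sqrt(2) / 3)
  x <- rexp(20)
  expect_equal(coefficient_of_variation(5 * x), coefficient_of_variation(x),
               tolerance = 1e-12)
  expect_warning(v <- coefficient_of_variation(c(-1, 1)), "zero mean")
  expect_true(is.na(v))
})

test_that("RM-ANOVA degrees of freedom follow the 10 x 10 within design", {
  set.seed(10)
  subjects <- sprintf("s%02d", 1:8)
  grid <- expand.grid(subject = subjects, band = network_kinds(),
                      diagnostic = paste0("d", 1:10))
  grid$group <- ifelse(grid$subject %in% subjects[1:4], "control", "patient")
  grid$cv <- rnorm(nrow(grid), 0.5, 0.1)
  out <- rm_anova_cv(grid)
  expect_equal(out$DF, c(1, 9, 9, 81, 9, 9, 81))
  expect_equal(out$effect[1], "Group")
  expect_true(all(out$F >= 0))
  # missing cells are rejected, no imputation
  bad <- grid[-1, ]
  expect_error(rm_anova_cv(bad), "balanced")
})

test_that("RM-ANOVA group F is calibrated under the null", {
  set.seed(11)
  fs <- replicate(100, {
    grid <- expand.grid(subject = sprintf("s%d", 1:6), band = paste0("b", 1:4),
                        diagnostic = paste0("d", 1:4))
    grid$group <- ifelse(grid$subject %in% sprintf("s%d", 1:3), "a", "b")
    subj_eff <- rnorm(6, 0, 0.05)
    grid$cv <- 0.5 + subj_eff[as.integer(factor(grid$subject))] +
      rnorm(nrow(grid), 0, 0.05)
    rm_anova_cv(grid)$F[1]
  })
  # F(1, 4) has mean df2/(df2-2) = 2; allow 3 SE of the replicate mean
  expect_lt(abs(mean(fs) - 2), 3 * sd(fs) / sqrt(length(fs)))
})

test_that("entropy-strength fits recover exact, null and noisy relationships", {
  # collinear points -> R^2 = 1
  e <- c(1, 2, 3, 4)
  s <- 2 - 0.5 * e
  fit <- entropy_strength_fit(e, s)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, -0.5)
  # zero entropy variance -> missing slope
  expect_true(is.na(entropy_strength_fit(rep(1, 5), rnorm(5))$slope))
  # independence at n = 14: P(R^2 < 0.2) has the exact F(1, 12) value
  # P(F < 0.2/0.8 * 12) ~ 0.89; the replicate rate must sit within
  # 3 binomial SE of it
  set.seed(12)
  low <- replicate(200, {
    entropy_strength_fit(rnorm(14), rnorm(14))$r_squared < 0.2
  })
  p_exact <- pf(0.2 / 0.8 * 12, 1, 12)
  se <- sqrt(p_exact * (1 - p_exact) / length(low))
  expect_lt(abs(mean(low) - p_exact), 3 * se)
})
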