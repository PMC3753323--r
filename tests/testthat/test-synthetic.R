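test_that("hemispherical layouts are valid, distinct and deterministic", {
  for (n in c(8, 64, 275)) {
    lay <- generate_layout(n, seed = 1)
    co <- layout_coords(lay)
    expect_equal(nrow(lay), n)
    expect_true(all(is.finite(co)))
    expect_true(all(co[, "z"] >= 0))
    expect_true(all(abs(rowSums(co^2) - 1) < 1e-8))  # unit radius
    expect_gt(min(dist(co)), 0)
    expect_false(any(duplicated(lay$sensor)))
  }
  expect_identical(generate_layout(275, seed = 1), generate_layout(275, seed = 1))
  expect_error(generate_layout(7), "n_sensors")
})

test_that("subject generation has the protocol shape and is seed-deterministic", {
  cfg <- cohort_config(n_subjects_per_group = 1, n_sensors = 10,
                       master_seed = 1)  # defaults: 6 blocks x 11 sets, 600 Hz
  lay <- generate_layout(10, seed = 1)
  rec <- generate_subject(group_params(), cfg, lay, seed = 3)
  expect_equal(dim(rec$data), c(10, 66, 1080))  # 6x11 epochs, 1.8 s x 600 Hz
  expect_equal(rec$sampling_rate, 600)
  expect_true(all(is.finite(rec$data)))
  rec2 <- generate_subject(group_params(), cfg, lay, seed = 3)
  expect_identical(rec$data, rec2$data)
  rec3 <- generate_subject(group_params(), cfg, lay, seed = 4)
  expect_false(identical(rec$data, rec3$data))
})

test_that("cohorts are balanced, manifest-complete and reproducible", {
  cfg <- tiny_cohort_config()
  co <- generate_cohort(cfg)
  expect_length(co$recordings, 4)
  groups <- vapply(co$recordings, function(r) r$group, "")
  expect_equal(sum(groups == "control"), 2)
  expect_equal(sum(groups == "patient"), 2)
  expect_named(co$manifest$subject_seeds, names(co$recordings))
  expect_true(all(c("n_sensors", "master_seed", "control", "patient") %in%
                    names(co$manifest$config)))
  co2 <- generate_cohort(cfg)
  expect_identical(
    lapply(co$recordings, function(r) r$data),
    lapply(co2$recordings, function(r) r$data)
  )
})

test_that("cohort containers round-trip through disk with layout CSV", {
  co <- generate_cohort(tiny_cohort_config())
  path <- file.path(tempdir(), "cohort.rds")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_identical(back$recordings[[1]]$data, co$recordings[[1]]$data)
  lay <- read_layout_csv(file.path(tempdir(), "cohort_layout.csv"))
  expect_equal(layout_coords(lay), layout_coords(co$layout), tolerance = 1e-12)
  expect_true(file.exists(file.path(tempdir(), "cohort_manifest.json")))
})

test_that("group parameter validation rejects out-of-range values", {
  expect_error(group_params(trial_jitter = -1), "trial_jitter")
  expect_error(group_params(noise_sd = 0), "noise_sd")
  expect_error(group_params(regularity = c(gamma_low = 2, beta = 0, alpha = 0,
                                           theta = 0)), "regularity")
  expect_error(group_params(xfreq_coupling = c(theta_nope = 1)) |>
                 (\(p) generate_subject(p, tiny_cohort_config(),
                                        generate_layout(10, 1), 1))(),
               "xfreq_coupling")
})

test_that("uncoupled sensors stay at the independent-noise NMI floor", {
  # Monte-Carlo floor: NMI between fully independent band-limited series
  # run through the identical estimator settings
  cfg <- tiny_cohort_config(n_sensors = 10)
  pars <- group_params(coupling_scale = c(gamma_low = 0, beta = 0, alpha = 0,
                                          theta = 0),
                       xfreq_coupling = c(theta_gamma_low = 0))
  fx <- band_decomposition_for(cfg, pars, seed = 21)
  vals <- c()
  for (t in seq_len(3)) {
    W <- build_intra_matrix(fx$decomp, "alpha", t)
    vals <- c(vals, W[upper.tri(W)])
  }
  set.seed(99)
  floor_vals <- replicate(200, {
    x <- narrowband_floor_series()
    y <- narrowband_floor_series()
    normalized_mi(x, y)
  })
  expect_lt(mean(vals), mean(floor_vals) + 3 * sd(floor_vals))
})
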