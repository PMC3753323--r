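test_that("MODWT preserves length, energy and matches the direct definition", {
  set.seed(1)
  for (wv in c("d4", "db4")) {
    x <- rnorm(216)
    d <- modwt_decompose(x, n_scales = 4, wavelet = wv)
    expect_equal(dim(d$details), c(216, 4))
    en <- sum(d$details^2) + sum(d$smooth^2)
    expect_lt(abs(en - sum(x^2)) / sum(x^2), 1e-10)
    ref <- oracle_modwt(x, 4, wv)
    expect_equal(unname(d$details), ref$details, tolerance = 1e-12)
    expect_equal(d$smooth, ref$smooth, tolerance = 1e-12)
  }
})

test_that("MODWT is exactly equivariant under circular shifts", {
  set.seed(2)
  x <- rnorm(216)
  s <- 17
  xs <- c(x[(216 - s + 1):216], x[1:(216 - s)])
  d <- modwt_decompose(x)$details
  ds <- modwt_decompose(xs)$details
  expect_equal(ds, rbind(d[(216 - s + 1):216, ], d[1:(216 - s), ]),
               tolerance = 1e-12)
})

test_that("scale bands localize oscillations at their nominal frequencies", {
  t <- (0:215) / 120
  # 20 Hz lies in the 15-30 Hz scale-2 band
  d <- modwt_decompose(sin(2 * pi * 20 * t))$details
  expect_equal(unname(which.max(colSums(d^2))), 2L)
  d <- modwt_decompose(sin(2 * pi * 6 * t))$details   # theta
  expect_equal(unname(which.max(colSums(d^2))), 4L)
  d <- modwt_decompose(sin(2 * pi * 45 * t))$details  # low gamma
  expect_equal(unname(which.max(colSums(d^2))), 1L)
})

test_that("series shorter than the deepest filter support are rejected", {
  expect_error(modwt_decompose(rnorm(20), n_scales = 4), "too short")
  expect_silent(modwt_decompose(rnorm(25), n_scales = 4))
})

test_that("resampling hits the protocol sample count and keeps spectral peaks", {
  t600 <- (0:1079) / 600
  data <- array(0, dim = c(2, 3, 1080))
  for (tr in 1:3) {
    data[1, tr, ] <- sin(2 * pi * 10 * t600)
    data[2, tr, ] <- rnorm(1080)
  }
  rec <- epoched_recording("s", "control", data, 600)
  out <- resample_to_analysis_rate(rec, 120)
  expect_equal(dim(out$data), c(2, 3, 216))  # 1800 ms at 120 Hz
  spec <- abs(fft(out$data[1, 1, ]))[2:108]
  expect_equal((which.max(spec)) * 120 / 216, 10, tolerance = 0.6)
  # identity case returns the recording unchanged
  expect_identical(resample_to_analysis_rate(rec, 600), rec)
  expect_error(resample_to_analysis_rate(rec, 250), "divide")
})

test_that("epoching uses half-open onset windows in onset order", {
  cont <- matrix(rep(0:99, each = 2), nrow = 2, byrow = FALSE)
  cont[1, ] <- 0:99
  rec <- epoch_recording(cont, onsets = c(20, 0), duration = 1, rate = 10)
  expect_equal(dim(rec$data), c(2, 2, 10))
  expect_equal(rec$data[1, 1, ], 0:9)    # onset 0 -> samples 0..9
  expect_equal(rec$data[1, 2, ], 20:29)  # trials sorted by onset
  # identical onsets give identical trials; overlap allowed
  r2 <- epoch_recording(cont, onsets = c(5, 5), duration = 1, rate = 10)
  expect_identical(r2$data[, 1, ], r2$data[, 2, ])
  expect_error(epoch_recording(cont, onsets = 95, duration = 1, rate = 10),
               "beyond")
})

test_that("band decomposition exposes four equal-length detail arrays", {
  fx <- band_decomposition_for(tiny_cohort_config(), group_params(), seed = 4)
  d <- fx$decomp
  expect_named(d$bands, c("gamma_low", "beta", "alpha", "theta"))
  for (b in names(d$bands)) expect_equal(dim(d$bands[[b]]), c(10, 6, 216))
  expect_true(all(vapply(d$bands, function(a) all(is.finite(a)), TRUE)))
})
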