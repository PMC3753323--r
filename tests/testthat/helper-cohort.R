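# Small cohort / pipeline fixtures shared across test files. Everything is
# generated in code; sizes are kept small so the whole suite stays fast.

tiny_cohort_config <- function(master_seed = 11L, n_subjects = 2L,
                               n_sensors = 10L, n_blocks = 2L,
                               sets_per_block = 3L) {
  cohort_config(
    n_subjects_per_group = n_subjects, n_sensors = n_sensors,
    n_blocks = n_blocks, sets_per_block = sets_per_block,
    native_rate = 120, analysis_rate = 120, master_seed = master_seed
  )
}

tiny_run_config <- function(cohort = tiny_cohort_config(), ...) {
  run_config(
    cohort = cohort, kappas = seq(0.1, 0.5, 0.1),
    n_perm_univariate = 99, n_perm_fda = 99,
    mod_restarts = 2, rand_orders = 3, rent_boxes = 1000, seed = 7L, ...
  )
}

# deterministic weighted test matrix
random_weight_matrix <- function(n, seed = 1) {
  set.seed(seed)
  W <- matrix(runif(n * n), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

band_decomposition_for <- function(config, params, seed = 5L) {
  lay <- generate_layout(config$n_sensors, seed = seed)
  rec <- generate_subject(params, config, lay, seed = seed)
  rec <- resample_to_analysis_rate(rec, config$analysis_rate)
  list(layout = lay, decomp = decompose_bands(rec))
}

# one independent "sensor" series processed like the alpha-band pipeline:
# narrowband source + white noise -> MODWT scale-3 detail series
narrowband_floor_series <- function(n = 216, rate = 120) {
  x <- megnets:::narrowband_noise(n, 1, 8.25, 11.75, rate)[, 1] + rnorm(n)
  modwt_decompose(x)$details[, 3]
}
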