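#' Group-level generative parameters for the synthetic cohort
#'
#' Encodes the statistical structure of one group's recordings: how strongly
#' sensors share band-limited sources (`coupling_scale`, driving
#' inter-sensor mutual information), how stereotyped the band envelopes are
#' (`regularity`, driving wavelet entropy down as it increases), how strongly
#' a low band drives a high band's amplitude (`xfreq_coupling`,
#' driving inter-frequency mutual information), how much the sensor mixing
#' fluctuates from trial to trial (`trial_jitter`, driving the coefficient of
#' variation of network diagnostics), and the white sensor-noise level
#' (`noise_sd`).
#'
#' @param coupling_scale named non-negative vector over bands
#'   (`gamma_low`, `beta`, `alpha`, `theta`); shared-source loading.
#' @param regularity named vector over bands in `[0, 1]`; envelope
#'   stereotypy. Higher values concentrate band energy into bursts and lower
#'   the wavelet entropy.
#' @param xfreq_coupling named non-negative vector over ordered band pairs,
#'   e.g. `c(theta_gamma_low = 0.4)`: each sensor's low-band waveform
#'   modulates its high-band amplitude with this gain (phase-locked
#'   amplitude coupling).
#' @param trial_jitter non-negative SD of the per-trial perturbation of the
#'   source-loading matrix.
#' @param noise_sd positive white-noise SD.
#' @return A validated `group_params` list.
#' @export
group_params <- function(coupling_scale = c(gamma_low = 0.6, beta = 0.8,
                                            alpha = 1.0, theta = 1.2),
                         regularity = c(gamma_low = 0.15, beta = 0.15,
                                        alpha = 0.15, theta = 0.15),
                         xfreq_coupling = c(theta_gamma_low = 0.4),
                         trial_jitter = 0.15,
                         noise_sd = 1.0) {
  coupling_scale <- coupling_scale[BAND_NAMES]
  regularity <- regularity[BAND_NAMES]
  if (anyNA(coupling_scale) || any(coupling_scale < 0))
    stop("coupling_scale must be named over all four bands and >= 0")
  if (anyNA(regularity) || any(regularity < 0) || any(regularity > 1))
    stop("regularity must be named over all four bands, in [0, 1]")
  if (length(xfreq_coupling) && (is.null(names(xfreq_coupling)) ||
                                 any(xfreq_coupling < 0)))
    stop("xfreq_coupling must be a named non-negative vector")
  if (!is.finite(trial_jitter) || trial_jitter < 0)
    stop("trial_jitter must be finite and >= 0")
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be finite and > 0")
  structure(list(coupling_scale = coupling_scale, regularity = regularity,
                 xfreq_coupling = xfreq_coupling,
                 trial_jitter = trial_jitter, noise_sd = noise_sd),
            class = "group_params")
}

#' Patient-like parameter preset
#'
#' Relative to [group_params()] defaults (the control preset): 1.4x band
#' coupling, higher envelope regularity, doubled theta–low-gamma coupling and
#' doubled trial jitter — giving higher strength, lower entropy and stronger
#' cross-frequency coupling. Note that the realized trial-to-trial CV of
#' network diagnostics reflects the jitter-to-coupling ratio, not jitter
#' alone: raising `trial_jitter` with everything else fixed raises the CV,
#' but this preset also raises coupling.
#' @export
patient_params <- function() {
  ctrl <- group_params()
  group_params(
    coupling_scale = ctrl$coupling_scale * 1.4,
    regularity = ctrl$regularity + 0.25,
    xfreq_coupling = ctrl$xfreq_coupling * 2,
    trial_jitter = ctrl$trial_jitter * 2,
    noise_sd = ctrl$noise_sd
  )
}

#' Configuration of a two-group synthetic cohort
#'
#' Defaults mirror the acquisition protocol the analysis assumes: 6 blocks of
#' 11 stimulus-response periods (66 epochs of 1.8 s), 600 Hz native sampling
#' analyzed at 120 Hz, and 14 subjects per group with a 275-sensor layout.
#'
#' @param n_subjects_per_group subjects per group.
#' @param n_sensors sensors in the layout (>= 8).
#' @param n_blocks,sets_per_block task structure; trials = product.
#' @param epoch_duration epoch length in seconds.
#' @param native_rate,analysis_rate sampling rates in Hz;
#'   `epoch_duration * analysis_rate` must be an integer.
#' @param control,patient `group_params` for the two groups.
#' @param master_seed integer master seed; all subject seeds derive from it.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_subjects_per_group = 14, n_sensors = 275,
                          n_blocks = 6, sets_per_block = 11,
                          epoch_duration = 1.8, native_rate = 600,
                          analysis_rate = 120,
                          control = group_params(),
                          patient = patient_params(),
                          master_seed = 1L) {
  n_an <- epoch_duration * analysis_rate
  if (abs(n_an - round(n_an)) > 1e-9)
    stop("epoch_duration * analysis_rate must be an integer")
  n_na <- epoch_duration * native_rate
  if (abs(n_na - round(n_na)) > 1e-9)
    stop("epoch_duration * native_rate must be an integer")
  if (n_blocks * sets_per_block < 2)
    stop("need at least 2 trials (n_blocks * sets_per_block >= 2)")
  if (n_sensors < 8) stop("n_sensors must be >= 8")
  stopifnot(inherits(control, "group_params"), inherits(patient, "group_params"))
  structure(list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    n_sensors = as.integer(n_sensors),
    n_blocks = as.integer(n_blocks),
    sets_per_block = as.integer(sets_per_block),
    epoch_duration = epoch_duration,
    native_rate = native_rate,
    analysis_rate = analysis_rate,
    control = control, patient = patient,
    master_seed = as.integer(master_seed)
  ), class = "cohort_config")
}

#' Construct an epoched recording
#'
#' @param subject_id label.
#' @param group `"control"` or `"patient"`.
#' @param data numeric array sensors x trials x samples, all finite.
#' @param sampling_rate Hz.
#' @return `epoched_recording` object.
#' @export
epoched_recording <- function(subject_id, group, data, sampling_rate) {
  group <- match.arg(group, c("control", "patient"))
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!all(is.finite(data))) stop("recording contains non-finite values")
  structure(list(subject_id = subject_id, group = group, data = data,
                 sampling_rate = sampling_rate),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_recording> %s (%s): %d sensors x %d trials x %d samples @ %g Hz\n",
              x$subject_id, x$group, d[1], d[2], d[3], x$sampling_rate))
  invisible(x)
}

# 4th-order Butterworth band-pass magnitude response on an FFT frequency
# grid; applied spectrally to white noise to synthesize narrowband sources.
butter_bp_gain <- function(freqs, f_lo, f_hi) {
  f0sq <- f_lo * f_hi
  bw <- f_hi - f_lo
  g <- numeric(length(freqs))
  pos <- freqs > 0
  ratio <- (freqs[pos]^2 - f0sq) / (bw * freqs[pos])
  g[pos] <- 1 / sqrt(1 + ratio^4)
  g
}

# Band-limit the columns of a white-noise matrix to [f_lo, f_hi] at rate
# `rate` (spectral Butterworth magnitude, zero phase) and rescale each
# column to unit SD.
bandlimit_white <- function(w, f_lo, f_hi, rate) {
  n <- nrow(w)
  freqs <- (seq_len(n) - 1) / n * rate
  freqs <- pmin(freqs, rate - freqs)  # two-sided grid
  gain <- butter_bp_gain(freqs, f_lo, f_hi)
  x <- Re(mvfft(mvfft(w) * gain, inverse = TRUE)) / n
  sds <- sqrt(colMeans(x^2) - colMeans(x)^2) * sqrt(n / (n - 1))
  sds[sds < 1e-12] <- 1
  x / rep(sds, each = n)
}

# Narrowband Gaussian sources: columns of a T x m matrix.
narrowband_noise <- function(n, m, f_lo, f_hi, rate) {
  bandlimit_white(matrix(rnorm(n * m), n, m), f_lo, f_hi, rate)
}

# Amplitude envelope of each column via the analytic signal.
envelope_mat <- function(x) {
  n <- nrow(x)
  X <- mvfft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(mvfft(X * h, inverse = TRUE) / n)
}

# Concentrate each column's envelope (regularity knob): multiplying by
# (e / mean(e))^(2 r) sharpens bursts, lowering the time-point energy
# entropy monotonically in r; the series is rescaled to its original SD so
# the knob does not change band power.
sharpen_envelope <- function(x, r) {
  if (r <= 0) return(x)
  n <- nrow(x)
  e <- envelope_mat(x)
  e <- e / rep(colMeans(e), each = n)
  y <- x * e^(2 * r)
  col_sd <- function(m) sqrt(pmax(0, colMeans(m^2) - colMeans(m)^2))
  s0 <- col_sd(x)
  s1 <- col_sd(y)
  s1[s1 < 1e-12] <- 1
  y * rep(s0 / s1, each = n)
}

# Band edges used by the generator: oscillatory centers (theta 6, alpha 10,
# beta 20, low gamma 45 Hz) with bandwidth equal to half the nominal
# scale-band width, keeping sources well inside each dyadic band.
generator_band_edges <- function() {
  out <- list()
  for (f in BAND_NAMES) {
    ctr <- BAND_CENTERS[[f]]
    bw <- (BAND_EDGES[[f]][2] - BAND_EDGES[[f]][1]) / 2
    out[[f]] <- c(max(0.5, ctr - bw / 2), ctr + bw / 2)
  }
  out
}

#' Generate one subject's epoched recording
#'
#' Per band, latent narrowband Gaussian sources at the native rate are mixed
#' into sensors through a distance-decaying loading matrix
#' (`exp(-d / 0.4)` over the unit-radius layout) scaled by the band's
#' `coupling_scale`, plus an independent narrowband source and white noise
#' per sensor. For cross-frequency pairs listed in `xfreq_coupling`, each
#' sensor's high-band amplitude is modulated by its instantaneous low-band
#' waveform with the given gain (phase-locked amplitude coupling); because
#' low-band sources are spatially shared, this induces low-high dependence
#' across sensor pairs.
#' Each trial redraws all sources and perturbs the loading matrix with
#' `N(0, trial_jitter)` entries; the envelope-regularity knob is applied per
#' sensor and band. Fully deterministic given `seed`.
#'
#' @param params `group_params`.
#' @param config `cohort_config`.
#' @param layout `sensor_layout` with `config$n_sensors` sensors.
#' @param seed integer seed.
#' @param subject_id,group labels stored on the recording.
#' @return `epoched_recording` at the native rate.
#' @export
generate_subject <- function(params, config, layout, seed,
                             subject_id = "S1", group = "control") {
  stopifnot(inherits(params, "group_params"), inherits(config, "cohort_config"),
            inherits(layout, "sensor_layout"))
  N <- config$n_sensors
  if (nrow(layout) != N) stop("layout size does not match config$n_sensors")
  n_trials <- config$n_blocks * config$sets_per_block
  n_samp <- round(config$epoch_duration * config$native_rate)
  rate <- config$native_rate
  edges <- generator_band_edges()

  K <- max(4L, min(12L, as.integer(ceiling(N / 20))))
  set.seed(as.integer(seed))
  # source locations on the cap (fixed across trials)
  z <- runif(K, 0.1, 0.95)
  az <- runif(K, 0, 2 * pi)
  src <- cbind(sqrt(1 - z^2) * cos(az), sqrt(1 - z^2) * sin(az), z)
  co <- layout_coords(layout)
  dmat <- sqrt(outer(rowSums(co^2), rep(1, K)) +
                 outer(rep(1, N), rowSums(src^2)) - 2 * co %*% t(src))
  G0 <- exp(-dmat / 0.4)

  # parse cross-frequency pairs "low_high" once
  xf <- params$xfreq_coupling
  xf_pairs <- list()
  if (length(xf)) {
    for (nm in names(xf)) {
      if (xf[[nm]] <= 0) next
      hit <- NULL
      for (lo in BAND_NAMES) for (hi in BAND_NAMES) {
        if (lo != hi && nm == paste(lo, hi, sep = "_")) hit <- c(lo, hi)
      }
      if (is.null(hit)) stop("unrecognized xfreq_coupling name: ", nm)
      xf_pairs[[length(xf_pairs) + 1]] <- list(lo = hit[1], hi = hit[2],
                                               gain = xf[[nm]])
    }
  }

  data <- array(0, dim = c(N, n_trials, n_samp))
  band_order <- c("theta", "alpha", "beta", "gamma_low")  # low bands first
  # trials are processed in chunks so FFT work is batched across trials
  # while batch matrices stay below ~30 MB
  chunk_size <- max(1L, min(n_trials, floor(4e6 / (n_samp * max(K, N)))))
  starts <- seq(1L, n_trials, by = chunk_size)
  for (s0 in starts) {
    tn <- s0:min(s0 + chunk_size - 1L, n_trials)
    nc <- length(tn)
    wsh <- lapply(band_order, function(f) matrix(0, n_samp, K * nc))
    names(wsh) <- band_order
    wlo <- lapply(band_order, function(f) matrix(0, n_samp, N * nc))
    names(wlo) <- band_order
    jit <- lapply(band_order, function(f) array(0, dim = c(N, K, nc)))
    names(jit) <- band_order
    wn <- matrix(0, n_samp, N * nc)
    # per-trial random draws (one RNG stream per (subject, trial))
    for (ti in seq_len(nc)) {
      set.seed(derive_seed(seed, tn[ti]))
      for (f in band_order) {
        wsh[[f]][, (ti - 1) * K + seq_len(K)] <- rnorm(n_samp * K)
        wlo[[f]][, (ti - 1) * N + seq_len(N)] <- rnorm(n_samp * N)
        jit[[f]][, , ti] <- rnorm(N * K, sd = params$trial_jitter)
      }
      wn[, (ti - 1) * N + seq_len(N)] <- rnorm(n_samp * N,
                                               sd = params$noise_sd)
    }
    shared <- lapply(band_order, function(f)
      bandlimit_white(wsh[[f]], edges[[f]][1], edges[[f]][2], rate))
    names(shared) <- band_order
    local <- lapply(band_order, function(f)
      bandlimit_white(wlo[[f]], edges[[f]][1], edges[[f]][2], rate))
    names(local) <- band_order
    # mix sources into sensors per band
    y <- list()
    for (f in band_order) {
      yf <- local[[f]]
      for (ti in seq_len(nc)) {
        Gt <- G0 + jit[[f]][, , ti]
        cols <- (ti - 1) * N + seq_len(N)
        yf[, cols] <- yf[, cols] + params$coupling_scale[[f]] *
          (shared[[f]][, (ti - 1) * K + seq_len(K), drop = FALSE] %*% t(Gt))
      }
      y[[f]] <- yf
    }
    # cross-frequency coupling at the sensor level: each sensor's high-band
    # amplitude is modulated by its instantaneous (unit-variance) low-band
    # waveform, so high-band bursts lock to low-band peaks; with spatially
    # shared low-band sources this induces low-high dependence across
    # sensor pairs that the histogram-MI estimator detects
    for (p in xf_pairs) {
      lo <- y[[p$lo]]
      z <- lo / rep(pmax(1e-12, sqrt(colMeans(lo^2))), each = n_samp)
      y[[p$hi]] <- y[[p$hi]] * pmax(0.05, 1 + p$gain * z)
    }
    acc <- wn
    for (f in band_order)
      acc <- acc + sharpen_envelope(y[[f]], params$regularity[[f]])
    for (ti in seq_len(nc))
      data[, tn[ti], ] <- t(acc[, (ti - 1) * N + seq_len(N), drop = FALSE])
  }
  epoched_recording(subject_id, group, data, rate)
}

#' Generate a seeded two-group cohort
#'
#' @param config `cohort_config`.
#' @param layout optional `sensor_layout`; generated from the master seed if
#'   omitted.
#' @return `meg_cohort`: list with `recordings` (list of
#'   [epoched_recording()]), `layout`, and a `manifest` recording every
#'   parameter and derived per-subject seed.
#' @export
generate_cohort <- function(config, layout = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(layout)) layout <- generate_layout(config$n_sensors,
                                                 seed = config$master_seed)
  groups <- c("control", "patient")
  recordings <- list()
  seeds <- integer(0)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    par <- config[[g]]
    for (si in seq_len(config$n_subjects_per_group)) {
      sid <- sprintf("%s_%02d", ifelse(g == "control", "HC", "SZ"), si)
      sseed <- derive_seed(config$master_seed, gi, si)
      seeds[sid] <- sseed
      recordings[[sid]] <- generate_subject(par, config, layout, sseed,
                                            subject_id = sid, group = g)
    }
  }
  manifest <- list(
    config = unclass_config(config),
    subject_seeds = as.list(seeds),
    n_trials = config$n_blocks * config$sets_per_block,
    generated = TRUE
  )
  structure(list(recordings = recordings, layout = layout,
                 manifest = manifest),
            class = "meg_cohort")
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$control <- unclass(out$control)
  out$patient <- unclass(out$patient)
  out
}

#' @export
print.meg_cohort <- function(x, ...) {
  groups <- vapply(x$recordings, function(r) r$group, "")
  cat(sprintf("<meg_cohort> %d recordings (%d control, %d patient), %d sensors\n",
              length(x$recordings), sum(groups == "control"),
              sum(groups == "patient"), nrow(x$layout)))
  invisible(x)
}

#' Save / load a cohort container
#'
#' The cohort is stored as a single RDS container; the layout and manifest
#' are additionally written alongside as CSV and JSON for interoperability.
#'
#' @param cohort `meg_cohort`.
#' @param path `.rds` path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "meg_cohort"))
  saveRDS(cohort, path)
  base <- sub("\\.rds$", "", path)
  write_layout_csv(cohort$layout, paste0(base, "_layout.csv"))
  jsonlite::write_json(cohort$manifest, paste0(base, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- readRDS(path)
  stopifnot(inherits(cohort, "meg_cohort"))
  cohort
}
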