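#' Wavelet filters for the maximal overlap discrete wavelet transform
#'
#' `"d4"` is the 4-tap Daubechies filter with two vanishing moments (the
#' default); `"db4"` is the 8-tap Daubechies filter with four vanishing
#' moments. Both are supported because "Daubechies 4" is used for either in
#' the literature.
#' @keywords internal
modwt_filters <- function(wavelet = c("d4", "db4")) {
  wavelet <- match.arg(wavelet)
  if (wavelet == "d4") {
    h <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
  } else {
    h <- c(0.230377813308855, 0.714846570552542, 0.630880767929590,
           -0.027983769416984, -0.187034811718881, 0.030841381835987,
           0.032883011666983, -0.010597401784997)
  }
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # quadrature mirror (high-pass)
  list(h = h / sqrt(2), g = g / sqrt(2), L = L)  # MODWT rescaling
}

# circular row shift: row t of result = row (t - k) mod n of x
circ_shift_rows <- function(x, k) {
  n <- nrow(x)
  k <- k %% n
  if (k == 0) return(x)
  x[c((n - k + 1):n, 1:(n - k)), , drop = FALSE]
}

# MODWT pyramid on the columns of a matrix; periodic (circular) boundary.
modwt_mat <- function(x, n_scales = 4, wavelet = c("d4", "db4")) {
  filt <- modwt_filters(match.arg(wavelet))
  n <- nrow(x)
  need <- (filt$L - 1) * 2^(n_scales - 1) + 1
  if (n < need)
    stop(sprintf("series too short for %d MODWT scales: need >= %d samples",
                 n_scales, need))
  V <- x
  details <- vector("list", n_scales)
  for (j in seq_len(n_scales)) {
    step <- 2^(j - 1)
    W <- matrix(0, n, ncol(x))
    Vn <- matrix(0, n, ncol(x))
    for (l in seq_len(filt$L) - 1) {
      shifted <- circ_shift_rows(V, l * step)
      W <- W + filt$g[l + 1] * shifted
      Vn <- Vn + filt$h[l + 1] * shifted
    }
    details[[j]] <- W
    V <- Vn
  }
  list(details = details, smooth = V)
}

#' Maximal overlap discrete wavelet transform of a single series
#'
#' Undecimated (MODWT) decomposition with periodic boundary handling: each
#' detail series has the same length as the input, and the energy identity
#' `sum_j ||W_j||^2 + ||V_J||^2 = ||x||^2` holds exactly.
#'
#' @param x numeric vector.
#' @param n_scales number of detail scales (default 4; at a 120 Hz sampling
#'   rate scale 1 covers 30–60 Hz (low gamma), scale 2 15–30 Hz (beta),
#'   scale 3 8–15 Hz (alpha), scale 4 4–8 Hz (theta)).
#' @param wavelet `"d4"` (4-tap, default) or `"db4"` (8-tap).
#' @return list with `details` (samples x n_scales matrix, scale j in column
#'   j) and `smooth` (the final scaling series).
#' @export
modwt_decompose <- function(x, n_scales = 4, wavelet = c("d4", "db4")) {
  stopifnot(is.numeric(x))
  out <- modwt_mat(matrix(x, ncol = 1), n_scales, match.arg(wavelet))
  details <- do.call(cbind, lapply(out$details, as.numeric))
  colnames(details) <- paste0("scale", seq_len(n_scales))
  list(details = details, smooth = as.numeric(out$smooth))
}

#' Resample an epoched recording to the analysis rate
#'
#' Anti-alias low-pass FIR filtering (61-tap windowed design with cutoff at
#' the target Nyquist frequency, zero phase, reflected edges) followed by
#' decimation. The target rate must divide the native rate; the identity
#' case returns the recording unchanged.
#'
#' @param recording an [epoched_recording()].
#' @param target_rate target sampling rate in Hz.
#' @return resampled `epoched_recording`.
#' @export
resample_to_analysis_rate <- function(recording, target_rate = 120) {
  stopifnot(inherits(recording, "epoched_recording"))
  native <- recording$sampling_rate
  if (target_rate == native) return(recording)
  q <- native / target_rate
  if (abs(q - round(q)) > 1e-9)
    stop("target_rate must divide the native sampling rate")
  q <- as.integer(round(q))
  d <- dim(recording$data)
  n_out <- d[3] / q
  if (abs(n_out - round(n_out)) > 1e-9)
    stop("resampled epoch length is not an integer number of samples")
  n_out <- as.integer(round(n_out))
  h <- signal::fir1(60, 1 / q)  # cutoff at target Nyquist
  half <- 30
  keep <- seq(1, d[3], by = q)
  out <- array(0, dim = c(d[1], d[2], n_out))
  for (t in seq_len(d[2])) {
    x <- t(recording$data[, t, , drop = TRUE])
    if (d[1] == 1) x <- matrix(recording$data[1, t, ], ncol = 1)
    padded <- rbind(x[half:1, , drop = FALSE], x,
                    x[d[3]:(d[3] - half + 1), , drop = FALSE])
    y <- stats::filter(padded, h, sides = 2)
    y <- y[(half + 1):(half + d[3]), , drop = FALSE]
    out[, t, ] <- t(y[keep, , drop = FALSE])
  }
  epoched_recording(recording$subject_id, recording$group, out, target_rate)
}

#' Cut a continuous multichannel record into epochs
#'
#' Half-open windows `[onset, onset + duration * rate)`; onsets are 0-based
#' sample offsets into the record, and trials are ordered by onset.
#'
#' @param continuous numeric matrix, sensors x time.
#' @param onsets integer vector of 0-based onset samples.
#' @param duration epoch duration in seconds.
#' @param rate sampling rate in Hz.
#' @param subject_id,group labels for the resulting recording.
#' @return `epoched_recording` with one trial per onset.
#' @export
epoch_recording <- function(continuous, onsets, duration, rate,
                            subject_id = "S1", group = "control") {
  stopifnot(is.matrix(continuous), is.numeric(onsets))
  n <- round(duration * rate)
  if (abs(duration * rate - n) > 1e-9)
    stop("duration * rate must be an integer number of samples")
  onsets <- sort(onsets)
  if (any(onsets < 0) || any(onsets + n > ncol(continuous)))
    stop("onset window extends beyond the record")
  data <- array(0, dim = c(nrow(continuous), length(onsets), n))
  for (t in seq_along(onsets)) {
    idx <- (onsets[t] + 1):(onsets[t] + n)
    data[, t, ] <- continuous[, idx, drop = FALSE]
  }
  epoched_recording(subject_id, group, data, rate)
}

#' Decompose an epoched recording into the four wavelet scale bands
#'
#' Applies the MODWT per sensor and trial and returns the detail series of
#' scales 1–4 as the low-gamma, beta, alpha and theta bands (band labels
#' assume a 120 Hz sampling rate).
#'
#' @param recording `epoched_recording` (typically at 120 Hz).
#' @param wavelet `"d4"` or `"db4"`.
#' @return `band_decomposition`: list with `bands` (named list of
#'   sensors x trials x samples arrays), `sampling_rate`, `subject_id`,
#'   `group`.
#' @export
decompose_bands <- function(recording, wavelet = c("d4", "db4")) {
  stopifnot(inherits(recording, "epoched_recording"))
  wavelet <- match.arg(wavelet)
  d <- dim(recording$data)
  bands <- lapply(BAND_NAMES, function(b) array(0, dim = d))
  names(bands) <- BAND_NAMES
  for (t in seq_len(d[2])) {
    x <- t(matrix(recording$data[, t, ], nrow = d[1]))  # samples x sensors
    out <- modwt_mat(x, n_scales = 4, wavelet = wavelet)
    for (j in 1:4) bands[[BAND_NAMES[j]]][, t, ] <- t(out$details[[j]])
  }
  structure(list(bands = bands, sampling_rate = recording$sampling_rate,
                 subject_id = recording$subject_id, group = recording$group),
            class = "band_decomposition")
}
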