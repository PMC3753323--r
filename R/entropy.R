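#' Shannon wavelet entropy of a band-limited series
#'
#' Entropy (bits) of the normalized wavelet-energy distribution over time
#' points within a trial: `p_k = w_k^2 / sum(w^2)`,
#' `H = -sum p_k log2 p_k` with `0 log 0 = 0`. Bounded by
#' `0 <= H <= log2(length(x))`, with the maximum attained by a
#' constant-magnitude series and 0 by a single nonzero sample. Invariant
#' under scaling of the series.
#'
#' @param x numeric vector of wavelet detail coefficients for one sensor,
#'   band and trial.
#' @param normalized divide by `log2(length(x))` (default `FALSE`).
#' @return entropy in bits (or normalized units).
#' @export
wavelet_entropy <- function(x, normalized = FALSE) {
  stopifnot(is.numeric(x), length(x) > 0)
  e <- x^2
  tot <- sum(e)
  if (!is.finite(tot) || tot <= 0)
    stop("undefined entropy: series is all zero")
  p <- e / tot
  p <- p[p > 0]
  h <- -sum(p * log2(p))
  if (normalized) h <- h / log2(length(x))
  h
}

# Amplitude-histogram Shannon entropy (alternative estimator, selectable):
# entropy of the equal-width histogram of coefficient amplitudes.
histogram_entropy <- function(x, n_bins = 8) {
  stopifnot(length(x) > 1)
  r <- range(x)
  if (r[1] == r[2]) return(0)
  idx <- bin_indices(x, n_bins, "width")
  cnt <- tabulate(idx + 1L, nbins = n_bins)
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log2(p))
}

#' Entropy profile of a band decomposition
#'
#' Computes the wavelet entropy for every sensor, band and trial, plus
#' per-band subject means over sensors and trials.
#'
#' @param decomposition a [decompose_bands()] result.
#' @param estimator `"energy"` (time-point relative wavelet energy, default)
#'   or `"histogram"` (amplitude histogram).
#' @param normalized normalize by `log2(samples)`.
#' @return `entropy_profile`: list with `values` (sensors x bands x trials
#'   array) and `band_means` (named per-band means).
#' @export
entropy_profile <- function(decomposition, estimator = c("energy", "histogram"),
                            normalized = FALSE) {
  stopifnot(inherits(decomposition, "band_decomposition"))
  estimator <- match.arg(estimator)
  if (!all(BAND_NAMES %in% names(decomposition$bands)))
    stop("decomposition is missing one or more bands")
  d <- dim(decomposition$bands[[1]])
  values <- array(NA_real_, dim = c(d[1], length(BAND_NAMES), d[2]),
                  dimnames = list(NULL, BAND_NAMES, NULL))
  for (b in seq_along(BAND_NAMES)) {
    arr <- decomposition$bands[[BAND_NAMES[b]]]
    for (t in seq_len(d[2])) {
      for (s in seq_len(d[1])) {
        x <- arr[s, t, ]
        values[s, b, t] <- if (estimator == "energy")
          wavelet_entropy(x, normalized) else histogram_entropy(x)
      }
    }
  }
  band_means <- apply(values, 2, mean)
  structure(list(values = values, band_means = band_means,
                 subject_id = decomposition$subject_id,
                 group = decomposition$group),
            class = "entropy_profile")
}
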