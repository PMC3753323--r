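# Equal-width (default) or quantile bin assignment, 0-based indices.
bin_indices <- function(x, n_bins, binning = c("width", "quantile")) {
  binning <- match.arg(binning)
  if (binning == "width") {
    r <- range(x)
    if (r[1] == r[2]) return(integer(length(x)))
    idx <- floor((x - r[1]) / (r[2] - r[1]) * n_bins)
    idx[idx == n_bins] <- n_bins - 1L
  } else {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    idx <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE) - 1L
  }
  as.integer(idx)
}

plugin_entropy_bits <- function(idx, n_bins) {
  cnt <- tabulate(idx + 1L, nbins = n_bins)
  p <- cnt[cnt > 0] / length(idx)
  -sum(p * log2(p))
}

#' Histogram (plug-in) mutual information between two series
#'
#' Equal-width binning over each series' observed range (quantile binning
#' optional), plug-in entropies in bits, and
#' `I = H(x) + H(y) - H(x, y)` clipped at zero. A constant series has zero
#' marginal entropy; MI is then 0 and flagged.
#'
#' @param x,y numeric vectors of equal length (>= 32).
#' @param n_bins number of bins per axis (default 8, suited to 216-sample
#'   epochs).
#' @param binning `"width"` (default) or `"quantile"`.
#' @return list with `mi`, `hx`, `hy` (bits) and `degenerate` flag.
#' @export
histogram_mi <- function(x, y, n_bins = 8, binning = c("width", "quantile")) {
  binning <- match.arg(binning)
  stopifnot(length(x) == length(y), length(x) >= 32)
  ix <- bin_indices(x, n_bins, binning)
  iy <- bin_indices(y, n_bins, binning)
  hx <- plugin_entropy_bits(ix, n_bins)
  hy <- plugin_entropy_bits(iy, n_bins)
  degenerate <- (hx == 0 || hy == 0)
  if (degenerate) {
    warning("constant series: mutual information defined as 0")
    return(list(mi = 0, hx = hx, hy = hy, degenerate = TRUE))
  }
  hxy <- plugin_entropy_bits(ix * n_bins + iy, n_bins^2)
  mi <- max(0, hx + hy - hxy)
  list(mi = mi, hx = hx, hy = hy, degenerate = FALSE)
}

#' Normalized mutual information (Strehl–Ghosh)
#'
#' `NMI = I(x; y) / sqrt(H(x) H(y))`, clipped into `[0, 1]`; defined as 0
#' when either marginal entropy is 0.
#'
#' @inheritParams histogram_mi
#' @return NMI in `[0, 1]`.
#' @export
normalized_mi <- function(x, y, n_bins = 8, binning = c("width", "quantile")) {
  est <- histogram_mi(x, y, n_bins, binning)
  if (est$degenerate) return(0)
  min(1, est$mi / sqrt(est$hx * est$hy))
}

new_connectivity_matrix <- function(weights, kind, trial, sensors = NULL,
                                    raw = NULL) {
  dimnames(weights) <- list(sensors, sensors)
  structure(weights, kind = kind, trial = trial, raw = raw,
            class = c("connectivity_matrix", "matrix"))
}

# binned series for one band / trial: samples x sensors integer matrix
band_bins <- function(decomposition, band, trial, n_bins, binning) {
  arr <- decomposition$bands[[band]]
  x <- t(matrix(arr[, trial, ], nrow = dim(arr)[1]))
  if (binning == "width") return(cpp_bin_columns(x, as.integer(n_bins)))
  apply(x, 2, bin_indices, n_bins = n_bins, binning = binning)
}

#' Intra-frequency connectivity matrix
#'
#' Sensor-by-sensor normalized mutual information between the wavelet series
#' of one band within one trial: symmetric, zero diagonal, entries in
#' `[0, 1]`.
#'
#' @param decomposition a [decompose_bands()] result.
#' @param band one of `"gamma_low"`, `"beta"`, `"alpha"`, `"theta"`.
#' @param trial trial index.
#' @param n_bins,binning histogram estimator settings.
#' @return `connectivity_matrix` with attributes `kind` and `trial`.
#' @export
build_intra_matrix <- function(decomposition, band, trial, n_bins = 8,
                               binning = c("width", "quantile")) {
  stopifnot(inherits(decomposition, "band_decomposition"))
  band <- match.arg(band, BAND_NAMES)
  binning <- match.arg(binning)
  B <- band_bins(decomposition, band, trial, n_bins, binning)
  if (ncol(B) < 8) stop("need at least 8 sensors")
  W <- cpp_nmi_allpairs(B, as.integer(n_bins))
  new_connectivity_matrix(W, kind = band, trial = trial)
}

#' Inter-frequency connectivity matrix
#'
#' Raw entry `(i, j)` is the NMI between sensor `i` in band `f1` and sensor
#' `j` in band `f2`. Because this raw matrix is asymmetric, the stored
#' weights are the arithmetic mean of the raw matrix and its transpose with
#' the diagonal (same-sensor cross-band coupling) zeroed; the raw matrix is
#' retained as an attribute.
#'
#' @inheritParams build_intra_matrix
#' @param f1,f2 distinct band names.
#' @param symmetrize if `FALSE`, the raw asymmetric matrix is stored (with
#'   zero diagonal).
#' @return `connectivity_matrix` with attributes `kind`, `trial`, `raw`.
#' @export
build_inter_matrix <- function(decomposition, f1, f2, trial, n_bins = 8,
                               binning = c("width", "quantile"),
                               symmetrize = TRUE) {
  stopifnot(inherits(decomposition, "band_decomposition"))
  f1 <- match.arg(f1, BAND_NAMES)
  f2 <- match.arg(f2, BAND_NAMES)
  if (f1 == f2) stop("f1 and f2 must differ; use build_intra_matrix")
  binning <- match.arg(binning)
  B1 <- band_bins(decomposition, f1, trial, n_bins, binning)
  B2 <- band_bins(decomposition, f2, trial, n_bins, binning)
  raw <- cpp_nmi_cross(B1, B2, as.integer(n_bins))
  W <- if (symmetrize) (raw + t(raw)) / 2 else raw
  diag(W) <- 0
  new_connectivity_matrix(W, kind = paste(f1, f2, sep = "_"), trial = trial,
                          raw = raw)
}

#' The ten intra- and inter-frequency network kinds
#'
#' Four intra-frequency bands plus the six unordered band pairs, in a fixed
#' canonical order.
#' @return character vector of length 10.
#' @export
network_kinds <- function() {
  pairs <- utils::combn(BAND_NAMES, 2, paste, collapse = "_")
  c(BAND_NAMES, pairs)
}

#' All connectivity matrices for one trial
#'
#' @inheritParams build_intra_matrix
#' @param symmetrize symmetrization of inter-frequency matrices.
#' @return named list of 10 `connectivity_matrix` objects (4 intra + 6
#'   inter).
#' @export
connectivity_stack <- function(decomposition, trial, n_bins = 8,
                               binning = c("width", "quantile"),
                               symmetrize = TRUE) {
  stopifnot(inherits(decomposition, "band_decomposition"))
  binning <- match.arg(binning)
  kinds <- network_kinds()
  out <- vector("list", length(kinds))
  names(out) <- kinds
  bins <- lapply(BAND_NAMES, function(b)
    band_bins(decomposition, b, trial, n_bins, binning))
  names(bins) <- BAND_NAMES
  for (b in BAND_NAMES) {
    W <- cpp_nmi_allpairs(bins[[b]], as.integer(n_bins))
    out[[b]] <- new_connectivity_matrix(W, kind = b, trial = trial)
  }
  for (pair in utils::combn(BAND_NAMES, 2, simplify = FALSE)) {
    nm <- paste(pair, collapse = "_")
    raw <- cpp_nmi_cross(bins[[pair[1]]], bins[[pair[2]]], as.integer(n_bins))
    W <- if (symmetrize) (raw + t(raw)) / 2 else raw
    diag(W) <- 0
    out[[nm]] <- new_connectivity_matrix(W, kind = nm, trial = trial,
                                         raw = raw)
  }
  out
}

#' Sensor and network strength of a connectivity matrix
#'
#' Sensor strength is the mean weight between a sensor and all others;
#' network strength is the mean sensor strength.
#'
#' @param W square symmetric weight matrix (zero diagonal).
#' @return list with `sensor_strength` (length N) and `network_strength`.
#' @export
strength <- function(W) {
  W <- unclass(W)
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  n <- nrow(W)
  if (n < 2) stop("strength needs at least 2 sensors")
  ss <- rowSums(W) / (n - 1)
  list(sensor_strength = as.numeric(ss), network_strength = mean(ss))
}
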