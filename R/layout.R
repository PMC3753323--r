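#' Generate a quasi-uniform hemispherical sensor layout
#'
#' Places `n_sensors` points quasi-uniformly on a hemispherical cap of unit
#' radius (a stand-in for a whole-head sensor array). Points follow a
#' Fibonacci lattice on the upper hemisphere; the seed rotates the lattice
#' about the vertical axis so that distinct seeds give distinct but equally
#' uniform layouts.
#'
#' @param n_sensors number of sensors (at least 8).
#' @param seed integer seed; the layout is deterministic given the seed.
#' @return A `sensor_layout`: data frame with columns `sensor`, `x`, `y`, `z`
#'   (unit-radius coordinates, `z >= 0`).
#' @export
generate_layout <- function(n_sensors, seed = 1L) {
  if (!is.numeric(n_sensors) || length(n_sensors) != 1 || n_sensors < 8)
    stop("n_sensors must be a single number >= 8")
  n <- as.integer(n_sensors)
  set.seed(as.integer(seed))
  phase <- runif(1, 0, 2 * pi)
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n) - 0.5
  # map to upper hemisphere: z in (0, 1)
  z <- i / n
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- golden * (seq_len(n) - 1) + phase
  out <- data.frame(
    sensor = sprintf("S%03d", seq_len(n)),
    x = r * cos(theta),
    y = r * sin(theta),
    z = z,
    stringsAsFactors = FALSE
  )
  stopifnot(all(is.finite(as.matrix(out[, c("x", "y", "z")]))))
  class(out) <- c("sensor_layout", "data.frame")
  out
}

#' Sensor coordinate matrix of a layout
#' @param layout a `sensor_layout`.
#' @return numeric matrix (sensors x 3) with sensor names as row names.
#' @export
layout_coords <- function(layout) {
  m <- as.matrix(layout[, c("x", "y", "z")])
  rownames(m) <- layout$sensor
  m
}

#' Pairwise Euclidean distances between sensors
#' @param layout a `sensor_layout`.
#' @return symmetric distance matrix.
#' @export
layout_distances <- function(layout) {
  as.matrix(stats::dist(layout_coords(layout)))
}

#' Write / read a sensor layout as CSV (columns sensor, x, y, z)
#' @param layout a `sensor_layout`.
#' @param path file path.
#' @export
write_layout_csv <- function(layout, path) {
  write.csv(as.data.frame(layout), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout_csv
#' @export
read_layout_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sensor", "x", "y", "z") %in% names(out)))
  class(out) <- c("sensor_layout", "data.frame")
  out
}
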