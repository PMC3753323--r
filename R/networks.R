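edge_order_upper <- function(W) {
  n <- nrow(W)
  iu <- which(upper.tri(W))
  rows <- ((iu - 1) %% n) + 1
  cols <- ((iu - 1) %/% n) + 1
  w <- W[iu]
  ord <- order(-w, rows, cols)  # weight desc, ties lexicographic (i, j)
  list(rows = rows[ord], cols = cols[ord], n = n, m = length(iu))
}

new_binary_network <- function(A, cost) {
  structure(A, cost = cost, class = c("binary_network", "matrix"))
}

#' Cumulative thresholding of a weighted matrix
#'
#' Retains the `floor(kappa * N(N-1)/2)` strongest off-diagonal weights as
#' edges of a binary graph. Ties are broken deterministically in
#' lexicographic `(i, j)` order. Multiplying the weights by any positive
#' constant leaves the result unchanged, so fixed-density comparisons are
#' blind to overall strength differences.
#'
#' @param W square symmetric weight matrix.
#' @param kappa target density in `[0, 1]`.
#' @return `binary_network`: 0/1 adjacency matrix with attribute `cost`.
#' @export
cumulative_threshold <- function(W, kappa) {
  W <- unclass(W)
  stopifnot(is.matrix(W), nrow(W) == ncol(W), kappa >= 0, kappa <= 1)
  eo <- edge_order_upper(W)
  k <- floor(kappa * eo$m + 1e-9)
  A <- matrix(0L, eo$n, eo$n)
  if (k > 0) {
    sel <- seq_len(min(k, eo$m))
    A[cbind(eo$rows[sel], eo$cols[sel])] <- 1L
    A[cbind(eo$cols[sel], eo$rows[sel])] <- 1L
  }
  new_binary_network(A, kappa)
}

#' Standard network-density grid
#'
#' Densities 0.01 to 0.50 in steps of 0.01 (50 values); density 0 (the empty
#' graph) is excluded from diagnostic computation.
#' @export
default_kappa_grid <- function() seq(0.01, 0.50, by = 0.01)

#' Nested binary networks over a density sweep
#'
#' Thresholds one weighted matrix at every density of the grid. All networks
#' share a single edge ranking, so edge sets are nested along the grid and
#' the realized density is within one edge of the target.
#'
#' @param W square symmetric weight matrix.
#' @param kappas increasing density grid (default [default_kappa_grid()]).
#' @return `network_ensemble`: list of `binary_network`s with the grid as
#'   attribute `kappas`.
#' @export
threshold_sweep <- function(W, kappas = default_kappa_grid()) {
  stopifnot(!is.unsorted(kappas))
  nets <- lapply(kappas, function(k) cumulative_threshold(W, k))
  structure(nets, kappas = kappas, class = "network_ensemble")
}

#' Erdős–Rényi random-graph ensemble at fixed density
#'
#' `G(n, M)` graphs with exactly `M = floor(kappa * n(n-1)/2)` edges chosen
#' uniformly at random; deterministic given the seed. Used as the benchmark
#' null against which empirical diagnostic curves are compared.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param kappa density.
#' @param n_graphs ensemble size (default 66, matching the per-subject trial
#'   count).
#' @param seed integer seed.
#' @return list of `binary_network`s.
#' @export
er_random_graphs <- function(n_nodes, kappa, n_graphs = 66, seed = 1L) {
  stopifnot(n_nodes >= 2)
  m_possible <- n_nodes * (n_nodes - 1) / 2
  m <- floor(kappa * m_possible + 1e-9)
  iu <- which(upper.tri(matrix(0, n_nodes, n_nodes)))
  set.seed(as.integer(seed))
  lapply(seq_len(n_graphs), function(g) {
    A <- matrix(0L, n_nodes, n_nodes)
    if (m > 0) {
      sel <- sample(iu, m)
      A[sel] <- 1L
      A <- A + t(A)
    }
    new_binary_network(A, kappa)
  })
}
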