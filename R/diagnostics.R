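as_adj_int <- function(A) {
  A <- unclass(A)
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  storage.mode(A) <- "integer"
  diag(A) <- 0L
  A
}

#' Basic binary-graph diagnostics
#'
#' Path length (mean shortest-path length over connected ordered pairs),
#' mean local clustering (0 for nodes of degree < 2), global efficiency
#' (mean of `1/d` over all pairs, 0 for disconnected pairs), local
#' efficiency (mean nodal efficiency of neighborhood subgraphs), mean
#' normalized betweenness centrality, and degree assortativity (Pearson
#' degree–degree correlation over edges; `NA` with a flag when the degree
#' variance is zero, e.g. regular graphs).
#'
#' @param A binary adjacency matrix (symmetric, zero diagonal, >= 1 edge).
#' @return named list: `path_length`, `clustering`, `global_efficiency`,
#'   `local_efficiency`, `betweenness`, `assortativity`, `connected` flag,
#'   and per-node `betweenness_nodes` / `clustering_nodes`.
#' @export
basic_metrics <- function(A) {
  A <- as_adj_int(A)
  if (sum(A) == 0) stop("graph has no edges")
  cpp_basic_metrics(A)
}

#' Modularity by greedy agglomeration
#'
#' Newman modularity `Q = sum_c (e_c/m - (d_c/2m)^2)` of the best partition
#' found by greedy agglomerative merging with seeded random tie-breaking
#' restarts (restart 1 is deterministic).
#'
#' @param A binary adjacency matrix.
#' @param restarts number of restarts (default 10).
#' @param seed integer seed for tie-breaking.
#' @return best modularity found, or `NA` for an empty graph.
#' @export
modularity_greedy <- function(A, restarts = 10, seed = 1L) {
  A <- as_adj_int(A)
  if (sum(A) == 0) return(NA_real_)
  cpp_modularity(A, as.integer(restarts), as.integer(seed))
}

#' Hierarchy exponent
#'
#' Negative slope of the least-squares fit of `log C(k)` against `log k`
#' over degree classes with `k >= 2` and positive mean clustering. `NA` when
#' fewer than two usable degree classes exist (e.g. regular graphs).
#'
#' @param A binary adjacency matrix.
#' @return hierarchy exponent beta, or `NA`.
#' @export
hierarchy_exponent <- function(A) {
  cpp_hierarchy(as_adj_int(A))
}

#' Synchronizability
#'
#' Eigenratio `lambda_2 / lambda_max` of the combinatorial Laplacian of the
#' largest connected component (higher = more synchronizable; always in
#' `(0, 1]`). The reciprocal eigenratio convention is available via
#' `reciprocal = TRUE`. `NA` when the largest component has fewer than 3
#' nodes.
#'
#' @param A binary adjacency matrix.
#' @param reciprocal return `lambda_max / lambda_2` instead.
#' @return spectral ratio, or `NA`.
#' @export
synchronizability <- function(A, reciprocal = FALSE) {
  s <- cpp_synchronizability(as_adj_int(A))
  if (reciprocal && !is.na(s)) 1 / s else s
}

#' Robustness to node attack
#'
#' Nodes are removed one at a time (targeted: highest current degree, ties
#' by lowest index; random: uniform order, averaged over `n_orders` seeded
#' orders). Before each removal the size of the largest connected component
#' is recorded as a fraction of the original node count; the robustness is
#' the mean of this curve over the N removal steps (AUC in `[0, 1]`).
#'
#' @param A binary adjacency matrix (>= 2 nodes).
#' @param mode `"targeted"` or `"random"`.
#' @param n_orders random orders to average (default 20).
#' @param seed integer seed.
#' @return attack-robustness AUC.
#' @export
robustness <- function(A, mode = c("targeted", "random"), n_orders = 20,
                       seed = 1L) {
  mode <- match.arg(mode)
  cpp_robustness(as_adj_int(A), mode == "targeted", as.integer(n_orders),
                 as.integer(seed))
}

#' Mean connection distance
#'
#' Mean Euclidean distance between the endpoints of all edges, in the
#' layout's length units.
#'
#' @param A binary adjacency matrix with >= 1 edge.
#' @param layout `sensor_layout` covering all nodes.
#' @return mean connection distance.
#' @export
mean_connection_distance <- function(A, layout) {
  A <- as_adj_int(A)
  co <- layout_coords(layout)
  if (nrow(co) != nrow(A)) stop("layout does not cover all nodes")
  if (any(!is.finite(co))) stop("layout has missing coordinates")
  if (sum(A) == 0) stop("graph has no edges")
  cpp_mean_connection_distance(A, co)
}

#' Rent's exponent of a spatially embedded network
#'
#' Physical Rentian scaling: random axis-aligned boxes are sampled inside
#' the layout's bounding volume; for each box with `2 <= n <= N/2` enclosed
#' nodes and at least one boundary-crossing edge, `log(edges crossing)` is
#' regressed on `log(nodes inside)`. The slope is the Rent exponent. `NA`
#' when fewer than 30 usable boxes are found.
#'
#' @param A binary adjacency matrix (>= 8 nodes and >= 8 edges).
#' @param layout `sensor_layout` (boxes are sampled in the layout's native
#'   dimensionality).
#' @param n_boxes number of sampled boxes (default 5000).
#' @param seed integer seed.
#' @return Rent exponent, or `NA`.
#' @export
rent_exponent <- function(A, layout, n_boxes = 5000, seed = 1L) {
  A <- as_adj_int(A)
  co <- layout_coords(layout)
  if (nrow(co) != nrow(A)) stop("layout does not cover all nodes")
  cpp_rent(A, co, as.integer(n_boxes), as.integer(seed))
}

#' Cost-efficiency of a global-efficiency curve
#'
#' `CE = max over the grid of (E_glob(kappa) - kappa)`, with the smallest
#' maximizing density reported on ties.
#'
#' @param e_glob global-efficiency values over the density grid (may contain
#'   `NA`).
#' @param kappas the density grid.
#' @return list with `ce` and `kappa_star` (`NA` if the curve is all
#'   missing).
#' @export
cost_efficiency <- function(e_glob, kappas) {
  stopifnot(length(e_glob) == length(kappas))
  d <- e_glob - kappas
  ok <- which(is.finite(d))
  if (!length(ok)) return(list(ce = NA_real_, kappa_star = NA_real_))
  top <- max(d[ok])
  cand <- ok[d[ok] >= top - 1e-12]  # ties (to rounding) -> smallest kappa
  best <- cand[which.min(kappas[cand])]
  list(ce = d[best], kappa_star = kappas[best])
}

#' Diagnostic-versus-cost curves for one weighted matrix
#'
#' Thresholds the matrix over the density grid and evaluates all 13
#' diagnostics (the 12 grid diagnostics plus path length) at every density.
#' Densities at which a diagnostic is undefined are reported as `NA`, never
#' zero.
#'
#' @param W weighted connectivity matrix.
#' @param layout optional `sensor_layout`; without it the two physical
#'   diagnostics (mean connection distance, Rent exponent) are `NA`.
#' @param kappas density grid (default [default_kappa_grid()]).
#' @param mod_restarts,rand_orders,rent_boxes diagnostic settings (see
#'   [modularity_greedy()], [robustness()], [rent_exponent()]).
#' @param seed integer seed for the seeded diagnostics.
#' @param box_cache optional pre-sampled Rent box set from
#'   [make_rent_box_cache()]; box membership depends only on the layout, so
#'   one cache serves every matrix analyzed against it.
#' @return matrix (length(kappas) x 13) with diagnostics in columns.
#' @export
diagnostic_sweep <- function(W, layout = NULL, kappas = default_kappa_grid(),
                             mod_restarts = 10, rand_orders = 20,
                             rent_boxes = 5000, seed = 1L,
                             box_cache = NULL) {
  W <- unclass(W)
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  do_phys <- !is.null(layout)
  co <- if (do_phys) layout_coords(layout) else matrix(0, nrow(W), 3)
  out <- cpp_diag_sweep(W, co, as.numeric(kappas), as.integer(mod_restarts),
                        as.integer(rand_orders), as.integer(rent_boxes),
                        as.integer(seed), do_phys, box_cache)
  colnames(out) <- DIAG_NAMES
  rownames(out) <- format(kappas)
  out
}

#' Trial-averaged diagnostic curves for an ensemble of weighted matrices
#'
#' Computes [diagnostic_sweep()] for each trial's weighted matrix and
#' averages per density over trials (missing values dropped pairwise), as
#' curves for one subject and network kind. Per-trial values are retained
#' for variability analysis.
#'
#' @param W_list list of weighted matrices (one per trial).
#' @inheritParams diagnostic_sweep
#' @return `diagnostic_curves`: list with `mean` (kappas x 13 matrix),
#'   `per_trial` (kappas x 13 x trials array) and `kappas`.
#' @export
diagnostic_curves <- function(W_list, layout = NULL,
                              kappas = default_kappa_grid(),
                              mod_restarts = 10, rand_orders = 20,
                              rent_boxes = 5000, seed = 1L) {
  stopifnot(is.list(W_list), length(W_list) >= 1)
  nt <- length(W_list)
  per_trial <- array(NA_real_,
                     dim = c(length(kappas), length(DIAG_NAMES), nt),
                     dimnames = list(format(kappas), DIAG_NAMES, NULL))
  for (t in seq_len(nt)) {
    per_trial[, , t] <- diagnostic_sweep(W_list[[t]], layout, kappas,
                                         mod_restarts, rand_orders,
                                         rent_boxes,
                                         seed = derive_seed(seed, t))
  }
  mean_mat <- apply(per_trial, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  structure(list(mean = mean_mat, per_trial = per_trial, kappas = kappas),
            class = "diagnostic_curves")
}

#' Diagnostic curves of an Erdős–Rényi null ensemble
#'
#' Generates a `G(n, M)` ensemble at every density of the grid and averages
#' each diagnostic over the ensemble, giving the random-graph reference
#' curve.
#'
#' @param n_nodes nodes.
#' @param layout optional layout for physical diagnostics.
#' @param kappas density grid.
#' @param n_graphs graphs per density (default 66).
#' @inheritParams diagnostic_sweep
#' @return matrix (length(kappas) x 13) of ensemble means.
#' @export
er_null_curves <- function(n_nodes, layout = NULL,
                           kappas = default_kappa_grid(), n_graphs = 66,
                           mod_restarts = 10, rand_orders = 20,
                           rent_boxes = 5000, seed = 1L) {
  do_phys <- !is.null(layout)
  co <- if (do_phys) layout_coords(layout) else matrix(0, n_nodes, 3)
  out <- matrix(NA_real_, length(kappas), length(DIAG_NAMES),
                dimnames = list(format(kappas), DIAG_NAMES))
  for (q in seq_along(kappas)) {
    graphs <- er_random_graphs(n_nodes, kappas[q], n_graphs,
                               seed = derive_seed(seed, q))
    vals <- matrix(NA_real_, n_graphs, length(DIAG_NAMES))
    for (g in seq_len(n_graphs)) {
      if (sum(graphs[[g]]) == 0) next
      vals[g, ] <- cpp_diag_sweep(matrix(as.numeric(graphs[[g]]), n_nodes),
                                  co, kappas[q], as.integer(mod_restarts),
                                  as.integer(rand_orders),
                                  as.integer(rent_boxes),
                                  derive_seed(seed, q, g), do_phys)[1, ]
    }
    out[q, ] <- apply(vals, 2, function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  }
  out
}

#' Pre-sample Rent's-exponent boxes for a layout
#'
#' Rentian scaling samples random boxes whose node membership depends only
#' on the sensor coordinates; pre-sampling them once avoids redundant work
#' when many matrices share a layout.
#'
#' @param layout `sensor_layout`.
#' @param n_boxes number of boxes.
#' @param seed integer seed.
#' @return opaque cache object for [diagnostic_sweep()].
#' @export
make_rent_box_cache <- function(layout, n_boxes = 5000, seed = 1L) {
  cpp_make_rent_boxes(layout_coords(layout), as.integer(n_boxes),
                      as.integer(seed))
}
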