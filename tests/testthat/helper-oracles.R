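# Brute-force reference implementations, independent of the package's
# compiled kernels. Used as oracles for the graph-diagnostic suite.

oracle_dists <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n))            # Floyd-Warshall
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_connected <- function(A) all(is.finite(oracle_dists(A)))

oracle_path_length <- function(A) {
  D <- oracle_dists(A)
  d <- D[row(D) != col(D)]
  d <- d[is.finite(d) & d > 0]
  if (!length(d)) NA_real_ else mean(d)
}

oracle_global_efficiency <- function(A) {
  D <- oracle_dists(A)
  inv <- 1 / D[row(D) != col(D)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

oracle_clustering_nodes <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / (k * (k - 1))
  })
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  vals <- sapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(A[nb, nb, drop = FALSE])
  })
  mean(vals)
}

# Betweenness by shortest-path counting from the distance matrix (dynamic
# programming over path concatenation, not Brandes accumulation).
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_dists(A)
  sigma <- matrix(0, n, n)  # number of shortest paths s -> t
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (d in sort(unique(D[s, is.finite(D[s, ]) & D[s, ] > 0]))) {
      for (t in which(D[s, ] == d)) {
        preds <- which(A[, t] == 1 & D[s, ] == d - 1)
        sigma[s, t] <- sum(sigma[s, preds])
      }
    }
  }
  cb <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s >= t || s == v || t == v) next
        if (!is.finite(D[s, t]) || sigma[s, t] == 0) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t])
          tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
    cb[v] <- tot
  }
  norm <- (n - 1) * (n - 2) / 2
  if (norm > 0) cb / norm else cb * 0
}

oracle_assortativity <- function(A) {
  deg <- rowSums(A)
  ij <- which(A == 1, arr.ind = TRUE)   # ordered edge endpoints
  x <- deg[ij[, 1]]
  y <- deg[ij[, 2]]
  if (var(x) < 1e-12) return(NA_real_)
  cov(x, y) * (length(x) - 1) / length(x) /
    (var(x) * (length(x) - 1) / length(x))
}

oracle_modularity_value <- function(A, membership) {
  m <- sum(A) / 2
  deg <- rowSums(A)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    q <- q + sum(A[idx, idx]) / 2 / m - (sum(deg[idx]) / (2 * m))^2
  }
  q
}

# All set partitions of n elements as restricted growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (v in seq_len(maxv + 1)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0)
  out
}

oracle_modularity_exhaustive <- function(A) {
  parts <- all_partitions(nrow(A))
  max(vapply(parts, function(p) oracle_modularity_value(A, p), numeric(1)))
}

# adjacency matrix from an edge-set bitmask over the upper triangle
graph_from_mask <- function(n, mask) {
  A <- matrix(0L, n, n)
  pairs <- which(upper.tri(A))
  sel <- pairs[bitwAnd(bitwShiftR(mask, seq_along(pairs) - 1L), 1L) == 1L]
  A[sel] <- 1L
  A + t(A)
}

random_connected_graph <- function(n, p = 0.35) {
  repeat {
    A <- matrix(0L, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
    A <- A + t(A)
    if (sum(A) > 0 && oracle_connected(A)) return(A)
  }
}

adjacency_to_igraph <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# ring / star / complete / path constructors
graph_cycle <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    A[i, j] <- 1L
    A[j, i] <- 1L
  }
  A
}
graph_complete <- function(n) {
  A <- matrix(1L, n, n)
  diag(A) <- 0L
  A
}
graph_star <- function(n) {
  A <- matrix(0L, n, n)
  A[1, 2:n] <- 1L
  A[2:n, 1] <- 1L
  A
}
graph_path <- function(n) {
  A <- matrix(0L, n, n)
  A[cbind(1:(n - 1), 2:n)] <- 1L
  A + t(A)
}

# entropy / MI oracles
oracle_entropy_bits <- function(x) {
  p <- x^2 / sum(x^2)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_mi_bits <- function(ix, iy) {
  tab <- table(ix, iy)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  h <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  h(px) + h(py) - h(as.numeric(p))
}

# direct-definition MODWT (nested loops over the pyramid)
oracle_modwt <- function(x, n_scales, wavelet = "d4") {
  filt <- megnets:::modwt_filters(wavelet)
  n <- length(x)
  V <- x
  details <- matrix(0, n, n_scales)
  for (j in seq_len(n_scales)) {
    step <- 2^(j - 1)
    W <- numeric(n)
    Vn <- numeric(n)
    for (t in seq_len(n)) {
      for (l in seq_len(filt$L) - 1) {
        idx <- ((t - 1 - l * step) %% n) + 1
        W[t] <- W[t] + filt$g[l + 1] * V[idx]
        Vn[t] <- Vn[t] + filt$h[l + 1] * V[idx]
      }
    }
    details[, j] <- W
    V <- Vn
  }
  list(details = details, smooth = V)
}
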