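#' Two-sample permutation test on means
#'
#' Statistic `|mean(a) - mean(b)|`; p-value by seeded label permutation with
#' the add-one convention `p = (1 + #{permuted >= observed}) / (n_perm + 1)`,
#' so the smallest attainable p is `1/(n_perm + 1)`.
#'
#' @param a,b numeric samples (each length >= 2).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return p-value in `(0, 1]`.
#' @export
permutation_test <- function(a, b, n_perm = 10000, seed = 1L) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  pooled <- c(a, b)
  if (max(pooled) == min(pooled)) return(1)
  obs <- abs(mean(a) - mean(b))
  # the permutation stream operates on the canonically sorted pool with
  # subset size min(|a|, |b|), so exchanging the two samples gives an
  # identical p-value under the same seed
  pooled <- sort(pooled)
  ns <- min(length(a), length(b))
  n <- length(pooled)
  tot <- sum(pooled)
  set.seed(as.integer(seed))
  count <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, ns)
    ma <- sum(pooled[idx]) / ns
    mb <- (tot - ma * ns) / (n - ns)
    if (abs(ma - mb) >= obs - 1e-12) count <- count + 1L
  }
  (1 + count) / (n_perm + 1)
}

#' Holm–Bonferroni step-down adjustment
#'
#' Adjusted p-values of the Holm step-down procedure (monotone, capped at
#' 1), returned in the original order.
#'
#' @param p p-values in `(0, 1]`.
#' @return adjusted p-values.
#' @export
holm_bonferroni <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "holm")
}

#' Benjamini–Hochberg discovery flags
#'
#' Standard step-up rule at level `q`, applied jointly over the whole input
#' (e.g. all 120 cells of a comparison grid).
#'
#' @param p p-values in `(0, 1]`.
#' @param q target false discovery rate (default 0.05).
#' @return logical discovery flags (empty input gives an empty vector).
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  if (!length(p)) return(logical(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH") <= q
}

#' Functional-data-analysis permutation test on curves
#'
#' Treats each subject's diagnostic-versus-density curve as the unit of
#' analysis. The statistic is the integrated absolute group-mean difference
#' over the grid (`sum_k |mean_A(k) - mean_B(k)|`; the supremum statistic is
#' available as an option); grid points missing in a group mean are dropped
#' pairwise. The p-value uses seeded label permutations with the add-one
#' convention.
#'
#' @param curves_a,curves_b numeric matrices, subjects x grid points.
#' @param n_perm number of permutations (default 20000).
#' @param seed integer seed.
#' @param statistic `"integrated"` (default) or `"sup"`.
#' @return p-value, or `NA` if the whole grid is missing.
#' @export
fda_permutation_test <- function(curves_a, curves_b, n_perm = 20000,
                                 seed = 1L, statistic = c("integrated", "sup")) {
  statistic <- match.arg(statistic)
  stopifnot(is.matrix(curves_a), is.matrix(curves_b),
            ncol(curves_a) == ncol(curves_b),
            nrow(curves_a) >= 2, nrow(curves_b) >= 2)
  all_curves <- rbind(curves_a, curves_b)
  na <- nrow(curves_a)
  n <- nrow(all_curves)
  stat_fun <- function(mat, ia) {
    ma <- colMeans(mat[ia, , drop = FALSE], na.rm = TRUE)
    mb <- colMeans(mat[-ia, , drop = FALSE], na.rm = TRUE)
    d <- abs(ma - mb)
    d <- d[is.finite(d)]
    if (!length(d)) return(NA_real_)
    if (statistic == "integrated") sum(d) else max(d)
  }
  obs <- stat_fun(all_curves, seq_len(na))
  if (is.na(obs)) return(NA_real_)
  # permute over the canonically ordered pool with subset size
  # min(nA, nB): exchanging the groups then gives an identical p-value
  # under the same seed (the statistic is partition-symmetric)
  key <- rowSums(all_curves, na.rm = TRUE)
  canon <- all_curves[do.call(order, c(list(key),
                                       as.data.frame(all_curves))), ,
                      drop = FALSE]
  ns <- min(na, n - na)
  set.seed(as.integer(seed))
  count <- 0L
  for (i in seq_len(n_perm)) {
    s <- stat_fun(canon, sample.int(n, ns))
    if (!is.na(s) && s >= obs - 1e-12) count <- count + 1L
  }
  (1 + count) / (n_perm + 1)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean;
#' scale-invariant and `NA` (flagged by a warning) when the mean is zero.
#'
#' @param x numeric values (length >= 2).
#' @return CV, or `NA` when the mean is 0.
#' @export
coefficient_of_variation <- function(x) {
  stopifnot(length(x) >= 2)
  m <- mean(x)
  if (!is.finite(m) || m == 0) {
    warning("zero mean: CV undefined")
    return(NA_real_)
  }
  sd(x) / m
}

#' Repeated-measures ANOVA of trial-to-trial variability
#'
#' Classical univariate sums-of-squares decomposition with one
#' between-subject factor (group) and two within-subject factors (network
#' kind and diagnostic), applied to cost-averaged CV values. Reports SSE,
#' DF, MSE, F and p per effect in the conventional layout (group; band;
#' diagnostic; band x diagnostic; band x group; diagnostic x group;
#' band x diagnostic x group). No sphericity correction is applied.
#'
#' @param cv_table data frame with columns `subject`, `group`, `band`
#'   (network kind), `diagnostic`, `cv`; must be a complete balanced design.
#' @return `anova_result`: data frame with one row per effect.
#' @export
rm_anova_cv <- function(cv_table) {
  req <- c("subject", "group", "band", "diagnostic", "cv")
  stopifnot(all(req %in% names(cv_table)))
  if (anyNA(cv_table$cv)) stop("missing CV cells: design must be complete")
  tab <- table(cv_table$subject, cv_table$band, cv_table$diagnostic)
  if (any(tab != 1)) stop("design must be balanced with one value per cell")
  d <- data.frame(
    subject = factor(cv_table$subject),
    group = factor(cv_table$group),
    band = factor(cv_table$band),
    diagnostic = factor(cv_table$diagnostic),
    cv = cv_table$cv
  )
  fit <- aov(cv ~ group * band * diagnostic +
               Error(subject / (band * diagnostic)), data = d)
  sm <- summary(fit)
  grab <- function(stratum, effect) {
    tb <- sm[[stratum]][[1]]
    row <- trimws(rownames(tb)) == effect
    if (!any(row)) stop("effect not found: ", effect)
    c(SSE = tb[row, "Sum Sq"], DF = tb[row, "Df"],
      MSE = tb[row, "Mean Sq"], F = tb[row, "F value"],
      p = tb[row, "Pr(>F)"])
  }
  rows <- rbind(
    Group = grab("Error: subject", "group"),
    `Frequency Band` = grab("Error: subject:band", "band"),
    Diagnostic = grab("Error: subject:diagnostic", "diagnostic"),
    `Frequency Band*Diagnostic` = grab("Error: subject:band:diagnostic",
                                       "band:diagnostic"),
    `Frequency Band*Group` = grab("Error: subject:band", "group:band"),
    `Diagnostic*Group` = grab("Error: subject:diagnostic", "group:diagnostic"),
    `Frequency Band*Diagnostic*Group` = grab("Error: subject:band:diagnostic",
                                             "group:band:diagnostic")
  )
  out <- data.frame(effect = rownames(rows), rows, row.names = NULL,
                    check.names = FALSE)
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Linear entropy–strength relationship
#'
#' Ordinary least squares of strength on entropy over units (subjects or
#' sensors), as fitted separately per group and band.
#'
#' @param entropy,strength numeric vectors (>= 3 points).
#' @return list with `slope`, `intercept`, `r_squared` (slope `NA` when the
#'   entropy variance is zero).
#' @export
entropy_strength_fit <- function(entropy, strength) {
  stopifnot(length(entropy) == length(strength), length(entropy) >= 3)
  if (var(entropy) < 1e-14)
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_))
  fit <- lm(strength ~ entropy)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}
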