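#' Analysis configuration for the full pipeline
#'
#' Single document from which every downstream stage parameter is reachable.
#' Defaults follow the standard protocol: 8-bin equal-width MI estimator,
#' energy-based wavelet entropy in bits, 4-tap Daubechies MODWT, density
#' grid 0.01–0.50 in steps of 0.01, 10000 / 20000 permutations for the
#' univariate / curve tests, FDR level `q = 0.05` and uncorrected
#' `alpha = 0.05`.
#'
#' @param cohort a [cohort_config()] (the cohort to simulate), or `NULL`
#'   when an existing cohort object is passed to [run_pipeline()].
#' @param n_bins,binning MI histogram settings.
#' @param entropy_estimator,entropy_normalized entropy settings.
#' @param wavelet `"d4"` or `"db4"`.
#' @param symmetrize symmetrize inter-frequency matrices.
#' @param kappas density grid.
#' @param n_perm_univariate,n_perm_fda permutation counts.
#' @param fda_statistic `"integrated"` or `"sup"`.
#' @param q,alpha FDR level and uncorrected significance level.
#' @param mod_restarts,rand_orders,rent_boxes diagnostic settings.
#' @param seed analysis seed (distinct from the cohort's master seed).
#' @return `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(), n_bins = 8,
                       binning = "width", entropy_estimator = "energy",
                       entropy_normalized = FALSE, wavelet = "d4",
                       symmetrize = TRUE, kappas = default_kappa_grid(),
                       n_perm_univariate = 10000, n_perm_fda = 20000,
                       fda_statistic = "integrated", q = 0.05, alpha = 0.05,
                       mod_restarts = 10, rand_orders = 20,
                       rent_boxes = 5000, seed = 1L) {
  cfg <- list(cohort = cohort, n_bins = n_bins, binning = binning,
              entropy_estimator = entropy_estimator,
              entropy_normalized = entropy_normalized, wavelet = wavelet,
              symmetrize = symmetrize, kappas = kappas,
              n_perm_univariate = n_perm_univariate, n_perm_fda = n_perm_fda,
              fda_statistic = fda_statistic, q = q, alpha = alpha,
              mod_restarts = mod_restarts, rand_orders = rand_orders,
              rent_boxes = rent_boxes, seed = as.integer(seed))
  stopifnot(is.null(cfg$cohort) || inherits(cfg$cohort, "cohort_config"),
            cfg$q > 0, cfg$q < 1, cfg$alpha > 0, cfg$alpha < 1,
            all(cfg$kappas > 0), all(cfg$kappas <= 1),
            !is.unsorted(cfg$kappas))
  structure(cfg, class = "run_config")
}

#' Load a run configuration from JSON
#'
#' Mirrors [run_config()]; unknown keys are rejected. The `cohort` entry may
#' contain `control` / `patient` objects mirroring [group_params()].
#'
#' @param path JSON file path.
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  extra <- setdiff(names(doc), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  if (!is.null(doc$cohort)) {
    ck <- names(formals(cohort_config))
    bad <- setdiff(names(doc$cohort), ck)
    if (length(bad)) stop("unknown cohort keys: ", paste(bad, collapse = ", "))
    co <- doc$cohort
    for (g in c("control", "patient")) {
      if (!is.null(co[[g]])) {
        gp <- co[[g]]
        co[[g]] <- group_params(
          coupling_scale = unlist(gp$coupling_scale),
          regularity = unlist(gp$regularity),
          xfreq_coupling = unlist(gp$xfreq_coupling),
          trial_jitter = gp$trial_jitter %||% 0.15,
          noise_sd = gp$noise_sd %||% 1.0
        )
      }
    }
    doc$cohort <- do.call(cohort_config, co)
  }
  do.call(run_config, doc)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(serialize_config(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

serialize_config <- function(config) {
  out <- unclass(config)
  if (!is.null(out$cohort)) out$cohort <- unclass_config(out$cohort)
  out
}

analyze_subject <- function(recording, layout, config, box_cache = NULL) {
  if (is.null(box_cache))
    box_cache <- make_rent_box_cache(layout, config$rent_boxes,
                                     derive_seed(config$seed, 99))
  rec <- resample_to_analysis_rate(recording,
                                   config$cohort$analysis_rate %||% 120)
  decomp <- decompose_bands(rec, wavelet = config$wavelet)
  ent <- entropy_profile(decomp, estimator = config$entropy_estimator,
                         normalized = config$entropy_normalized)
  n_trials <- dim(rec$data)[2]
  kinds <- network_kinds()
  nk <- length(config$kappas)
  per_trial <- array(NA_real_,
                     dim = c(nk, length(DIAG_NAMES), n_trials, length(kinds)),
                     dimnames = list(NULL, DIAG_NAMES, NULL, kinds))
  net_strength <- matrix(NA_real_, n_trials, length(kinds),
                         dimnames = list(NULL, kinds))
  sensor_strength_sum <- matrix(0, nrow(layout), length(kinds),
                                dimnames = list(NULL, kinds))
  co <- layout_coords(layout)
  for (t in seq_len(n_trials)) {
    mats <- connectivity_stack(decomp, t, n_bins = config$n_bins,
                               binning = config$binning,
                               symmetrize = config$symmetrize)
    for (k in seq_along(kinds)) {
      W <- mats[[kinds[k]]]
      st <- strength(W)
      net_strength[t, k] <- st$network_strength
      sensor_strength_sum[, k] <- sensor_strength_sum[, k] + st$sensor_strength
      per_trial[, , t, k] <- cpp_diag_sweep(
        unclass(W), co, config$kappas, as.integer(config$mod_restarts),
        as.integer(config$rand_orders), as.integer(config$rent_boxes),
        derive_seed(config$seed, t, k), TRUE, box_cache)
    }
  }
  curves_mean <- apply(per_trial, c(1, 2, 4), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  # cost-averaged CV over trials per kind x diagnostic
  cv <- matrix(NA_real_, length(kinds), length(DIAG_NAMES),
               dimnames = list(kinds, DIAG_NAMES))
  for (k in seq_along(kinds)) {
    for (dg in seq_along(DIAG_NAMES)) {
      vals <- per_trial[, dg, , k, drop = FALSE]
      dim(vals) <- c(nk, n_trials)
      cv_per_cost <- apply(vals, 1, function(v) {
        v <- v[is.finite(v)]
        if (length(v) < 2 || mean(v) == 0) return(NA_real_)
        sd(v) / mean(v)
      })
      cv[k, dg] <- if (all(is.na(cv_per_cost))) NA_real_ else
        mean(cv_per_cost, na.rm = TRUE)
    }
  }
  list(
    subject_id = rec$subject_id,
    group = rec$group,
    entropy_band_mean = apply(ent$values, 2, mean),       # per band
    entropy_sensor_band = apply(ent$values, c(1, 2), mean),  # sensors x bands
    net_strength_mean = colMeans(net_strength),           # per kind
    sensor_strength = sensor_strength_sum / n_trials,     # sensors x kinds
    curves_mean = curves_mean,                            # kappas x 13 x kinds
    cv = cv                                               # kinds x 13
  )
}

#' Run the full multiscale analysis pipeline
#'
#' Simulates (or accepts) a two-group cohort and executes every stage:
#' resampling to the analysis rate, MODWT band decomposition, wavelet
#' entropy, intra- and inter-frequency NMI connectivity and strength,
#' cumulative-threshold density sweeps with all graph diagnostics,
#' cost-efficiency, Erdős–Rényi null curves, group permutation tests with
#' Holm correction, the FDA curve-comparison grid with BH discovery flags,
#' trial-to-trial CV with a repeated-measures ANOVA, and entropy–strength
#' regressions. Fully deterministic given the config.
#'
#' @param config a [run_config()].
#' @param cohort optional pre-built [generate_cohort()] result; when `NULL`,
#'   the cohort in `config$cohort` is simulated.
#' @param verbose print per-stage progress.
#' @return `result_bundle` (see [write_report()]).
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  if (is.null(cohort)) {
    say("simulating cohort ...")
    cohort <- generate_cohort(config$cohort)
  }
  stopifnot(inherits(cohort, "meg_cohort"))
  layout <- cohort$layout
  kinds <- network_kinds()
  subjects <- names(cohort$recordings)
  res <- vector("list", length(subjects))
  names(res) <- subjects
  box_cache <- make_rent_box_cache(layout, config$rent_boxes,
                                   derive_seed(config$seed, 99))
  for (s in subjects) {
    say("analyzing subject %s ...", s)
    res[[s]] <- analyze_subject(cohort$recordings[[s]], layout, config,
                                box_cache)
  }
  groups <- vapply(res, function(r) r$group, "")
  is_a <- groups == "control"

  # ---- univariate group tests: entropy and intra-band strength ----------
  say("group tests ...")
  ent_mat <- t(vapply(res, function(r) r$entropy_band_mean,
                      numeric(length(BAND_NAMES))))
  str_mat <- t(vapply(res, function(r) r$net_strength_mean,
                      numeric(length(kinds))))
  colnames(str_mat) <- kinds
  univariate <- do.call(rbind, lapply(seq_along(BAND_NAMES), function(b) {
    band <- BAND_NAMES[b]
    pe <- permutation_test(ent_mat[is_a, b], ent_mat[!is_a, b],
                           n_perm = config$n_perm_univariate,
                           seed = derive_seed(config$seed, 1, b))
    ps <- permutation_test(str_mat[is_a, band], str_mat[!is_a, band],
                           n_perm = config$n_perm_univariate,
                           seed = derive_seed(config$seed, 2, b))
    data.frame(band = band,
               measure = c("entropy", "strength"),
               control_mean = c(mean(ent_mat[is_a, b]),
                                mean(str_mat[is_a, band])),
               patient_mean = c(mean(ent_mat[!is_a, b]),
                                mean(str_mat[!is_a, band])),
               p = c(pe, ps))
  }))
  univariate$p_holm <- NA_real_
  for (msr in c("entropy", "strength")) {
    i <- univariate$measure == msr
    univariate$p_holm[i] <- holm_bonferroni(univariate$p[i])
  }

  # ---- FDA grid over (kind x diagnostic) --------------------------------
  say("FDA curve tests ...")
  nk <- length(config$kappas)
  fda <- expand.grid(kind = kinds, diagnostic = GRID_DIAGNOSTICS,
                     stringsAsFactors = FALSE)
  fda$p <- NA_real_
  fda$direction <- NA_character_
  for (i in seq_len(nrow(fda))) {
    k <- fda$kind[i]
    dg <- fda$diagnostic[i]
    curves <- t(vapply(res, function(r) r$curves_mean[, dg, k], numeric(nk)))
    a <- curves[is_a, , drop = FALSE]
    b <- curves[!is_a, , drop = FALSE]
    fda$p[i] <- fda_permutation_test(
      a, b, n_perm = config$n_perm_fda,
      seed = derive_seed(config$seed, 3, i),
      statistic = config$fda_statistic)
    dmean <- mean(colMeans(b, na.rm = TRUE) - colMeans(a, na.rm = TRUE),
                  na.rm = TRUE)
    fda$direction[i] <- if (is.na(dmean)) NA_character_ else
      if (dmean > 0) "patient" else "control"
  }
  ok <- is.finite(fda$p)
  fda$fdr_flag <- FALSE
  fda$fdr_flag[ok] <- benjamini_hochberg(fda$p[ok], q = config$q)
  fda$uncorrected_flag <- ok & fda$p <= config$alpha

  # ---- CV table and RM-ANOVA -------------------------------------------
  say("variability ANOVA ...")
  cv_table <- do.call(rbind, lapply(subjects, function(s) {
    cv <- res[[s]]$cv[, CV_DIAGNOSTICS, drop = FALSE]
    data.frame(subject = s, group = res[[s]]$group,
               band = rep(rownames(cv), times = ncol(cv)),
               diagnostic = rep(colnames(cv), each = nrow(cv)),
               cv = as.numeric(cv))
  }))
  # diagnostics with any undefined cell are dropped (no imputation)
  anova_input <- cv_table
  bad_diag <- unique(anova_input$diagnostic[is.na(anova_input$cv)])
  if (length(bad_diag)) {
    warning("RM-ANOVA drops diagnostics with undefined CV cells: ",
            paste(bad_diag, collapse = ", "))
    anova_input <- anova_input[!anova_input$diagnostic %in% bad_diag, ]
  }
  anova_tab <- tryCatch(rm_anova_cv(anova_input), error = function(e) {
    warning("RM-ANOVA skipped: ", conditionMessage(e))
    NULL
  })

  # ---- cost-efficiency ---------------------------------------------------
  ce <- do.call(rbind, lapply(subjects, function(s) {
    do.call(rbind, lapply(kinds, function(k) {
      r <- cost_efficiency(res[[s]]$curves_mean[, "global_efficiency", k],
                           config$kappas)
      data.frame(subject = s, group = res[[s]]$group, kind = k,
                 cost_efficiency = r$ce, kappa_star = r$kappa_star)
    }))
  }))

  # ---- ER null curves ----------------------------------------------------
  say("ER null ensemble ...")
  er_curves <- er_null_curves(nrow(layout), layout, config$kappas,
                              n_graphs = dim(cohort$recordings[[1]]$data)[2],
                              mod_restarts = config$mod_restarts,
                              rand_orders = config$rand_orders,
                              rent_boxes = config$rent_boxes,
                              seed = derive_seed(config$seed, 4))
  er_ce <- cost_efficiency(er_curves[, "global_efficiency"], config$kappas)

  # ---- entropy-strength regressions -------------------------------------
  safe_fit <- function(e, s) {
    if (length(e) < 3)
      return(list(slope = NA_real_, intercept = NA_real_,
                  r_squared = NA_real_))
    entropy_strength_fit(e, s)
  }
  fits <- do.call(rbind, lapply(BAND_NAMES, function(band) {
    do.call(rbind, lapply(c("control", "patient"), function(g) {
      gi <- groups == g
      subj <- safe_fit(ent_mat[gi, match(band, BAND_NAMES)],
                       str_mat[gi, band])
      ent_sens <- Reduce(`+`, lapply(res[gi], function(r)
        r$entropy_sensor_band[, band])) / sum(gi)
      str_sens <- Reduce(`+`, lapply(res[gi], function(r)
        r$sensor_strength[, band])) / sum(gi)
      sens <- safe_fit(ent_sens, str_sens)
      data.frame(band = band, group = g,
                 level = c("subject", "sensor"),
                 slope = c(subj$slope, sens$slope),
                 intercept = c(subj$intercept, sens$intercept),
                 r_squared = c(subj$r_squared, sens$r_squared))
    }))
  }))

  manifest <- list(
    config_hash = config_hash(config),
    config = serialize_config(config),
    package_version = as.character(utils::packageVersion("megnets")),
    n_subjects = length(subjects),
    n_trials = dim(cohort$recordings[[1]]$data)[2],
    n_sensors = nrow(layout),
    n_kinds = length(kinds),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  structure(list(
    subjects = res, groups = groups, layout = layout,
    entropy = ent_mat, strength = str_mat,
    univariate = univariate, fda_grid = fda,
    cv_table = cv_table, anova = anova_tab,
    cost_efficiency = ce, er_curves = er_curves, er_cost_efficiency = er_ce,
    fits = fits, kappas = config$kappas, manifest = manifest
  ), class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf("<result_bundle> %d subjects, %d network kinds, %d densities\n",
              length(x$subjects), length(network_kinds()), length(x$kappas)))
  cat(sprintf("  FDA grid: %d p-values, %d FDR discoveries at q\n",
              nrow(x$fda_grid), sum(x$fda_grid$fdr_flag, na.rm = TRUE)))
  invisible(x)
}

#' Write a result bundle to disk
#'
#' Writes the tabular analogs of the analysis figures as CSV (entropy and
#' strength tables, diagnostic curves in long form, cost-efficiency,
#' p-value grid, CV table, ANOVA table, regression fits, ER null curves), a
#' JSON manifest, and, when ggplot2 is available, summary plots as PDF.
#'
#' @param bundle a `result_bundle`.
#' @param outdir output directory (created if needed).
#' @param plots also render PDF figures (requires ggplot2).
#' @return invisible vector of file paths written.
#' @export
write_report <- function(bundle, outdir, plots = FALSE) {
  stopifnot(inherits(bundle, "result_bundle"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(outdir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  subjects <- names(bundle$subjects)
  ent <- data.frame(subject = rep(subjects, each = length(BAND_NAMES)),
                    group = rep(bundle$groups, each = length(BAND_NAMES)),
                    band = rep(BAND_NAMES, times = length(subjects)),
                    entropy = as.numeric(t(bundle$entropy)))
  put(ent, "entropy_subject.csv")
  kinds <- network_kinds()
  str_df <- data.frame(subject = rep(subjects, each = length(kinds)),
                       group = rep(bundle$groups, each = length(kinds)),
                       kind = rep(kinds, times = length(subjects)),
                       strength = as.numeric(t(bundle$strength)))
  put(str_df, "strength_subject.csv")
  curves <- do.call(rbind, lapply(subjects, function(s) {
    cm <- bundle$subjects[[s]]$curves_mean
    do.call(rbind, lapply(kinds, function(k) {
      data.frame(subject = s, group = bundle$subjects[[s]]$group,
                 network_kind = k,
                 diagnostic = rep(DIAG_NAMES, each = length(bundle$kappas)),
                 cost = rep(bundle$kappas, times = length(DIAG_NAMES)),
                 value = as.numeric(cm[, , k]),
                 missing_flag = !is.finite(as.numeric(cm[, , k])))
    }))
  }))
  put(curves, "diagnostic_curves.csv")
  put(bundle$univariate, "univariate_tests.csv")
  put(bundle$fda_grid, "fda_grid.csv")
  put(bundle$cv_table, "cv_table.csv")
  if (!is.null(bundle$anova)) put(as.data.frame(bundle$anova), "anova.csv")
  put(bundle$cost_efficiency, "cost_efficiency.csv")
  put(bundle$fits, "entropy_strength_fits.csv")
  er <- data.frame(cost = bundle$kappas, bundle$er_curves,
                   check.names = FALSE)
  put(er, "er_null_curves.csv")
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(bundle$manifest, mpath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, mpath)
  if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
    paths <- c(paths, write_report_plots(bundle, outdir))
  }
  invisible(paths)
}

write_report_plots <- function(bundle, outdir) {
  gg <- ggplot2::ggplot
  aes <- ggplot2::aes
  paths <- character(0)
  save_plot <- function(p, name, w = 7, h = 5) {
    f <- file.path(outdir, name)
    ggplot2::ggsave(f, p, width = w, height = h)
    paths <<- c(paths, f)
  }
  subjects <- names(bundle$subjects)
  ent <- data.frame(group = rep(bundle$groups, each = length(BAND_NAMES)),
                    band = factor(rep(BAND_NAMES, times = length(subjects)),
                                  levels = rev(BAND_NAMES)),
                    entropy = as.numeric(t(bundle$entropy)))
  p1 <- gg(ent, aes(band, entropy, fill = group)) +
    ggplot2::stat_summary(fun = mean, geom = "col",
                          position = ggplot2::position_dodge()) +
    ggplot2::labs(title = "Wavelet entropy by band", y = "entropy (bits)")
  save_plot(p1, "entropy_bars.pdf")
  grid <- bundle$fda_grid
  grid$logp <- -log10(grid$p)
  p2 <- gg(grid, aes(kind, diagnostic, fill = logp)) +
    ggplot2::geom_tile() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(title = "FDA group differences", fill = "-log10 p")
  save_plot(p2, "fda_grid.pdf", w = 9, h = 6)
  ce <- bundle$cost_efficiency
  p3 <- gg(ce, aes(kind, cost_efficiency, fill = group)) +
    ggplot2::stat_summary(fun = mean, geom = "col",
                          position = ggplot2::position_dodge()) +
    ggplot2::geom_hline(yintercept = bundle$er_cost_efficiency$ce,
                        linetype = 2) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(title = "Cost-efficiency (dashed: ER null)")
  save_plot(p3, "cost_efficiency.pdf", w = 9, h = 5)
  paths
}
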