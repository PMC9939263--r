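#' Linking-probability verification experiment
#'
#' Simulates an ensemble at the default configuration and compares, per dyad
#' type, the mean realized linking proportion across replicates with the
#' input probability. With 10 000 replicates the six absolute deviations are
#' expected to fall well below 0.01.
#'
#' @param n_reps Number of replicate networks.
#' @param config A [sim_config].
#' @param seed Optional seed.
#' @return Object of class `verify_report`: the six-row comparison table
#'   plus the ensemble and a manifest (experiment name, seed, config,
#'   package version).
#' @export
run_verify <- function(n_reps = 10000L, config = sim_config(), seed = NULL) {
  ens <- simulate_ensemble(config, n_reps = n_reps, seed = seed,
                           global_metrics = FALSE)
  structure(
    list(
      table = ens$linking,
      ensemble = ens,
      manifest = experiment_manifest("verify", seed, config,
                                     n_reps = n_reps)
    ),
    class = "verify_report"
  )
}

#' @export
print.verify_report <- function(x, ...) {
  cat(sprintf(
    "Linking-probability verification (%d replicates)\n",
    x$manifest$n_reps
  ))
  print(x$table, digits = 4)
  cat(sprintf("max |deviation| = %.4f\n", max(x$table$abs_deviation)))
  invisible(x)
}

#' Full-range age-distribution experiment
#'
#' Simulates networks with the proportion of old individuals free over
#' \[0, 1\] and summarizes the three global metrics in equal-width
#' proportion-old bins, producing the curve data behind the mean-degree
#' decline, the accelerating diameter increase, and the near-flat
#' transitivity profile.
#'
#' @param n_reps Number of replicate networks (default 20 000).
#' @param config A [sim_config].
#' @param seed Optional seed.
#' @param n_bins Number of proportion-old bins.
#' @return Object of class `fullrange_curves`: `curves` (binned means and
#'   IQRs), the replicate table, and a manifest.
#' @export
run_fullrange <- function(n_reps = 20000L, config = sim_config(),
                          seed = NULL, n_bins = 20L) {
  ens <- simulate_ensemble(config, n_reps = n_reps, seed = seed,
                           global_metrics = TRUE)
  structure(
    list(
      curves = bin_ensemble(ens, n_bins = n_bins),
      replicates = ens$replicates,
      manifest = experiment_manifest("fullrange", seed, config,
                                     n_reps = n_reps, n_bins = n_bins)
    ),
    class = "fullrange_curves"
  )
}

#' @export
print.fullrange_curves <- function(x, ...) {
  cat(sprintf(
    "Full-range experiment: %d replicates in %d proportion-old bins\n",
    x$manifest$n_reps, x$manifest$n_bins
  ))
  cols <- c("midpoint", "n", "mean_degree_mean", "diameter_mean",
            "transitivity_mean")
  print(round(x$curves[, cols], 3), row.names = FALSE)
  invisible(x)
}

#' @export
plot.fullrange_curves <- function(x, ...) {
  curves <- x$curves
  old_par <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old_par))
  for (m in c("mean_degree", "diameter", "transitivity")) {
    graphics::plot(
      curves$midpoint, curves[[paste0(m, "_mean")]],
      type = "b", xlab = "proportion old", ylab = m, ...
    )
  }
  invisible(x)
}

#' Restricted-range experiment with detectability fits
#'
#' Wraps [restricted_range_experiment()] and additionally pushes each bout's
#' networks through [fit_global_structure()] for every global metric,
#' recording whether the 95% interval of the proportion-old coefficient
#' overlaps zero — the statistical-detectability question at empirical
#' sample size.
#'
#' @param n_bouts Number of bouts (default 50).
#' @param n_networks Networks per bout (default 19).
#' @param config A [sim_config].
#' @param prop_old_bounds Bounds on the proportion of old individuals.
#' @param seed Optional master seed.
#' @param fit_models Also fit the per-bout global-structure models.
#' @return Object of class `restricted_report`: the experiment, the per-bout
#'   slope table, the per-bout fit table (`bout`, `response`, estimate,
#'   interval, overlap flag), and a manifest.
#' @export
run_restricted <- function(n_bouts = 50L, n_networks = 19L,
                           config = sim_config(),
                           prop_old_bounds = c(0.04, 0.20),
                           seed = NULL, fit_models = TRUE) {
  rr <- restricted_range_experiment(
    config, n_networks = n_networks, prop_old_bounds = prop_old_bounds,
    n_bouts = n_bouts, seed = seed
  )
  fits <- NULL
  if (fit_models) {
    rows <- list()
    for (b in unique(rr$replicates$bout)) {
      bd <- rr$replicates[rr$replicates$bout == b, ]
      for (resp in c("mean_degree", "diameter", "transitivity")) {
        eff <- tryCatch(
          proportion_old_effect(
            suppressWarnings(fit_global_structure(bd, resp))
          ),
          error = function(e) c(estimate = NA, lwr = NA, upr = NA,
                                overlaps_zero = NA)
        )
        rows[[length(rows) + 1L]] <- data.frame(
          bout = b, response = resp, estimate = eff[["estimate"]],
          lwr = eff[["lwr"]], upr = eff[["upr"]],
          overlaps_zero = eff[["overlaps_zero"]]
        )
      }
    }
    fits <- do.call(rbind, rows)
  }
  structure(
    list(
      experiment = rr, slopes = rr$slopes, fits = fits,
      manifest = experiment_manifest("restricted", seed, config,
                                     n_bouts = n_bouts,
                                     n_networks = n_networks,
                                     prop_old_bounds = prop_old_bounds)
    ),
    class = "restricted_report"
  )
}

#' @export
print.restricted_report <- function(x, ...) {
  print(x$experiment)
  if (!is.null(x$fits)) {
    for (resp in unique(x$fits$response)) {
      f <- x$fits[x$fits$response == resp, ]
      cat(sprintf(
        "  %-12s proportion-old interval overlaps 0 in %d/%d bouts\n",
        resp, sum(f$overlaps_zero, na.rm = TRUE), nrow(f)
      ))
    }
  }
  invisible(x)
}

#' Sensitivity experiment
#'
#' Wraps [sensitivity_sweep()] with a manifest.
#'
#' @param config A [sim_config].
#' @param grid Perturbation grid (`NULL` for the default).
#' @param n_reps_per_cell Replicates per cell.
#' @param seed Optional seed.
#' @return Object of class `sensitivity_report`.
#' @export
run_sensitivity <- function(config = sim_config(), grid = NULL,
                            n_reps_per_cell = 2000L, seed = NULL) {
  sweep <- sensitivity_sweep(config, grid = grid,
                             n_reps_per_cell = n_reps_per_cell, seed = seed)
  structure(
    list(
      sweep = sweep,
      manifest = experiment_manifest("sensitivity", seed, config,
                                     n_reps_per_cell = n_reps_per_cell)
    ),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity sweep: %d cells\n", nrow(x$sweep)))
  cols <- c("target", "factor", "mean_degree_linear_sign",
            "diameter_linear_sign", "transitivity_linear_sign")
  print(x$sweep[, cols], row.names = FALSE)
  invisible(x)
}

#' End-to-end synthetic pipeline
#'
#' Generates a synthetic longitudinal grooming dataset, computes node and
#' global metrics, fits the within-individual trajectory model for each
#' requested response and the global-structure model for each global metric,
#' and returns everything with the generating ground truth for recovery
#' diagnostics.
#'
#' @param params A [synth_params].
#' @param n_networks Number of group-year networks.
#' @param seed Optional seed.
#' @param responses Trajectory responses to fit.
#' @param method Trajectory estimation method (see [fit_trajectory()]).
#' @param min_age Minimum age for trajectory rows.
#' @return Object of class `synthetic_pipeline`: the dataset, observation
#'   and global-metric tables, named lists of `trajectory_fit` and
#'   `global_structure_fit` objects, the truth record, and a manifest.
#' @export
run_synthetic_pipeline <- function(params = synth_params(),
                                   n_networks = 19L, seed = NULL,
                                   responses = c("eigenvector",
                                                 "betweenness", "closeness",
                                                 "clustering"),
                                   method = "glmm", min_age = 10) {
  dataset <- generate_dataset(params, n_networks = n_networks, seed = seed)
  obs <- observation_table(dataset)
  glob <- global_metric_table(dataset,
                              old_threshold = params$old_threshold)
  trajectory <- lapply(responses, function(r) {
    tryCatch(
      suppressWarnings(
        fit_trajectory(obs, response = r, min_age = min_age,
                       method = method)
      ),
      error = function(e) e
    )
  })
  names(trajectory) <- responses
  global <- lapply(c("mean_degree", "diameter", "transitivity"),
                   function(r) {
                     tryCatch(
                       suppressWarnings(fit_global_structure(glob, r)),
                       error = function(e) e
                     )
                   })
  names(global) <- c("mean_degree", "diameter", "transitivity")
  structure(
    list(
      dataset = dataset, observations = obs, global_records = glob,
      trajectory = trajectory, global = global, truth = dataset$truth,
      manifest = experiment_manifest("synthetic_pipeline", seed, params,
                                     n_networks = n_networks,
                                     min_age = min_age)
    ),
    class = "synthetic_pipeline"
  )
}

#' @export
print.synthetic_pipeline <- function(x, ...) {
  print(x$dataset)
  cat("\nWithin-individual age effects (standardized scale):\n")
  for (r in names(x$trajectory)) {
    fit <- x$trajectory[[r]]
    if (inherits(fit, "error")) {
      cat(sprintf("  %-12s fit failed: %s\n", r, conditionMessage(fit)))
    } else {
      eff <- within_age_effect(fit)
      cat(sprintf("  %-12s %+0.3f [%+0.3f, %+0.3f]\n",
                  r, eff[1], eff[2], eff[3]))
    }
  }
  cat("\nProportion-old effects on global structure:\n")
  for (r in names(x$global)) {
    fit <- x$global[[r]]
    if (inherits(fit, "error")) {
      cat(sprintf("  %-12s fit failed: %s\n", r, conditionMessage(fit)))
    } else {
      eff <- proportion_old_effect(fit)
      cat(sprintf("  %-12s %+0.3f [%+0.3f, %+0.3f]%s\n",
                  r, eff[1], eff[2], eff[3],
                  if (eff[4] == 1) " (overlaps 0)" else ""))
    }
  }
  invisible(x)
}

# Minimal provenance record attached to every experiment result.
experiment_manifest <- function(name, seed, config, ...) {
  c(
    list(
      experiment = name,
      seed = seed,
      config = config,
      package_version = as.character(utils::packageVersion("agesocnet")),
      timestamp = format(Sys.time(), tz = "UTC")
    ),
    list(...)
  )
}
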