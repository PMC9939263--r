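#' Restricted-range detectability experiment
#'
#' Probes whether the simulated effect of age structure on global network
#' metrics is statistically detectable when the proportion of old individuals
#' is confined to the empirically observed interval. Each bout generates
#' `n_networks` networks with the number of old individuals drawn uniformly
#' from the integers implied by `prop_old_bounds` (at n = 50 and bounds
#' \[0.04, 0.20\]: 2..10), then fits an ordinary least-squares trend of each
#' global metric on the proportion of old individuals.
#'
#' @param config A [sim_config].
#' @param n_networks Networks per bout (default 19, mirroring an empirical
#'   sample of 19 group-year networks).
#' @param prop_old_bounds Bounds on the proportion of old individuals.
#' @param n_bouts Number of independent bouts (default 50).
#' @param seed Optional master seed; bout b uses stream `seed + b` so bouts
#'   are independently reproducible.
#' @return An object of class `restricted_range`: list with `slopes` (one row
#'   per bout x metric), `replicates` (network-level metrics with a bout
#'   column), the admissible `n_old` values, `config` and `seed`.
#' @examples
#' rr <- restricted_range_experiment(n_bouts = 3, seed = 1)
#' head(rr$slopes)
#' @export
restricted_range_experiment <- function(config = sim_config(),
                                        n_networks = 19L,
                                        prop_old_bounds = c(0.04, 0.20),
                                        n_bouts = 50L,
                                        seed = NULL) {
  if (n_networks < 1L || n_bouts < 1L) {
    stop("n_networks and n_bouts must be >= 1", call. = FALSE)
  }
  if (any(prop_old_bounds < 0) || any(prop_old_bounds > 1) ||
      prop_old_bounds[1] > prop_old_bounds[2]) {
    stop("prop_old_bounds must be an ordered interval within [0, 1]",
         call. = FALSE)
  }
  n <- config$n_individuals
  lo <- as.integer(ceiling(prop_old_bounds[1] * n))
  hi <- as.integer(floor(prop_old_bounds[2] * n))
  if (lo > hi) {
    stop(
      sprintf(
        "prop_old_bounds [%g, %g] admit no integer n_old at n = %d",
        prop_old_bounds[1], prop_old_bounds[2], n
      ),
      call. = FALSE
    )
  }
  metrics <- c("mean_degree", "diameter", "transitivity")
  rep_list <- vector("list", n_bouts)
  slope_list <- vector("list", n_bouts)
  for (b in seq_len(n_bouts)) {
    if (!is.null(seed)) set.seed(seed + b)
    n_old_values <- lo + sample.int(hi - lo + 1L, n_networks,
                                    replace = TRUE) - 1L
    reps <- ensemble_core(config, n_networks, n_old_values = n_old_values)
    reps$bout <- b
    rep_list[[b]] <- reps
    slope_list[[b]] <- data.frame(
      bout = b,
      metric = metrics,
      slope = vapply(metrics, function(m) {
        stats::coef(stats::lm(reps[[m]] ~ reps$proportion_old))[2]
      }, numeric(1)),
      row.names = NULL
    )
  }
  structure(
    list(
      slopes = do.call(rbind, slope_list),
      replicates = do.call(rbind, rep_list),
      n_old_values = lo:hi,
      config = config,
      seed = seed
    ),
    class = "restricted_range"
  )
}

#' @export
print.restricted_range <- function(x, ...) {
  n_bouts <- length(unique(x$slopes$bout))
  cat(sprintf(
    "Restricted-range experiment: %d bouts, n_old in {%s}\n",
    n_bouts, paste(range(x$n_old_values), collapse = "..")
  ))
  for (m in unique(x$slopes$metric)) {
    s <- x$slopes$slope[x$slopes$metric == m]
    cat(sprintf(
      "  %-12s slopes: %d negative / %d positive (mean %.3f)\n",
      m, sum(s < 0), sum(s > 0), mean(s)
    ))
  }
  invisible(x)
}

# Default perturbation grid: identity, then each factor applied jointly to
# all six probabilities and singly to each probability.
default_sensitivity_grid <- function(factors = c(0.8, 0.9, 1.1, 1.2)) {
  cells <- list(list(target = "none", factor = 1))
  for (f in factors) {
    cells <- c(cells, list(list(target = "all", factor = f)))
    for (ty in DYAD_TYPES) {
      cells <- c(cells, list(list(target = ty, factor = f)))
    }
  }
  cells
}

#' Sensitivity of simulated network structure to the linking probabilities
#'
#' Re-runs the ensemble under multiplicative perturbations of the linking
#' probability table and reports the qualitative shape (signs of fitted
#' linear and quadratic trends of each global metric against the proportion
#' of old individuals) in every cell. Probabilities pushed outside \[0, 1\]
#' by a perturbation are clamped, with a warning.
#'
#' @param config A [sim_config].
#' @param grid List of cells, each a list with `target` (`"none"`, `"all"` or
#'   one dyad type) and `factor` (multiplier). `NULL` selects the default
#'   grid of +/-10% and +/-20% perturbations, jointly and singly.
#' @param n_reps_per_cell Replicates simulated per cell.
#' @param seed Optional seed (cell c uses stream `seed + c`).
#' @return Data frame of class `sensitivity_sweep`: one row per cell with
#'   the perturbation, the fitted linear and quadratic coefficients of each
#'   metric on proportion old, and their signs.
#' @export
sensitivity_sweep <- function(config = sim_config(), grid = NULL,
                              n_reps_per_cell = 2000L, seed = NULL) {
  if (is.null(grid)) grid <- default_sensitivity_grid()
  metrics <- c("mean_degree", "diameter", "transitivity")
  rows <- vector("list", length(grid))
  for (ci in seq_along(grid)) {
    cell <- grid[[ci]]
    p <- as.numeric(config$linking_probs)
    names(p) <- DYAD_TYPES
    if (identical(cell$target, "all")) {
      p <- p * cell$factor
    } else if (!identical(cell$target, "none")) {
      p[cell$target] <- p[cell$target] * cell$factor
    }
    if (any(p < 0 | p > 1)) {
      warning(
        sprintf(
          "cell %d (%s x %g): probabilities clamped to [0, 1]",
          ci, cell$target, cell$factor
        ),
        call. = FALSE
      )
      p <- pmin(pmax(p, 0), 1)
    }
    cell_config <- sim_config(
      n_individuals = config$n_individuals,
      n_kin_groups = config$n_kin_groups,
      kin_group_size = config$kin_group_size,
      linking_probs = p,
      n_old_range = config$n_old_range
    )
    if (!is.null(seed)) set.seed(seed + ci)
    reps <- ensemble_core(cell_config, n_reps_per_cell)
    rec <- list(cell = ci, target = cell$target, factor = cell$factor,
                n_reps = n_reps_per_cell)
    for (m in metrics) {
      fit <- stats::lm(reps[[m]] ~ reps$proportion_old +
                         I(reps$proportion_old^2))
      cf <- stats::coef(fit)
      rec[[paste0(m, "_linear")]] <- unname(cf[2])
      rec[[paste0(m, "_quadratic")]] <- unname(cf[3])
      rec[[paste0(m, "_linear_sign")]] <- sign(unname(cf[2]))
      rec[[paste0(m, "_mean")]] <- mean(reps[[m]], na.rm = TRUE)
    }
    rows[[ci]] <- as.data.frame(rec)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_sweep", "data.frame")
  out
}
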