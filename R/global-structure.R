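#' Fit a global-structure model: network topology vs age distribution
#'
#' Regresses one global network metric on the proportion of old individuals
#' across networks. Average relatedness enters as a covariate when available
#' and non-constant; network density enters exactly for the diameter and
#' transitivity responses (density drives both); diameter is log-transformed.
#' A Gaussian year random intercept is included when the records carry a
#' `year` column with more than one level (empirical-style data); otherwise
#' the model is an ordinary linear regression (simulated ensembles have no
#' year structure).
#'
#' @param records Data frame, one row per network, with columns
#'   `proportion_old`, `mean_degree`, `diameter`, `transitivity`, `density`
#'   and optionally `average_relatedness` and `year` (e.g. from
#'   [global_metric_table()]).
#' @param response `"mean_degree"`, `"diameter"` or `"transitivity"`.
#' @return Object of class `global_structure_fit` with a coefficient table
#'   (estimate and 95% interval), the year variance component (when
#'   applicable), covariates used, and the underlying model.
#' @examples
#' ens <- simulate_ensemble(sim_config(n_old_range = c(2, 10)),
#'                          n_reps = 19, seed = 1)
#' fit_global_structure(ens$replicates, "mean_degree")
#' @export
fit_global_structure <- function(records,
                                 response = c("mean_degree", "diameter",
                                              "transitivity")) {
  response <- match.arg(response)
  if (nrow(records) < 8L) {
    stop("need at least 8 networks to fit a global-structure model",
         call. = FALSE)
  }
  d <- as.data.frame(records)
  y <- d[[response]]
  log_transformed <- FALSE
  if (response == "diameter") {
    if (any(y <= 0)) {
      stop("diameter must be positive for the log transform; found ",
           sum(y <= 0), " non-positive value(s)", call. = FALSE)
    }
    y <- log(y)
    log_transformed <- TRUE
  }
  d$.y <- y
  degenerate <- stats::sd(y) == 0
  covars <- "proportion_old"
  dropped <- character(0)
  if ("average_relatedness" %in% names(d) &&
      !all(is.na(d$average_relatedness))) {
    if (stats::sd(d$average_relatedness) > 0) {
      covars <- c(covars, "average_relatedness")
    } else {
      dropped <- c(dropped, "average_relatedness")
      warning("average_relatedness is constant; dropped", call. = FALSE)
    }
  }
  if (response %in% c("diameter", "transitivity")) {
    if (stats::sd(d$density) > 0) {
      covars <- c(covars, "density")
    } else {
      dropped <- c(dropped, "density")
      warning("density is constant; dropped", call. = FALSE)
    }
  }
  use_year <- "year" %in% names(d) && !all(is.na(d$year)) &&
    length(unique(d$year)) > 1L
  year_var <- NA_real_
  if (degenerate) {
    warning("response '", response, "' is constant: degenerate fit",
            call. = FALSE)
    ci <- data.frame(
      term = c("(Intercept)", covars),
      estimate = c(y[1], rep(0, length(covars))),
      lwr = c(y[1], rep(0, length(covars))),
      upr = c(y[1], rep(0, length(covars)))
    )
    model <- NULL
  } else if (use_year) {
    f <- stats::as.formula(
      paste(".y ~", paste(covars, collapse = " + "), "+ (1 | year)")
    )
    model <- glmmTMB::glmmTMB(f, data = d, family = stats::gaussian())
    ci <- wald_ci_table(model)
    vc <- glmmTMB::VarCorr(model)$cond
    if (!is.null(vc$year)) year_var <- as.numeric(vc$year[1, 1])
  } else {
    f <- stats::as.formula(paste(".y ~", paste(covars, collapse = " + ")))
    model <- stats::lm(f, data = d)
    cf <- summary(model)$coefficients
    ci <- data.frame(
      term = rownames(cf),
      estimate = cf[, 1],
      lwr = cf[, 1] - stats::qt(0.975, model$df.residual) * cf[, 2],
      upr = cf[, 1] + stats::qt(0.975, model$df.residual) * cf[, 2],
      row.names = NULL
    )
  }
  structure(
    list(
      response = response, coefficients = ci,
      log_transformed = log_transformed,
      covariates = covars, dropped_covariates = dropped,
      year_variance = year_var, n_networks = nrow(d),
      degenerate = degenerate, model = model
    ),
    class = "global_structure_fit"
  )
}

#' @export
print.global_structure_fit <- function(x, ...) {
  cat(sprintf(
    "Global-structure model: %s%s on %d networks\n",
    if (x$log_transformed) "log " else "", x$response, x$n_networks
  ))
  if (x$degenerate) cat("  (degenerate: constant response)\n")
  tab <- x$coefficients
  tab[, -1] <- round(tab[, -1], 4)
  print(tab, row.names = FALSE)
  if (!is.na(x$year_variance)) {
    cat(sprintf("Year variance component: %.4f\n", x$year_variance))
  }
  invisible(x)
}

#' @export
coef.global_structure_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
confint.global_structure_fit <- function(object, parm, level = 0.95, ...) {
  tab <- object$coefficients
  out <- as.matrix(tab[, c("lwr", "upr")])
  rownames(out) <- tab$term
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Proportion-old effect of a global-structure fit
#'
#' @param fit A `global_structure_fit`.
#' @return Named numeric: estimate, 95% bounds, and whether the interval
#'   overlaps zero (1 = yes).
#' @export
proportion_old_effect <- function(fit) {
  tab <- fit$coefficients
  row <- tab[tab$term == "proportion_old", ]
  c(
    estimate = row$estimate, lwr = row$lwr, upr = row$upr,
    overlaps_zero = as.numeric(row$lwr <= 0 && row$upr >= 0)
  )
}
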