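#' Within-individual age centring
#'
#' Decomposes each individual's age into a between-individual term (the
#' individual's mean age over all of its observations, "average age") and a
#' within-individual term (the deviation of the current age from that mean,
#' "delta age"). The decomposition is an exact linear bijection:
#' `average_age + delta_age == age` row by row, and each individual's delta
#' ages sum to zero. Individuals observed once get `delta_age = 0`.
#'
#' @param rows Data frame with columns `id` and `age` (years).
#' @return `rows` with columns `average_age` and `delta_age` appended.
#' @examples
#' centre_ages(data.frame(id = c("a", "a", "a"), age = c(10, 12, 14)))
#' @export
centre_ages <- function(rows) {
  if (is.null(rows$id) || is.null(rows$age)) {
    stop("rows must have columns 'id' and 'age'", call. = FALSE)
  }
  if (anyNA(rows$age)) {
    bad <- which(is.na(rows$age))
    stop("missing age in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rows$average_age <- stats::ave(rows$age, rows$id, FUN = mean)
  rows$delta_age <- rows$age - rows$average_age
  rows
}

#' Observation table for trajectory models
#'
#' Computes node metrics for every network of a dataset and assembles the
#' per-female, per-year observation rows used by [fit_trajectory()]:
#' identifiers, group, year, age, rank class, and the four
#' indirect-connectedness metrics.
#'
#' @param dataset A `grooming_dataset` (or list of igraph graphs carrying
#'   `age`/`rank` vertex attributes and `group`/`year` graph attributes).
#' @param weighted Use edge weights for the weighted metrics.
#' @return Data frame of observation rows (all adult females; trajectory
#'   fits apply their own minimum-age filter).
#' @export
observation_table <- function(dataset, weighted = TRUE) {
  tab <- node_metric_table(dataset, weighted = weighted)
  tab[, c("id", "group", "year", "age", "rank", "degree", "strength",
          "eigenvector", "betweenness", "closeness", "clustering")]
}

# Squeeze [0, 1] data off the boundary for Beta-family fits
# (Smithson & Verkuilen transform).
squeeze_unit <- function(y) {
  m <- length(y)
  (y * (m - 1) + 0.5) / m
}

trajectory_families <- c("eigenvector", "betweenness", "closeness",
                         "clustering")

# Response-specific preparation: returns list(y, family, excluded, note).
prepare_response <- function(data, response) {
  y <- data[[response]]
  keep <- rep(TRUE, length(y))
  note <- NULL
  family <- NULL
  switch(
    response,
    eigenvector = {
      keep <- y > 0
      if (any(!keep)) {
        note <- sprintf(
          "%d isolate(s) with eigenvector 0 excluded from the log-Gaussian fit",
          sum(!keep)
        )
      }
      y <- log(y[keep])
      family <- stats::gaussian()
    },
    betweenness = {
      y <- round(y) # count family needs integers; measurement stays raw
      family <- "zi_poisson"
    },
    closeness = {
      y <- squeeze_unit(y)
      family <- glmmTMB::beta_family()
    },
    clustering = {
      family <- glmmTMB::ordbeta()
    },
    stop("unknown response: ", response, call. = FALSE)
  )
  list(y = y, keep = keep, family = family, note = note)
}

wald_ci_table <- function(fit) {
  est <- glmmTMB::fixef(fit)$cond
  se <- sqrt(diag(stats::vcov(fit)$cond))
  data.frame(
    term = names(est),
    estimate = as.numeric(est),
    lwr = as.numeric(est - 1.96 * se),
    upr = as.numeric(est + 1.96 * se),
    row.names = NULL
  )
}

fit_glmmtmb_checked <- function(formula, data, family, ziformula = ~0) {
  fit <- suppressWarnings(
    glmmTMB::glmmTMB(formula, data = data, family = family,
                     ziformula = ziformula)
  )
  ok <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  list(fit = fit, ok = ok)
}

#' Fit a within-individual age-trajectory model to a network metric
#'
#' Models one indirect-connectedness metric as a function of
#' within-individual age (`delta_age`), average age, rank class and (by
#' default) a `delta_age x rank` interaction, with random intercepts for
#' individual, group and year and a random `delta_age` slope over
#' individuals. Response families follow the nature of each metric:
#' log-Gaussian for eigenvector centrality (isolates excluded, logged),
#' zero-inflated Poisson on rounded betweenness, Beta for closeness
#' (boundary values squeezed), and ordered (zero-one-inflated) Beta for the
#' clustering coefficient. When every interaction coefficient's 95% interval
#' overlaps zero the interaction is dropped and the model refitted; the
#' structure kept is recorded.
#'
#' Continuous predictors are standardized internally; coefficients are
#' reported on the standardized predictor scale with the scaling recorded in
#' the returned object.
#'
#' If the full random-effects structure does not converge the random slope
#' is dropped with a warning (recorded in the object); if the simplified
#' model also fails, an error with diagnostics is raised.
#'
#' @param data Observation rows (see [observation_table()]): columns `id`,
#'   `group`, `year`, `age`, `rank` and the response metric.
#' @param response One of `"eigenvector"`, `"betweenness"`, `"closeness"`,
#'   `"clustering"`.
#' @param min_age Minimum age (years) for inclusion (default 10: prime
#'   adulthood onward).
#' @param method `"glmm"` (hierarchical model, the default) or
#'   `"two_stage"` (per-individual OLS slopes pooled by inverse variance; a
#'   fast fallback estimator of the within-individual age effect).
#' @param interaction Start from a model with the `delta_age x rank`
#'   interaction (dropped when not supported; see above).
#' @param drop_ns_interaction Apply the interval-overlap dropping rule;
#'   set `FALSE` to keep the interaction regardless (e.g. to inspect the
#'   rank-specific slopes themselves).
#' @return Object of class `trajectory_fit` with a coefficient table
#'   (estimate and 95% interval per term), the family, whether the
#'   interaction and random slope were kept, exclusion notes and the
#'   underlying model object.
#' @export
fit_trajectory <- function(data, response = trajectory_families,
                           min_age = 10, method = c("glmm", "two_stage"),
                           interaction = TRUE,
                           drop_ns_interaction = TRUE) {
  response <- match.arg(response)
  method <- match.arg(method)
  data <- data[data$age >= min_age, , drop = FALSE]
  data <- centre_ages(data)
  multi <- stats::ave(seq_len(nrow(data)), data$id, FUN = length)
  if (sum(tapply(multi, data$id, function(x) x[1] >= 2)) < 2L) {
    stop("need at least 2 individuals with at least 2 observations each",
         call. = FALSE)
  }
  data$rank <- factor(data$rank, levels = c("low", "medium", "high"))
  prep <- prepare_response(data, response)
  d <- data[prep$keep, , drop = FALSE]
  d$.y <- prep$y
  sd_delta <- stats::sd(d$delta_age)
  sd_avg <- stats::sd(d$average_age)
  d$delta_age_s <- d$delta_age / sd_delta
  d$average_age_s <- (d$average_age - mean(d$average_age)) / sd_avg
  scaling <- c(delta_age_sd = sd_delta, average_age_sd = sd_avg)

  if (method == "two_stage") {
    return(fit_trajectory_two_stage(d, response, prep, scaling))
  }

  zif <- if (identical(prep$family, "zi_poisson")) ~1 else ~0
  fam <- if (identical(prep$family, "zi_poisson")) {
    stats::poisson()
  } else {
    prep$family
  }
  fixed <- if (interaction) {
    .y ~ delta_age_s * rank + average_age_s
  } else {
    .y ~ delta_age_s + rank + average_age_s
  }
  re_full <- ~ (1 + delta_age_s | id) + (1 | group) + (1 | year)
  re_simple <- ~ (1 | id) + (1 | group) + (1 | year)
  random_slope_kept <- TRUE
  f <- stats::update.formula(fixed, paste(". ~ . +",
                                          paste(deparse(re_full[[2]]),
                                                collapse = " ")))
  res <- fit_glmmtmb_checked(f, d, fam, zif)
  if (!res$ok) {
    warning(
      "full random-effects structure did not converge for ", response,
      "; refitting without the individual random slope", call. = FALSE
    )
    random_slope_kept <- FALSE
    f <- stats::update.formula(fixed, paste(". ~ . +",
                                            paste(deparse(re_simple[[2]]),
                                                  collapse = " ")))
    res <- fit_glmmtmb_checked(f, d, fam, zif)
    if (!res$ok) {
      stop(
        sprintf(
          "trajectory model for '%s' failed to converge (convergence = %s, pdHess = %s)",
          response, res$fit$fit$convergence, isTRUE(res$fit$sdr$pdHess)
        ),
        call. = FALSE
      )
    }
  }
  fit <- res$fit
  ci <- wald_ci_table(fit)
  interaction_kept <- interaction
  if (interaction && drop_ns_interaction) {
    int_rows <- grepl("delta_age_s:rank", ci$term)
    if (any(int_rows) && all(ci$lwr[int_rows] <= 0 & ci$upr[int_rows] >= 0)) {
      interaction_kept <- FALSE
      fixed2 <- .y ~ delta_age_s + rank + average_age_s
      re2 <- if (random_slope_kept) re_full else re_simple
      f2 <- stats::update.formula(fixed2, paste(". ~ . +",
                                                paste(deparse(re2[[2]]),
                                                      collapse = " ")))
      res2 <- fit_glmmtmb_checked(f2, d, fam, zif)
      if (res2$ok) {
        fit <- res2$fit
        ci <- wald_ci_table(fit)
      } else {
        interaction_kept <- TRUE # keep the converged model
      }
    }
  }
  vc <- tryCatch(glmmTMB::VarCorr(fit)$cond, error = function(e) NULL)
  structure(
    list(
      response = response, method = "glmm",
      family = if (identical(prep$family, "zi_poisson")) {
        "zero-inflated Poisson"
      } else if (inherits(prep$family, "family")) {
        prep$family$family
      } else {
        "unknown"
      },
      coefficients = ci,
      interaction_kept = interaction_kept,
      random_slope_kept = random_slope_kept,
      variance_components = vc,
      n_obs = nrow(d), n_individuals = length(unique(d$id)),
      excluded_note = prep$note,
      scaling = scaling,
      model = fit
    ),
    class = "trajectory_fit"
  )
}

# Two-stage fallback: transform the response, remove group-year (network)
# means, take per-individual OLS slopes on delta_age, and pool with
# design-based weights (the slope information sum(centred delta_age^2));
# per-individual sampling-variance weights are degenerate at 2-3
# observations per female. The pooled SE uses a common residual variance
# estimated from individuals with spare degrees of freedom.
fit_trajectory_two_stage <- function(d, response, prep, scaling) {
  yt <- switch(
    response,
    eigenvector = d$.y, # already log
    betweenness = log1p(d$.y),
    closeness = stats::qlogis(d$.y),
    clustering = stats::qlogis(squeeze_unit(d$.y))
  )
  net <- paste(d$group, d$year)
  d$.yt <- yt - stats::ave(yt, net, FUN = mean)
  ids <- split(seq_len(nrow(d)), d$id)
  est <- w <- rss <- df <- numeric(0)
  for (rows in ids) {
    if (length(rows) < 2L || stats::sd(d$delta_age_s[rows]) == 0) next
    da <- d$delta_age_s[rows]
    sl <- stats::lm(d$.yt[rows] ~ da)
    info <- sum((da - mean(da))^2)
    est <- c(est, stats::coef(sl)[2])
    w <- c(w, info)
    rss <- c(rss, sum(stats::residuals(sl)^2))
    df <- c(df, length(rows) - 2L)
  }
  if (length(est) < 2L) {
    stop("too few individuals with estimable slopes", call. = FALSE)
  }
  sigma2 <- if (sum(df) > 0) sum(rss) / sum(df) else stats::var(est)
  pooled <- sum(w * est) / sum(w)
  pooled_se <- sqrt(sigma2 / sum(w))
  ci <- data.frame(
    term = "delta_age_s",
    estimate = pooled,
    lwr = pooled - 1.96 * pooled_se,
    upr = pooled + 1.96 * pooled_se
  )
  structure(
    list(
      response = response, method = "two_stage",
      family = "per-individual OLS, precision-weighted pooling",
      coefficients = ci,
      interaction_kept = FALSE, random_slope_kept = FALSE,
      variance_components = NULL,
      n_obs = nrow(d), n_individuals = length(est),
      excluded_note = prep$note, scaling = scaling, model = NULL
    ),
    class = "trajectory_fit"
  )
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf(
    "Trajectory model: %s (%s, %s)\n", x$response, x$family, x$method
  ))
  cat(sprintf("  %d observations of %d individuals\n",
              x$n_obs, x$n_individuals))
  if (!is.null(x$excluded_note)) cat("  note:", x$excluded_note, "\n")
  if (x$method == "glmm") {
    cat(sprintf(
      "  delta_age x rank interaction %s; individual random slope %s\n",
      if (x$interaction_kept) "kept" else "dropped",
      if (x$random_slope_kept) "kept" else "dropped"
    ))
  }
  cat("Fixed effects (standardized predictor scale, 95% intervals):\n")
  tab <- x$coefficients
  tab[, -1] <- round(tab[, -1], 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.trajectory_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$variance_components)) {
    cat("\nVariance components:\n")
    print(object$variance_components)
  }
  invisible(object)
}

#' @export
coef.trajectory_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
confint.trajectory_fit <- function(object, parm, level = 0.95, ...) {
  tab <- object$coefficients
  out <- as.matrix(tab[, c("lwr", "upr")])
  rownames(out) <- tab$term
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Extract the within-individual age effect
#'
#' @param fit A `trajectory_fit`.
#' @return Named numeric: estimate, lower and upper 95% bound of the
#'   `delta_age` coefficient (standardized scale); main effect when an
#'   interaction is present.
#' @export
within_age_effect <- function(fit) {
  tab <- fit$coefficients
  row <- tab[tab$term == "delta_age_s", ]
  if (nrow(row) == 0L) stop("no delta_age term in fit", call. = FALSE)
  c(estimate = row$estimate, lwr = row$lwr, upr = row$upr)
}
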