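test_that("age centring is exact arithmetic", {
  x <- centre_ages(data.frame(id = c("a", "a", "a"), age = c(10, 12, 14)))
  expect_equal(x$average_age, rep(12, 3))
  expect_equal(x$delta_age, c(-2, 0, 2))
  one <- centre_ages(data.frame(id = "z", age = 11))
  expect_equal(one$average_age, 11)
  expect_equal(one$delta_age, 0)
  expect_error(centre_ages(data.frame(id = "a", age = NA)), "missing age")
  expect_error(centre_ages(data.frame(x = 1)), "id")
})

test_that("centring is an exact linear bijection on arbitrary inputs", {
  set.seed(91)
  for (rep in 1:5) {
    n <- sample(20:120, 1)
    rows <- data.frame(
      id = sample(letters, n, replace = TRUE),
      age = round(runif(n, 6, 28), 3)
    )
    cc <- centre_ages(rows)
    expect_true(all(abs(cc$average_age + cc$delta_age - rows$age) < 1e-12))
    sums <- tapply(cc$delta_age, cc$id, sum)
    expect_true(all(abs(sums) < 1e-12))
  }
})

test_that("trajectory fits validate their inputs", {
  obs <- data.frame(id = c("a", "b"), group = "g", year = 1,
                    age = c(12, 13), rank = "low", closeness = c(0.2, 0.3),
                    eigenvector = 1, betweenness = 0, clustering = 0,
                    degree = 1, strength = 1)
  expect_error(fit_trajectory(obs, "closeness"), "at least 2")
  expect_error(fit_trajectory(obs, "volume"), "'arg'")
})

test_that("non-null within-individual decline is recovered with the right sign", {
  ds <- generate_dataset(synth_params(), seed = 101)
  obs <- observation_table(ds)
  fit <- suppressWarnings(fit_trajectory(obs, "closeness"))
  eff <- within_age_effect(fit)
  expect_lt(eff[["estimate"]], 0)
  expect_lt(eff[["upr"]], 0) # interval excludes zero at default effect size
  expect_s3_class(fit, "trajectory_fit")
  expect_output(print(fit), "closeness")
  expect_true("delta_age_s" %in% rownames(confint(fit)))
})

test_that("the two-stage fallback agrees in sign with the hierarchical fit", {
  agree <- 0
  for (s in 1:5) {
    ds <- generate_dataset(synth_params(), seed = 110 + s)
    obs <- observation_table(ds)
    g <- suppressWarnings(fit_trajectory(obs, "closeness"))
    t2 <- fit_trajectory(obs, "closeness", method = "two_stage")
    if (sign(within_age_effect(g)[["estimate"]]) ==
        sign(within_age_effect(t2)[["estimate"]])) {
      agree <- agree + 1
    }
  }
  expect_gte(agree, 4)
})

test_that("estimates are invariant to row order and id relabelling", {
  ds <- generate_dataset(synth_params(), seed = 121)
  obs <- observation_table(ds)
  set.seed(122)
  shuffled <- obs[sample(nrow(obs)), ]
  relabel <- obs
  key <- stats::setNames(
    sprintf("X%04d", seq_along(unique(obs$id))), unique(obs$id)
  )
  relabel$id <- key[relabel$id]

  f0 <- fit_trajectory(obs, "closeness", method = "two_stage")
  f1 <- fit_trajectory(shuffled, "closeness", method = "two_stage")
  f2 <- fit_trajectory(relabel, "closeness", method = "two_stage")
  expect_equal(within_age_effect(f1), within_age_effect(f0),
               tolerance = 1e-10)
  expect_equal(within_age_effect(f2), within_age_effect(f0),
               tolerance = 1e-10)

  g0 <- suppressWarnings(fit_trajectory(obs, "closeness"))
  g1 <- suppressWarnings(fit_trajectory(shuffled, "closeness"))
  expect_equal(within_age_effect(g1), within_age_effect(g0),
               tolerance = 1e-4)
})

test_that("rank-dependent truth is detected via the interaction, and the generated ordering shows in degree slopes", {
  p <- synth_params(
    rank_change_age_interaction = c(high = -0.5, medium = -0.25, low = 0)
  )
  kept <- 0
  ordered <- 0
  n <- 4
  for (s in seq_len(n)) {
    ds <- generate_dataset(p, seed = 130 + s)
    obs <- observation_table(ds)
    f <- tryCatch(
      suppressWarnings(fit_trajectory(obs, "betweenness")),
      error = function(e) NULL
    )
    if (!is.null(f) && f$interaction_kept) kept <- kept + 1
    # the generating ordering (high declines fastest) read off degrees
    obs10 <- centre_ages(obs[obs$age >= 10, ])
    sl <- vapply(c("low", "medium", "high"), function(rk) {
      o <- obs10[obs10$rank == rk, ]
      yw <- o$degree - stats::ave(o$degree, o$id, FUN = mean)
      dw <- o$delta_age - stats::ave(o$delta_age, o$id, FUN = mean)
      unname(stats::coef(stats::lm(yw ~ 0 + dw))[1])
    }, numeric(1))
    if (sl[["high"]] < sl[["medium"]] && sl[["medium"]] < sl[["low"]]) {
      ordered <- ordered + 1
    }
  }
  expect_gte(kept, 3)
  expect_gte(ordered, 3)
})

test_that("global-structure models use the prescribed covariate structure", {
  ens <- simulate_ensemble(sim_config(), n_reps = 500, seed = 141)
  rec <- ens$replicates
  rec$diameter[rec$diameter <= 0] <- NA
  rec <- rec[!is.na(rec$diameter), ]

  f_md <- fit_global_structure(rec, "mean_degree")
  expect_false("density" %in% f_md$covariates)
  f_di <- fit_global_structure(rec, "diameter")
  expect_true("density" %in% f_di$covariates)
  expect_true(f_di$log_transformed)

  # full-range large sample recovers the declining mean-degree trend
  eff <- proportion_old_effect(f_md)
  expect_lt(eff[["estimate"]], 0)
  expect_lt(eff[["upr"]], 0)

  # degenerate response: zero coefficient with a warning
  rec2 <- rec[1:10, ]
  rec2$transitivity <- 0.5
  expect_warning(f_c <- fit_global_structure(rec2, "transitivity"),
                 "constant")
  expect_equal(
    f_c$coefficients$estimate[f_c$coefficients$term == "proportion_old"], 0
  )
  expect_error(fit_global_structure(rec[1:5, ], "mean_degree"), "at least 8")
})

test_that("global-structure models accept year random effects and relatedness", {
  ds <- generate_dataset(synth_params(), seed = 151)
  glob <- global_metric_table(ds)
  fit <- suppressWarnings(fit_global_structure(glob, "mean_degree"))
  expect_true("average_relatedness" %in% fit$covariates)
  expect_false(is.na(fit$year_variance))
  expect_gte(fit$year_variance, 0)
  # constant relatedness is dropped with a warning
  glob2 <- glob
  glob2$average_relatedness <- 0.1
  expect_warning(fit_global_structure(glob2, "mean_degree"), "dropped")
})
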