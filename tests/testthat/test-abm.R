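test_that("linking probability table defaults to the empirical estimates and validates", {
  p <- linking_probs()
  expect_s3_class(p, "linking_probs")
  expect_equal(
    as.numeric(p),
    c(0.33, 0.02, 0.37, 0.05, 0.27, 0.08)
  )
  expect_equal(names(p), DYAD_TYPES)
  expect_error(linking_probs(old_old_kin = 1.2), "\\[0, 1\\]")
  expect_error(linking_probs(young_young_nonkin = -0.1), "young_young_nonkin")
  # a plain vector missing a type is a configuration error
  expect_error(
    agesocnet:::validate_linking_probs(c(old_old_kin = 0.3)),
    "missing dyad type"
  )
})

test_that("simulation configuration enforces the kin-partition and range invariants", {
  cfg <- sim_config()
  expect_equal(cfg$n_individuals, 50L)
  expect_equal(cfg$n_kin_groups * cfg$kin_group_size, cfg$n_individuals)
  expect_error(sim_config(n_individuals = 50, n_kin_groups = 7), "partition")
  expect_error(sim_config(n_old_range = c(10, 5)), "n_old_range")
  expect_error(sim_config(n_old_range = c(0, 60)), "n_old_range")
})

test_that("population assignment honours n_old and partitions kin groups", {
  cfg <- sim_config()
  set.seed(1)
  pop <- assign_population(cfg, n_old = 10)
  expect_equal(sum(pop$age_class == "old"), 10L)
  expect_equal(sum(pop$age_class == "young"), 40L)
  expect_equal(as.vector(table(pop$kin_group)), rep(5L, 10L))

  pop0 <- assign_population(cfg, n_old = 0)
  expect_true(all(pop0$age_class == "young"))

  expect_error(assign_population(cfg, n_old = 51), "51")
  expect_error(assign_population(cfg, n_old = -1), "-1")
})

test_that("within-kin-group dyad count matches the combinatorial oracle", {
  # 10 groups of 5 -> 10 * choose(5, 2) = 100 kin dyads, any assignment
  set.seed(2)
  for (n_old in c(0, 17, 50)) {
    pop <- assign_population(sim_config(), n_old)
    dy <- population_dyads(pop)
    expect_equal(sum(grepl("_kin$", dy$dyad_type) &
                       !grepl("nonkin", dy$dyad_type)), 100L)
    expect_equal(nrow(dy), choose(50, 2))
  }
})

test_that("dyad classification is definitional, symmetric, and rejects self-dyads", {
  a <- list(id = 1, age_class = "old", kin_group = 3)
  b <- list(id = 2, age_class = "old", kin_group = 3)
  c_ <- list(id = 3, age_class = "young", kin_group = 1)
  d <- list(id = 4, age_class = "old", kin_group = 2)
  expect_equal(as.character(classify_dyad(a, b)), "old_old_kin")
  expect_equal(as.character(classify_dyad(c_, d)), "old_young_nonkin")
  expect_error(classify_dyad(a, a), "self-dyad")

  set.seed(3)
  pop <- assign_population(sim_config(), 20)
  for (k in 1:25) {
    ij <- sample(50, 2)
    expect_identical(
      classify_dyad(pop[ij[1], ], pop[ij[2], ]),
      classify_dyad(pop[ij[2], ], pop[ij[1], ])
    )
  }
})

test_that("network draws honour degenerate probability tables", {
  set.seed(4)
  pop <- assign_population(sim_config(), 25)
  g1 <- draw_network(pop, probs = rep(1, 6) |> stats::setNames(DYAD_TYPES))
  expect_equal(igraph::ecount(g1), choose(50, 2))
  g0 <- draw_network(pop, probs = rep(0, 6) |> stats::setNames(DYAD_TYPES))
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(igraph::graph_attr(g1, "n_old"), 25L)
  expect_false(igraph::any_loop(g1))
})

test_that("Monte-Carlo edge counts match the closed-form expectation at n_old = 50", {
  # all-old group: E[edges] = 100 * 0.33 + 1125 * 0.02 = 55.5
  set.seed(5)
  cfg <- sim_config()
  reps <- agesocnet:::ensemble_core(cfg, 2000,
                                    n_old_values = rep(50L, 2000),
                                    global_metrics = FALSE)
  expect_equal(mean(reps$n_edges) * 2 / 50, mean(reps$mean_degree))
  se <- stats::sd(reps$n_edges) / sqrt(2000)
  expect_lt(abs(mean(reps$n_edges) - 55.5), 3 * se)
})

test_that("closed-form expected mean degree matches hand-derived endpoints and decreases", {
  expect_equal(expected_mean_degree(0), (2 / 50) * (100 * 0.27 + 1125 * 0.08))
  expect_equal(expected_mean_degree(0), 4.68)
  expect_equal(expected_mean_degree(50), (2 / 50) * (100 * 0.33 + 1125 * 0.02))
  expect_equal(expected_mean_degree(50), 2.22)
  curve <- expected_mean_degree(0:50)
  expect_true(all(diff(curve) < 0))
  expect_error(expected_mean_degree(60), "n_old")
})

test_that("ensembles are reproducible, bounded and carry coherent bookkeeping", {
  cfg <- sim_config()
  e1 <- simulate_ensemble(cfg, n_reps = 50, seed = 11)
  e2 <- simulate_ensemble(cfg, n_reps = 50, seed = 11)
  expect_identical(e1$replicates, e2$replicates) # full determinism
  e3 <- simulate_ensemble(cfg, n_reps = 1, seed = 1)
  expect_equal(nrow(e3$replicates), 1L)
  expect_error(simulate_ensemble(cfg, n_reps = 0), "positive")
  expect_equal(e1$replicates$proportion_old,
               e1$replicates$n_old / cfg$n_individuals)
  expect_true(all(e1$replicates$density >= 0 & e1$replicates$density <= 1))
  expect_true(all(e1$replicates$transitivity >= 0 &
                    e1$replicates$transitivity <= 1))
  expect_output(print(summary(e1)), "Linking proportions")
})

test_that("restricted-range bounds map to the right integer n_old set", {
  rr <- restricted_range_experiment(n_bouts = 2, seed = 7)
  expect_equal(rr$n_old_values, 2:10) # ceiling(0.04*50) .. floor(0.20*50)
  expect_true(all(rr$replicates$n_old %in% 2:10))
  expect_equal(nrow(rr$slopes), 2 * 3)
  expect_equal(nrow(rr$replicates), 2 * 19)
  expect_error(
    restricted_range_experiment(prop_old_bounds = c(0.031, 0.039)),
    "no integer"
  )
  # bout streams: same master seed reproduces slopes exactly
  rr2 <- restricted_range_experiment(n_bouts = 2, seed = 7)
  expect_identical(rr$slopes, rr2$slopes)
})

test_that("sensitivity: identity cell reproduces baseline; sign robust to +/-20% by closed form", {
  grid <- list(list(target = "none", factor = 1),
               list(target = "all", factor = 1.2))
  sw <- sensitivity_sweep(sim_config(), grid = grid,
                          n_reps_per_cell = 400, seed = 9)
  expect_equal(nrow(sw), 2L)
  # identity cell: mean of mean degree across uniform n_old within MC error
  # of the closed-form average
  exp_mean <- mean(expected_mean_degree(0:50))
  expect_lt(abs(sw$mean_degree_mean[1] - exp_mean), 0.15)
  expect_equal(sw$mean_degree_linear_sign, c(-1, -1))

  # closed-form check: the declining mean-degree trend survives +/-20%
  # multiplicative perturbation of all six probabilities
  for (f in c(0.8, 1.2)) {
    p <- linking_probs()
    cfg <- sim_config(linking_probs = pmin(as.numeric(p) * f, 1) |>
                        stats::setNames(DYAD_TYPES))
    curve <- expected_mean_degree(0:50, cfg)
    expect_true(all(diff(curve) < 0))
  }

  # perturbations escaping [0, 1] are clamped with a warning
  expect_warning(
    sensitivity_sweep(
      sim_config(),
      grid = list(list(target = "old_young_kin", factor = 3)),
      n_reps_per_cell = 10, seed = 1
    ),
    "clamped"
  )
})

test_that("binned ensemble summaries are bookkept per bin", {
  ens <- simulate_ensemble(sim_config(), n_reps = 300, seed = 13)
  b <- bin_ensemble(ens, n_bins = 10)
  expect_lte(nrow(b), 10)
  expect_equal(sum(b$n), 300)
  expect_true(all(c("mean_degree_mean", "diameter_iqr") %in% names(b)))
})
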