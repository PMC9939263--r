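#' Dyad types used by the age-structured network model
#'
#' A dyad (unordered pair of individuals) is classified by the age classes of
#' its two members (old/old, old/young, young/young) and by whether the two
#' belong to the same kin group. The six resulting types index the linking
#' probability table that drives the simulator.
#'
#' @format Character vector of length six, in the canonical order used
#'   throughout the package.
#' @export
DYAD_TYPES <- c(
  "old_old_kin", "old_old_nonkin",
  "old_young_kin", "old_young_nonkin",
  "young_young_kin", "young_young_nonkin"
)

#' Linking probability table
#'
#' Constructs the table of Bernoulli edge probabilities, one per dyad type.
#' The defaults are the empirical grooming-network estimates for adult female
#' rhesus macaques: the probability that a dyad of each type shares a grooming
#' tie, averaged over 19 observed group-year networks.
#'
#' @param old_old_kin,old_old_nonkin,old_young_kin,old_young_nonkin,young_young_kin,young_young_nonkin
#'   Probabilities in \[0, 1\].
#' @return A named numeric vector of class `linking_probs` ordered as
#'   [DYAD_TYPES].
#' @examples
#' linking_probs()
#' linking_probs(old_old_kin = 0.5)
#' @export
linking_probs <- function(old_old_kin = 0.33, old_old_nonkin = 0.02,
                          old_young_kin = 0.37, old_young_nonkin = 0.05,
                          young_young_kin = 0.27, young_young_nonkin = 0.08) {
  p <- c(
    old_old_kin = old_old_kin, old_old_nonkin = old_old_nonkin,
    old_young_kin = old_young_kin, old_young_nonkin = old_young_nonkin,
    young_young_kin = young_young_kin, young_young_nonkin = young_young_nonkin
  )
  validate_linking_probs(p)
}

validate_linking_probs <- function(p) {
  if (!is.numeric(p)) {
    stop("linking probabilities must be numeric", call. = FALSE)
  }
  missing_types <- setdiff(DYAD_TYPES, names(p))
  if (length(missing_types) > 0L) {
    stop(
      "linking probability table is missing dyad type(s): ",
      paste(missing_types, collapse = ", "),
      call. = FALSE
    )
  }
  p <- p[DYAD_TYPES]
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    bad <- names(p)[is.na(p) | p < 0 | p > 1]
    stop(
      "linking probabilities must lie in [0, 1]; offending type(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  structure(p, class = "linking_probs")
}

#' @export
print.linking_probs <- function(x, ...) {
  cat("Dyad-type linking probabilities:\n")
  print(unclass(x))
  invisible(x)
}

#' Simulation configuration for the age-structured network model
#'
#' Bundles the population design of the simulator: group size, the kin-group
#' partition, the linking probability table, and the range from which the
#' number of old individuals is drawn (discrete uniform on the integers of
#' `n_old_range`). Defaults mirror the macaque system: groups of 50 adult
#' females partitioned into 10 matrilineal kin groups of 5, with the number of
#' old (>18 y) individuals free to range over 0..50.
#'
#' @param n_individuals Group size (number of nodes per network).
#' @param n_kin_groups Number of kin groups; must satisfy
#'   `n_kin_groups * kin_group_size == n_individuals`.
#' @param kin_group_size Individuals per kin group.
#' @param linking_probs A [linking_probs] table.
#' @param n_old_range Integer vector `c(lo, hi)`; each replicate draws the
#'   number of old individuals uniformly from `lo:hi`.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config()
#' sim_config(n_old_range = c(2, 10))
#' @export
sim_config <- function(n_individuals = 50L, n_kin_groups = 10L,
                       kin_group_size = 5L,
                       linking_probs = agesocnet::linking_probs(),
                       n_old_range = c(0L, n_individuals)) {
  n_individuals <- as.integer(n_individuals)
  n_kin_groups <- as.integer(n_kin_groups)
  kin_group_size <- as.integer(kin_group_size)
  n_old_range <- as.integer(n_old_range)
  if (n_individuals < 2L) stop("n_individuals must be at least 2", call. = FALSE)
  if (n_kin_groups * kin_group_size != n_individuals) {
    stop(
      sprintf(
        "kin groups must partition the group: %d x %d != %d",
        n_kin_groups, kin_group_size, n_individuals
      ),
      call. = FALSE
    )
  }
  if (length(n_old_range) != 2L || anyNA(n_old_range) ||
      n_old_range[1] > n_old_range[2] ||
      n_old_range[1] < 0L || n_old_range[2] > n_individuals) {
    stop(
      "n_old_range must satisfy 0 <= lo <= hi <= n_individuals; got [",
      paste(n_old_range, collapse = ", "), "]",
      call. = FALSE
    )
  }
  probs <- validate_linking_probs(linking_probs)
  structure(
    list(
      n_individuals = n_individuals,
      n_kin_groups = n_kin_groups,
      kin_group_size = kin_group_size,
      linking_probs = probs,
      n_old_range = n_old_range
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation configuration: %d individuals, %d kin groups of %d\n",
    x$n_individuals, x$n_kin_groups, x$kin_group_size
  ))
  cat(sprintf(
    "n_old drawn uniformly from {%d, ..., %d}\n",
    x$n_old_range[1], x$n_old_range[2]
  ))
  print(x$linking_probs)
  invisible(x)
}

#' Randomly assign age classes and kin groups to a simulated group
#'
#' Assigns `n_old` individuals (chosen uniformly at random) to the "old" age
#' class and the remainder to "young", and independently partitions the group
#' into kin groups by a uniform random permutation of kin labels.
#'
#' @param config A [sim_config].
#' @param n_old Number of old individuals, in `0..n_individuals`.
#' @return A data frame of class `abm_population` with columns `id`,
#'   `age_class` (factor, levels old/young) and `kin_group`, plus attribute
#'   `n_old`.
#' @examples
#' pop <- assign_population(sim_config(), n_old = 10)
#' table(pop$age_class)
#' @export
assign_population <- function(config = sim_config(), n_old) {
  n <- config$n_individuals
  n_old <- as.integer(n_old)
  if (length(n_old) != 1L || is.na(n_old) || n_old < 0L || n_old > n) {
    stop(
      sprintf("n_old = %s is outside the admissible range 0..%d", n_old, n),
      call. = FALSE
    )
  }
  age_class <- rep("young", n)
  if (n_old > 0L) age_class[sample.int(n, n_old)] <- "old"
  kin_group <- sample(rep.int(seq_len(config$n_kin_groups),
                              config$kin_group_size))
  pop <- data.frame(
    id = seq_len(n),
    age_class = factor(age_class, levels = c("old", "young")),
    kin_group = kin_group
  )
  attr(pop, "n_old") <- n_old
  attr(pop, "config") <- config
  class(pop) <- c("abm_population", "data.frame")
  pop
}

#' Classify a dyad by age classes and kinship
#'
#' Returns the dyad type of a pair of individuals: the unordered pair of age
#' classes combined with whether the two share a kin group. Symmetric in its
#' arguments.
#'
#' @param a,b Individuals: lists or one-row data frames with fields
#'   `age_class`, `kin_group` and (optionally) `id`. Vectorised: equal-length
#'   data frames classify pairs row-wise.
#' @return Factor with levels [DYAD_TYPES].
#' @examples
#' pop <- assign_population(sim_config(), 10)
#' classify_dyad(pop[1, ], pop[2, ])
#' @export
classify_dyad <- function(a, b) {
  if (!is.null(a$id) && !is.null(b$id) && any(a$id == b$id)) {
    stop(
      "self-dyad: an individual cannot form a dyad with itself (id ",
      paste(unique(a$id[a$id == b$id]), collapse = ", "), ")",
      call. = FALSE
    )
  }
  dyad_type_code(
    as.character(a$age_class), as.character(b$age_class),
    a$kin_group == b$kin_group
  )
}

# Internal vectorised classifier: returns factor over DYAD_TYPES.
dyad_type_code <- function(age_a, age_b, same_kin) {
  n_old_pair <- (age_a == "old") + (age_b == "old")
  idx <- (2L - n_old_pair) * 2L + ifelse(same_kin, 1L, 2L)
  factor(DYAD_TYPES[idx], levels = DYAD_TYPES)
}

#' Enumerate all dyads of a population
#'
#' @param pop An `abm_population`.
#' @return Data frame with columns `i`, `j` (ids, `i < j`) and `dyad_type`.
#' @export
population_dyads <- function(pop) {
  n <- nrow(pop)
  ij <- pair_index(n)
  data.frame(
    i = ij$i, j = ij$j,
    dyad_type = dyad_type_code(
      as.character(pop$age_class)[ij$i], as.character(pop$age_class)[ij$j],
      pop$kin_group[ij$i] == pop$kin_group[ij$j]
    )
  )
}

# All unordered pairs 1..n, i < j, in column-major order.
pair_index <- function(n) {
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  list(i = i, j = j)
}

#' Draw one random network from a population
#'
#' Each of the n(n-1)/2 dyads independently receives an undirected edge with
#' the linking probability of its dyad type (a Bernoulli draw per dyad).
#'
#' @param pop An `abm_population`.
#' @param probs A [linking_probs] table (defaults to the table in the
#'   population's configuration).
#' @return An undirected, unweighted [igraph][igraph::make_empty_graph] graph
#'   with vertex attributes `age_class` and `kin_group` and graph attributes
#'   `n_old` and `n_individuals` (provenance of the draw).
#' @examples
#' pop <- assign_population(sim_config(), 25)
#' g <- draw_network(pop)
#' igraph::ecount(g)
#' @export
draw_network <- function(pop, probs = NULL) {
  config <- attr(pop, "config")
  if (is.null(probs)) probs <- config$linking_probs
  probs <- validate_linking_probs(probs)
  n <- nrow(pop)
  ij <- pair_index(n)
  typ <- dyad_type_int(pop$age_class == "old", pop$kin_group, ij)
  p <- unclass(probs)[typ]
  edge <- stats::runif(length(p)) < p
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (any(edge)) {
    g <- igraph::add_edges(g, rbind(ij$i[edge], ij$j[edge]))
  }
  igraph::V(g)$name <- as.character(pop$id)
  igraph::V(g)$age_class <- as.character(pop$age_class)
  igraph::V(g)$kin_group <- pop$kin_group
  g <- igraph::set_graph_attr(g, "n_old", attr(pop, "n_old"))
  g <- igraph::set_graph_attr(g, "n_individuals", n)
  g
}

# Fast integer dyad-type codes (1..6 over DYAD_TYPES) from a logical old
# indicator and integer kin labels, for precomputed pair indices.
dyad_type_int <- function(old, kin, ij) {
  n_old_pair <- old[ij$i] + old[ij$j]
  same_kin <- kin[ij$i] == kin[ij$j]
  (2L - n_old_pair) * 2L + ifelse(same_kin, 1L, 2L)
}

#' Closed-form expected mean degree of the simulator
#'
#' Analytic expectation of the mean binary degree of a simulated network given
#' the number of old individuals. Age classes of a dyad follow sampling
#' without replacement of `n_old` old labels among `n` individuals; kin and
#' non-kin dyad counts are fixed by the kin-group design. Serves as an
#' independent oracle for the Monte-Carlo ensembles.
#'
#' @param n_old Number (or vector of numbers) of old individuals.
#' @param config A [sim_config].
#' @return Expected mean degree (dimensionless), vectorised over `n_old`.
#' @examples
#' expected_mean_degree(0)   # all-young group
#' expected_mean_degree(50)  # all-old group
#' @export
expected_mean_degree <- function(n_old, config = sim_config()) {
  n <- config$n_individuals
  if (any(n_old < 0 | n_old > n)) {
    stop(
      sprintf("n_old outside 0..%d: %s", n,
              paste(n_old[n_old < 0 | n_old > n], collapse = ", ")),
      call. = FALSE
    )
  }
  p <- unclass(config$linking_probs)
  kin_dyads <- config$n_kin_groups * choose(config$kin_group_size, 2)
  all_dyads <- choose(n, 2)
  nonkin_dyads <- all_dyads - kin_dyads
  denom <- n * (n - 1)
  p_oo <- n_old * (n_old - 1) / denom
  p_oy <- 2 * n_old * (n - n_old) / denom
  p_yy <- (n - n_old) * (n - n_old - 1) / denom
  e_edges <-
    kin_dyads * (p_oo * p[["old_old_kin"]] +
                 p_oy * p[["old_young_kin"]] +
                 p_yy * p[["young_young_kin"]]) +
    nonkin_dyads * (p_oo * p[["old_old_nonkin"]] +
                    p_oy * p[["old_young_nonkin"]] +
                    p_yy * p[["young_young_nonkin"]])
  2 * e_edges / n
}

# Internal ensemble engine. n_old_values, when supplied, fixes the draw per
# replicate; otherwise n_old is uniform on the config range. Returns the
# replicate-level data frame.
ensemble_core <- function(config, n_reps, n_old_values = NULL,
                          global_metrics = TRUE) {
  n <- config$n_individuals
  ij <- pair_index(n)
  n_dyads <- length(ij$i)
  kin_template <- rep.int(seq_len(config$n_kin_groups), config$kin_group_size)
  p_table <- unclass(config$linking_probs)
  lo <- config$n_old_range[1]
  hi <- config$n_old_range[2]
  if (is.null(n_old_values)) {
    n_old_values <- lo + sample.int(hi - lo + 1L, n_reps, replace = TRUE) - 1L
  }
  edge_pairs <- rbind(ij$i, ij$j)

  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    n_old <- n_old_values[r]
    old <- rep(FALSE, n)
    if (n_old > 0L) old[sample.int(n, n_old)] <- TRUE
    kin <- sample(kin_template)
    typ <- dyad_type_int(old, kin, ij)
    edge <- stats::runif(n_dyads) < p_table[typ]
    n_by_type <- tabulate(typ, 6L)
    e_by_type <- tabulate(typ[edge], 6L)
    realized <- ifelse(n_by_type > 0L, e_by_type / n_by_type, NA_real_)
    m <- sum(edge)
    rec <- c(
      n_old = n_old, proportion_old = n_old / n, n_edges = m,
      mean_degree = 2 * m / n, density = m / n_dyads,
      diameter = NA_real_, transitivity = NA_real_
    )
    if (global_metrics) {
      if (m == 0L) {
        rec[["diameter"]] <- 0
        rec[["transitivity"]] <- 0
      } else {
        g <- igraph::make_empty_graph(n, directed = FALSE)
        g <- igraph::add_edges(g, edge_pairs[, edge])
        rec[["diameter"]] <- igraph::diameter(g, unconnected = TRUE)
        tr <- igraph::transitivity(g, type = "global")
        rec[["transitivity"]] <- if (is.nan(tr)) 0 else tr
      }
    }
    out[[r]] <- c(rec, stats::setNames(realized, paste0("lp_", DYAD_TYPES)))
  }
  reps <- as.data.frame(do.call(rbind, out))
  reps <- cbind(rep = seq_len(n_reps), reps)
  reps
}

#' Simulate an ensemble of age-structured random networks
#'
#' Runs the full generative model for `n_reps` replicates. Each replicate
#' draws the number of old individuals uniformly from the configured range,
#' assigns age classes and kin groups at random, draws every dyad's edge by an
#' independent Bernoulli trial with its dyad-type linking probability, and
#' records global network metrics plus the realized linking proportion of
#' each dyad type.
#'
#' @param config A [sim_config].
#' @param n_reps Number of replicate networks (>= 1).
#' @param seed Optional integer seed; identical `(config, n_reps, seed,
#'   global_metrics)` reproduce the ensemble bit-identically.
#' @param global_metrics Compute diameter and transitivity per replicate
#'   (somewhat slower); mean degree and density are always recorded.
#' @return An object of class `abm_ensemble`: a list with `replicates` (one
#'   row per network), `linking` (input vs mean realized linking proportion
#'   per dyad type), `config`, `seed` and `n_reps`.
#' @examples
#' ens <- simulate_ensemble(sim_config(), n_reps = 200, seed = 1)
#' ens$linking
#' @export
simulate_ensemble <- function(config = sim_config(), n_reps, seed = NULL,
                              global_metrics = TRUE) {
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) {
    stop("n_reps must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  reps <- ensemble_core(config, n_reps, global_metrics = global_metrics)
  lp_cols <- paste0("lp_", DYAD_TYPES)
  linking <- data.frame(
    dyad_type = DYAD_TYPES,
    input_probability = as.numeric(config$linking_probs),
    realized_mean = vapply(
      lp_cols, function(cl) mean(reps[[cl]], na.rm = TRUE), numeric(1)
    ),
    row.names = NULL
  )
  linking$abs_deviation <- abs(linking$realized_mean -
                               linking$input_probability)
  structure(
    list(
      replicates = reps, linking = linking, config = config,
      seed = seed, n_reps = n_reps
    ),
    class = "abm_ensemble"
  )
}

#' @export
print.abm_ensemble <- function(x, ...) {
  cat(sprintf(
    "Age-structured network ensemble: %d replicates of %d individuals\n",
    x$n_reps, x$config$n_individuals
  ))
  cat("Input vs realized linking proportions:\n")
  print(x$linking, digits = 4)
  invisible(x)
}

#' @export
summary.abm_ensemble <- function(object, ...) {
  reps <- object$replicates
  metrics <- c("mean_degree", "diameter", "transitivity", "density")
  tab <- t(vapply(metrics, function(m) {
    v <- reps[[m]]
    c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
      min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE))
  }, numeric(4)))
  out <- list(
    n_reps = object$n_reps, linking = object$linking, global = tab
  )
  class(out) <- "summary.abm_ensemble"
  out
}

#' @export
print.summary.abm_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d simulated networks\n", x$n_reps))
  cat("\nGlobal metrics:\n")
  print(round(x$global, 4))
  cat("\nLinking proportions:\n")
  print(x$linking, digits = 4)
  invisible(x)
}

#' Bin ensemble metrics over the proportion of old individuals
#'
#' @param ensemble An `abm_ensemble` (or its `replicates` data frame).
#' @param n_bins Number of equal-width bins over \[0, 1\].
#' @return Data frame with one row per non-empty bin: bin midpoint, replicate
#'   count, and mean and interquartile range of each global metric.
#' @export
bin_ensemble <- function(ensemble, n_bins = 20L) {
  reps <- if (inherits(ensemble, "abm_ensemble")) {
    ensemble$replicates
  } else {
    ensemble
  }
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- cut(reps$proportion_old, breaks, include.lowest = TRUE)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  metrics <- c("mean_degree", "diameter", "transitivity", "density")
  rows <- lapply(seq_len(n_bins), function(b) {
    sel <- as.integer(bin) == b
    if (!any(sel)) return(NULL)
    rec <- c(bin = b, midpoint = mids[b], n = sum(sel))
    for (m in metrics) {
      v <- reps[[m]][sel]
      rec[paste0(m, "_mean")] <- mean(v, na.rm = TRUE)
      rec[paste0(m, "_iqr")] <- stats::IQR(v, na.rm = TRUE)
    }
    rec
  })
  as.data.frame(do.call(rbind, rows))
}
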