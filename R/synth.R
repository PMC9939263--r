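#' Parameters of the synthetic grooming-data generator
#'
#' Defines the longitudinal study design and the generating social process.
#' Defaults emulate a population of matrilineal, hierarchically ranked adult
#' females: six social groups followed over eight years, group sizes around
#' 50.7 adult females, matrilines averaging 5.2 close adult female kin,
#' adulthood from age 6, median adult death age 18 and maximum age 30. Within
#' individuals, the expected number of grooming partners declines with age
#' while total grooming time stays constant, and the odds that a partner is
#' kin increase with age.
#'
#' @param n_groups Number of social groups.
#' @param years Calendar years of the observation window.
#' @param group_size_mean,group_size_sd Adult female group size (drawn once
#'   per group).
#' @param matriline_size_mean Mean matriline size (sizes are
#'   `1 + Poisson(mean - 1)`).
#' @param age_entry Age (years) at which females enter the adult population.
#' @param median_death_age Target median adult age at death; calibrates the
#'   geometric yearly hazard `1 - 0.5^(1/(median_death_age - age_entry))`.
#' @param max_age Hard upper bound on age (death at this age).
#' @param init_age_decay Geometric decay of the initial cross-sectional age
#'   distribution (weight `init_age_decay^(age - age_entry)`); values below
#'   the survival factor encode a growing, young-skewed population.
#' @param base_partners Expected number of grooming partners a female
#'   nominates at the reference age.
#' @param ref_age Reference age (years) at which baseline rates apply.
#' @param partner_slope Change per year of age in the log expected partner
#'   count (negative: fewer partners with age).
#' @param partner_slope_sd Between-individual SD of the partner slope
#'   (individual random slopes).
#' @param rank_change_age_interaction Named numeric (`high`, `medium`,
#'   `low`): additive modifier of `partner_slope` per rank class.
#' @param kin_base Probability a nominated partner is kin at the reference
#'   age.
#' @param kin_bias_slope Change per year of age in the log-odds that a
#'   nominated partner is kin (positive: stronger kin bias with age).
#' @param total_groom_seconds_mean Mean total grooming seconds per female per
#'   year; age-invariant by construction.
#' @param groom_shape Gamma shape of the total-grooming-seconds draw.
#' @param obs_hours_per_female Focal observation hours per female per year;
#'   a dyad's observation time is the sum for its two members.
#' @param dirichlet_conc Concentration of the symmetric Dirichlet split of a
#'   female's grooming time over her partners.
#' @param max_dyad_rate Ceiling on a dyad's grooming rate (seconds per
#'   dyad-observation-hour) — a time-budget constraint: two females cannot
#'   groom together for more than this fraction of the time they are
#'   watched. Pins the strongest tie of every network.
#' @param old_threshold Age above which a female counts as old.
#' @return Object of class `synth_params`.
#' @export
synth_params <- function(n_groups = 6L,
                         years = 2010:2017,
                         group_size_mean = 50.7,
                         group_size_sd = 5,
                         matriline_size_mean = 5.2,
                         age_entry = 6L,
                         median_death_age = 18L,
                         max_age = 30L,
                         init_age_decay = 0.82,
                         base_partners = 1.4,
                         ref_age = 14,
                         partner_slope = -0.32,
                         partner_slope_sd = 0.02,
                         rank_change_age_interaction =
                           c(high = 0, medium = 0, low = 0),
                         kin_base = 0.55,
                         kin_bias_slope = 0.45,
                         total_groom_seconds_mean = 3600,
                         groom_shape = 10,
                         obs_hours_per_female = 50,
                         dirichlet_conc = 2,
                         max_dyad_rate = 30,
                         old_threshold = 18) {
  if (!(age_entry < median_death_age && median_death_age < max_age)) {
    stop("require age_entry < median_death_age < max_age", call. = FALSE)
  }
  if (n_groups < 1L || length(years) < 1L) {
    stop("need at least one group and one year", call. = FALSE)
  }
  if (group_size_mean <= 2 || matriline_size_mean < 1) {
    stop("infeasible group or matriline size", call. = FALSE)
  }
  if (!all(c("high", "medium", "low") %in%
           names(rank_change_age_interaction))) {
    stop("rank_change_age_interaction must name high, medium, low",
         call. = FALSE)
  }
  structure(
    list(
      n_groups = as.integer(n_groups), years = as.integer(years),
      group_size_mean = group_size_mean, group_size_sd = group_size_sd,
      matriline_size_mean = matriline_size_mean,
      age_entry = as.integer(age_entry),
      median_death_age = as.integer(median_death_age),
      max_age = as.integer(max_age),
      yearly_hazard = 1 - 0.5^(1 / (median_death_age - age_entry)),
      init_age_decay = init_age_decay,
      base_partners = base_partners, ref_age = ref_age,
      partner_slope = partner_slope, partner_slope_sd = partner_slope_sd,
      rank_change_age_interaction = rank_change_age_interaction,
      kin_base = kin_base, kin_bias_slope = kin_bias_slope,
      total_groom_seconds_mean = total_groom_seconds_mean,
      groom_shape = groom_shape,
      obs_hours_per_female = obs_hours_per_female,
      dirichlet_conc = dirichlet_conc,
      max_dyad_rate = max_dyad_rate,
      old_threshold = old_threshold
    ),
    class = "synth_params"
  )
}

#' @export
print.synth_params <- function(x, ...) {
  cat(sprintf(
    "Synthetic grooming-data parameters: %d groups x %d years\n",
    x$n_groups, length(x$years)
  ))
  cat(sprintf(
    "  adulthood %d-%d y, median death age %d (yearly hazard %.4f)\n",
    x$age_entry, x$max_age, x$median_death_age, x$yearly_hazard
  ))
  cat(sprintf(
    "  partner slope %+.3f /y (SD %.3f), kin-bias slope %+.3f /y\n",
    x$partner_slope, x$partner_slope_sd, x$kin_bias_slope
  ))
  invisible(x)
}

#' Simulate adult ages at death under the generator's survival model
#'
#' Death age is `age_entry + K` with `K ~ Geometric(yearly hazard)`,
#' truncated at `max_age`. Exposed so the survival calibration (median death
#' age) can be checked by direct Monte Carlo.
#'
#' @param params A [synth_params].
#' @param n Number of females to simulate.
#' @param seed Optional seed.
#' @return Integer vector of ages at death.
#' @export
simulate_death_ages <- function(params = synth_params(), n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- stats::rgeom(n, params$yearly_hazard)
  pmin(params$age_entry + k, params$max_age)
}

# Draw matriline sizes covering n individuals (1 + Poisson(mean - 1)).
draw_matriline_sizes <- function(n, mean_size) {
  sizes <- integer(0)
  while (sum(sizes) < n) {
    sizes <- c(sizes, 1L + stats::rpois(1, mean_size - 1))
  }
  excess <- sum(sizes) - n
  if (excess > 0L) sizes[length(sizes)] <- sizes[length(sizes)] - excess
  sizes[sizes > 0L]
}

#' Simulate a longitudinal roster of adult females
#'
#' Per group, initial ages follow a young-skewed geometric cross-section;
#' each year females age one year, die with the calibrated geometric hazard
#' (certain death at `max_age`), and are replaced by new `age_entry`-year-old
#' recruits who join an existing matriline with probability proportional to
#' its size. Each female carries a latent dominance score (ranks classed
#' yearly: high = 80%+ of others dominated, medium = 50-79%, low otherwise)
#' and an individual random deviation of the partner-count age slope.
#'
#' @param params A [synth_params].
#' @param seed Optional seed.
#' @return Data frame of class `synth_roster`: one row per female per year
#'   with `group`, `year`, `id`, `age`, `matriline`, `rank`, `latent_rank`,
#'   `indiv_slope`.
#' @export
generate_cohort <- function(params = synth_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ages_support <- params$age_entry:params$max_age
  init_w <- params$init_age_decay^(ages_support - params$age_entry)
  rows <- vector("list", params$n_groups * length(params$years))
  ri <- 0L
  next_id <- 1L
  for (g in seq_len(params$n_groups)) {
    size_g <- max(10L, round(stats::rnorm(1, params$group_size_mean,
                                          params$group_size_sd)))
    age <- sample(ages_support, size_g, replace = TRUE, prob = init_w)
    mat_sizes <- draw_matriline_sizes(size_g, params$matriline_size_mean)
    matriline <- paste0("G", g, "M",
                        rep.int(seq_along(mat_sizes), mat_sizes))
    matriline <- sample(matriline)
    id <- sprintf("G%d_%04d", g, next_id + seq_len(size_g) - 1L)
    next_id <- next_id + size_g
    latent <- stats::runif(size_g)
    islope <- stats::rnorm(size_g, 0, params$partner_slope_sd)
    for (y in params$years) {
      n <- length(id)
      frac_dom <- (rank(latent) - 1) / (n - 1)
      rank_class <- ifelse(frac_dom >= 0.8, "high",
                           ifelse(frac_dom >= 0.5, "medium", "low"))
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        group = paste0("G", g), year = y, id = id, age = age,
        matriline = matriline, rank = rank_class,
        latent_rank = latent, indiv_slope = islope,
        stringsAsFactors = FALSE
      )
      # transition to next year
      age <- age + 1L
      dies <- stats::runif(n) < params$yearly_hazard | age > params$max_age
      n_dead <- sum(dies)
      id <- id[!dies]; age <- age[!dies]; matriline <- matriline[!dies]
      latent <- latent[!dies]; islope <- islope[!dies]
      if (n_dead > 0L) {
        mat_pool <- table(matriline)
        new_mat <- sample(names(mat_pool), n_dead, replace = TRUE,
                          prob = as.numeric(mat_pool))
        new_id <- sprintf("G%d_%04d", g, next_id + seq_len(n_dead) - 1L)
        next_id <- next_id + n_dead
        id <- c(id, new_id)
        age <- c(age, rep(params$age_entry, n_dead))
        matriline <- c(matriline, new_mat)
        latent <- c(latent, stats::runif(n_dead))
        islope <- c(islope, stats::rnorm(n_dead, 0, params$partner_slope_sd))
      }
    }
  }
  roster <- do.call(rbind, rows[seq_len(ri)])
  attr(roster, "params") <- params
  class(roster) <- c("synth_roster", "data.frame")
  roster
}

#' Simulate one group-year grooming network
#'
#' Each female nominates a Poisson number of partners with log-mean linear in
#' her age (slope = population slope + her individual deviation + her rank
#' class modifier); each nomination is kin (same matriline) with probability
#' whose log-odds increase with age. Her total yearly grooming time is drawn
#' age-invariantly from a Gamma distribution and split over her partners by a
#' symmetric Dirichlet. Dyadic seconds are symmetrized (contributions from
#' both sides add) and divided by the dyad's combined observation hours to
#' give grooming rates.
#'
#' @param roster_slice Rows of a [generate_cohort()] roster for one group and
#'   year.
#' @param params A [synth_params].
#' @param seed Optional seed.
#' @return Undirected weighted igraph graph with vertex attributes `age`,
#'   `rank`, `matriline`, `groom_total` (the female's drawn total grooming
#'   seconds; 0 when she nominated no partners) and graph attributes
#'   `group`, `year`,
#'   `proportion_old`, `average_relatedness`. Females with no grooming are
#'   isolates.
#' @export
generate_group_year_network <- function(roster_slice,
                                        params = synth_params(),
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(roster_slice)
  if (n == 0L) stop("empty roster slice", call. = FALSE)
  age <- roster_slice$age
  d_age <- age - params$ref_age
  rank_mod <- params$rank_change_age_interaction[roster_slice$rank]
  slope <- params$partner_slope + roster_slice$indiv_slope + rank_mod
  lambda <- params$base_partners * exp(slope * d_age)
  k <- pmin(stats::rpois(n, lambda), n - 1L)
  p_kin <- stats::plogis(stats::qlogis(params$kin_base) +
                           params$kin_bias_slope * d_age)
  sec <- matrix(0, n, n)
  groom_total <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] == 0L) next
    same_mat <- which(roster_slice$matriline == roster_slice$matriline[i])
    kin_pool <- setdiff(same_mat, i)
    nonkin_pool <- setdiff(seq_len(n), c(same_mat))
    n_kin <- stats::rbinom(1, k[i], p_kin[i])
    n_kin <- min(n_kin, length(kin_pool))
    n_nonkin <- min(k[i] - n_kin, length(nonkin_pool))
    partners <- c(
      if (n_kin > 0L) sample(kin_pool, n_kin) else integer(0),
      if (n_nonkin > 0L) sample(nonkin_pool, n_nonkin) else integer(0)
    )
    if (length(partners) == 0L) next
    total <- stats::rgamma(1, shape = params$groom_shape,
                           rate = params$groom_shape /
                             params$total_groom_seconds_mean)
    groom_total[i] <- total
    w <- stats::rgamma(length(partners), params$dirichlet_conc, 1)
    w <- w / sum(w)
    sec[cbind(i, partners)] <- sec[cbind(i, partners)] + total * w
  }
  sec <- sec + t(sec)
  dyad_hours <- 2 * params$obs_hours_per_female
  idx <- which(upper.tri(sec) & sec > 0, arr.ind = TRUE)
  edges <- data.frame(
    id_a = roster_slice$id[idx[, 1]],
    id_b = roster_slice$id[idx[, 2]],
    weight = pmin(sec[idx] / dyad_hours, params$max_dyad_rate)
  )
  nodes <- data.frame(
    id = roster_slice$id, age = age, rank = roster_slice$rank,
    matriline = roster_slice$matriline, groom_total = groom_total,
    stringsAsFactors = FALSE
  )
  g <- if (nrow(edges) > 0L) {
    grooming_graph(edges, nodes)
  } else {
    igraph::graph_from_data_frame(
      data.frame(from = character(), to = character(), weight = numeric()),
      directed = FALSE, vertices = nodes
    )
  }
  same_mat_dyads <- sum(choose(table(roster_slice$matriline), 2))
  g <- igraph::set_graph_attr(g, "group", roster_slice$group[1])
  g <- igraph::set_graph_attr(g, "year", roster_slice$year[1])
  g <- igraph::set_graph_attr(g, "proportion_old",
                              mean(age > params$old_threshold))
  g <- igraph::set_graph_attr(g, "average_relatedness",
                              0.25 * same_mat_dyads / choose(n, 2))
  g
}

# The unbalanced group-year observation design: how many of the window's
# years each group contributes. With 6 groups, 8 years and 19 networks this
# is the canonical 8/2/3/2/1/3 pattern; otherwise group-years are sampled.
design_group_years <- function(params, n_networks) {
  n_gy <- params$n_groups * length(params$years)
  if (n_networks > n_gy) {
    stop(
      sprintf("n_networks = %d exceeds the %d available group-years",
              n_networks, n_gy),
      call. = FALSE
    )
  }
  groups <- paste0("G", seq_len(params$n_groups))
  if (params$n_groups == 6L && length(params$years) == 8L &&
      n_networks == 19L) {
    counts <- c(8L, 2L, 3L, 2L, 1L, 3L)
  } else {
    counts <- rep(1L, params$n_groups)
    extra <- n_networks - params$n_groups
    if (extra < 0L) {
      counts <- c(rep(1L, n_networks), rep(0L, params$n_groups - n_networks))
    } else if (extra > 0L) {
      pool <- rep(groups, length(params$years) - 1L)
      add <- table(sample(pool, extra))
      counts <- counts + as.integer(add[groups] %||% 0L)
      counts[is.na(counts)] <- 1L
    }
  }
  design <- do.call(rbind, lapply(seq_along(groups), function(g) {
    if (counts[g] == 0L) return(NULL)
    yrs <- if (counts[g] == length(params$years)) {
      params$years
    } else {
      sort(sample(params$years, counts[g]))
    }
    data.frame(group = groups[g], year = yrs, stringsAsFactors = FALSE)
  }))
  design$network <- seq_len(nrow(design))
  design
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a full synthetic longitudinal grooming dataset
#'
#' Simulates the cohort, samples an unbalanced group-year design (groups
#' contribute between one and all years of the window), builds one grooming
#' network per sampled group-year, and logs the generating ground truth for
#' parameter-recovery studies.
#'
#' @param params A [synth_params].
#' @param n_networks Number of group-year networks (default 19).
#' @param seed Optional seed; fixed seeds reproduce the dataset exactly.
#' @return Object of class `grooming_dataset`: list with `networks` (igraph
#'   graphs), `roster`, `design` (network/group/year), `truth` (a
#'   `TruthRecord`-style list: generating slopes, rank modifiers, individual
#'   random slopes, per-network proportion old) and `params`.
#' @examples
#' ds <- generate_dataset(n_networks = 4, seed = 1)
#' ds
#' @export
generate_dataset <- function(params = synth_params(), n_networks = 19L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  roster <- generate_cohort(params)
  design <- design_group_years(params, n_networks)
  networks <- lapply(seq_len(nrow(design)), function(k) {
    slice <- roster[roster$group == design$group[k] &
                      roster$year == design$year[k], ]
    generate_group_year_network(slice, params)
  })
  islopes <- roster[!duplicated(roster$id), c("id", "indiv_slope")]
  truth <- list(
    partner_slope = params$partner_slope,
    kin_bias_slope = params$kin_bias_slope,
    rank_change_age_interaction = params$rank_change_age_interaction,
    indiv_slopes = stats::setNames(islopes$indiv_slope, islopes$id),
    proportion_old = vapply(
      networks, function(g) igraph::graph_attr(g, "proportion_old"),
      numeric(1)
    )
  )
  structure(
    list(networks = networks, roster = roster, design = design,
         truth = truth, params = params, seed = seed),
    class = "grooming_dataset"
  )
}

#' @export
print.grooming_dataset <- function(x, ...) {
  sizes <- vapply(x$networks, function(g) as.integer(igraph::vcount(g)),
                  integer(1))
  cat(sprintf(
    "Synthetic grooming dataset: %d group-year networks (%d groups, %d-%d)\n",
    length(x$networks), length(unique(x$design$group)),
    min(x$design$year), max(x$design$year)
  ))
  cat(sprintf(
    "  network size %.1f females (range %d-%d); proportion old %.2f-%.2f\n",
    mean(sizes), min(sizes), max(sizes),
    min(x$truth$proportion_old), max(x$truth$proportion_old)
  ))
  cat(sprintf(
    "  truth: partner slope %+.3f, kin-bias slope %+.3f\n",
    x$truth$partner_slope, x$truth$kin_bias_slope
  ))
  invisible(x)
}
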