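---
title: "Ageing individuals and the structure of social networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ageing individuals and the structure of social networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`agesocnet` studies a question from behavioural ecology: adult females in
many group-living species interact with fewer partners as they age, and
concentrate their social effort on kin — do these individual-level changes
scale up to alter the topology of the whole social network, and when would
such an effect be statistically detectable? The package provides four
cooperating pieces:

1. an **agent-based network simulator** in which edge probabilities depend
   on the age classes and kinship of each dyad;
2. **network metrics** for weighted grooming networks and binary simulated
   networks;
3. a **synthetic longitudinal grooming-data generator** with logged ground
   truth; and
4. **hierarchical regression models** of individual metric trajectories
   (within-individual age centring) and of global structure against the
   proportion of old group members.

This vignette is the package's methods account: the models, their
assumptions, the tunable parameters, the numerical conventions, and what the
tests do and do not establish.

```{r setup}
library(agesocnet)
```

## The agent-based model

A simulated group has `n_individuals = 50` members (the mean adult female
group size in the macaque system the defaults emulate), partitioned into
`n_kin_groups = 10` kin groups of `kin_group_size = 5` (the mean number of
close adult female kin). Each replicate draws the number of old individuals
`n_old` from a **discrete uniform distribution on the integers** of
`n_old_range` (default 0..50); ages and kin labels are then assigned
uniformly at random and independently of each other. Counts of individuals
are integers, hence the discrete reading of the uniform range.

Every unordered pair of individuals (dyad) belongs to one of six types —
old/old, old/young or young/young, crossed with kin or non-kin — and
receives an edge by an independent Bernoulli draw with the type's linking
probability. The default table is the empirical estimate from 19 observed
grooming networks:

```{r}
linking_probs()
```

Note the structure these numbers impose: kin dyads are far likelier to be
linked than non-kin dyads at every age, old/old non-kin dyads are nearly
never linked, and old/young kin dyads are linked slightly *more* often than
young/young kin dyads. The model is a static draw: no rewiring, births,
deaths or within-simulation ageing, no continuous ages, no spatial or sex
structure.

### Closed-form oracle

Because age assignment is sampling without replacement, the expected number
of edges given `n_old` has a closed form, implemented in
`expected_mean_degree()`. With 100 kin dyads, 1125 non-kin dyads and the
default table, the expected mean degree is 4.68 for an all-young group and
2.22 for an all-old group, and it decreases strictly in `n_old`. The
Monte-Carlo ensembles are tested against this oracle, and the full-range
experiment's declining mean-degree curve is the stochastic image of it.

```{r}
expected_mean_degree(c(0, 25, 50))
```

### Experiments

- `run_verify()` (default 10 000 replicates) recomputes the realized
  linking proportion per dyad type and compares it with the input table;
  deviations settle well below 0.01. Dyad types absent from a replicate
  (no old/old dyads when `n_old < 2`) are skipped in that replicate's
  proportion, and ensemble means ignore them.
- `run_fullrange()` (default 20 000 replicates) lets the proportion old
  roam over [0, 1] and summarizes mean degree, diameter and transitivity in
  20 equal-width bins. Mean degree declines monotonically; diameter
  *accelerates* upward (the slope above 80% old exceeds the slope below
  20%); transitivity is nearly flat over [0, 0.8] while its dispersion (and
  the diameter's) grows with the old fraction — old-heavy networks take
  more varied shapes.
- `run_restricted()` confines the proportion old to the empirically
  observed band [0.04, 0.20] (integers 2..10 at n = 50), generates bouts of
  19 networks (the empirical sample size), and fits per-bout OLS trends and
  global-structure models. Across 50 bouts the mean-degree slopes take both
  signs and the proportion-old intervals overlap zero in the majority of
  bouts: at empirical sample size and age range, the true structural effect
  is usually undetectable.
- `run_sensitivity()` re-runs ensembles under multiplicative perturbations
  of the linking table (default grid: ±10% and ±20%, jointly and per
  probability, clamped to [0, 1] with a warning) and reports the signs of
  fitted linear and quadratic trends. The declining mean-degree trend
  survives ±20% joint perturbation — this also follows analytically from
  the closed form.

Replicate counts are configurable; the defaults (10 000 for verification,
20 000 for curve shape) were chosen because the binned curves are already
smooth at that scale, and they are the scales used by the package's own
tests and acceptance script.

Every experiment accepts a seed and is bit-reproducible from it; bouts and
sensitivity cells use fixed offsets from the master seed so each is
independently reproducible. Results carry a manifest (experiment name, seed,
configuration, package version).

## Network metrics

Empirical-style networks are undirected with weights in grooming seconds
per dyad-observation-hour; simulated networks are binary. Conventions,
chosen where the field's practice is ambiguous:

- **Weight to distance.** Shortest-path metrics need a cost; the package
  uses the reciprocal of the edge weight (strong ties are short). This is
  the standard affinity-to-cost convention.
- **Eigenvector centrality** is computed per connected component and scaled
  so each component's maximum is 1; isolates score 0. Per-component
  computation keeps scores strictly positive for every non-isolate, which
  the log-scale trajectory model requires; the alternative (a single global
  leading eigenvector) zeroes out every node outside the dominant
  component.
- **Closeness** uses the reachable-set formula
  $((r-1)/(n-1)) \cdot ((r-1)/\sum_u d(v,u))$ with $r$ the number of nodes
  reachable from $v$ (including $v$): bounded, defined on disconnected
  graphs, 0 for isolates. On weighted graphs the distances are first
  normalized by the network's smallest edge distance (its strongest tie).
  Without this, grooming rates above 1 s/h give path distances below one
  hop and closeness above 1, breaking both the [0, 1] contract and any
  Beta-family model; with it, closeness is invariant to the unit in which
  rates are expressed, and the convention reduces to the plain formula on
  binary graphs.
- **Betweenness** is shortest-path betweenness with fractional attribution
  among tied geodesics, on reciprocal-weight distances (weighted) or unit
  distances (binary), reported raw — the trajectory module, not the
  measurement, rounds it for its count model.
- **Local clustering** is binary even on weighted networks (ties among a
  node's neighbours over possible ties); nodes of degree < 2 score 0 and
  are flagged. Binary clustering yields exact zeros and ones, which is what
  the endpoint-inflated Beta trajectory family expects.
- **Diameter** is the longest geodesic over *connected pairs only* (finite
  on disconnected graphs — sparse all-old networks routinely fragment);
  an edgeless graph has diameter 0 and a flag. Weighted diameters are on
  raw reciprocal-weight distances.
- **Transitivity** is the global ratio 3·triangles / connected triples,
  always binary; a graph with no connected triple reports 0.

Metrics are computed through igraph; the test suite checks every metric
against independent brute-force oracles (dense eigendecomposition,
Floyd–Warshall distances, exhaustive shortest-path counting) on canonical
small graphs and on 50 random graphs up to 30 nodes, at 1e-6.

## The synthetic grooming-data generator

`generate_dataset()` emulates the *structure* of a longitudinal
grooming-network study of adult female macaques: 6 groups followed over 8
years, 19 group-year networks in the unbalanced pattern 8/2/3/2/1/3 (one
group observed every year, others 1–3 years), group sizes around 50.7,
matrilines averaging 5.2 living members, adulthood from age 6.

**Demography.** Adult survival is geometric with yearly hazard
$1 - 0.5^{1/12}$, the one-parameter choice that puts the median age at
death at 18 (death is certain at 30). Initial cross-sectional ages decay
geometrically (`init_age_decay = 0.82` per year of age), encoding a
growing, young-skewed population; with replacement recruitment at age 6 the
proportion of old (>18 y) females per network then spans roughly 0.03–0.19
across group-years, the empirically observed band. Observation counts per
female average ≈ 2.7 years (range 1–8), driven by the design and by
mortality.

**Behaviour.** Each female nominates a Poisson number of partners with
log-mean linear in her age: `base_partners` (1.4) at the reference age 14,
declining by `partner_slope` (−0.32 per year), modified by an individual
random slope (SD 0.02) and optionally by rank class
(`rank_change_age_interaction`, zero by default). Each nomination is kin —
a matriline mate — with probability whose log-odds rise with age
(`kin_bias_slope` = +0.45 per year from `kin_base` = 0.55 at the reference
age). Her total yearly grooming time is drawn from a Gamma distribution
(mean 3600 s, shape 10) *independently of age* — older females invest the
same time in fewer partners — and is split across her partners by a
symmetric Dirichlet (concentration 2). Dyadic seconds add over both
members, are divided by the dyad's combined focal hours to give rates, capped at
`max_dyad_rate` (30 s per dyad-observation-hour, a time-budget constraint
that also pins the strongest tie of every network). Ranks come from a
latent dominance score with the 80%/50% dominated cutoffs for
high/medium/low.

**Effect-size calibration.** The defaults are deliberately at the strong
end of the plausible range: the package's recovery tests require the
generating decline to be detectable at the printed design scale (19
networks, ≈2.8 observations per female), and the constant-total-time
constraint buffers weighted metrics against partner loss — fewer partners
get proportionally stronger, hence shorter, ties. Weighted closeness is the
most buffered: its within-individual decline is real but plateaus near 90%
detection power however hard the generating slopes push (pushing harder
saturates the young end of the network instead). Log eigenvector
centrality expresses the same generating decline far more identifiably,
and the acceptance checks use it for interval-exclusion while holding
closeness to sign recovery. A generator calibrated to the *real* system's
effect sizes would sit near the detection boundary (the empirical closeness
interval barely excluded zero), which is exactly the regime the
restricted-range experiment studies.

**What the generator does not emulate.** Real degree and weight
distributions (only the printed summary facts are matched), directed
grooming, males/juveniles, seasonality, dominance interactions, pedigree
relatedness (the emitted `average_relatedness` is a matriline-share proxy:
0.25 × the share of within-matriline dyads), and partner fidelity across
years (each year's network is drawn fresh given the roster). Passing
recovery tests therefore show that the *pipeline* estimates what the
generator encodes — not that real data would yield the same coefficients.

## Trajectory models

`centre_ages()` splits each female's age into her mean across observations
("average age", between-individual) and her deviation from it ("delta age",
within-individual). The decomposition is linear and exact to machine
precision; single-observation females get delta 0. The within-individual
term is the variable of scientific interest: it measures change *within* a
lifespan, uncontaminated by selective disappearance or cohort differences.

`fit_trajectory()` models one metric for females aged 10+ (prime adulthood
onward; networks themselves include all 6+ females) with fixed effects
delta age, average age, rank, and a delta-age × rank interaction, random
intercepts for individual, group and year, and a random delta-age slope
over individuals. Families follow the nature of each metric: Gaussian on
log eigenvector (isolates excluded, with a logged count), zero-inflated
Poisson on betweenness rounded to integers, Beta on closeness, and ordered
(zero-one-inflated) Beta on clustering. Closeness boundary values are
squeezed off 0/1 by the standard $(y(m-1)+0.5)/m$ transform. The engine is
glmmTMB (maximum likelihood); intervals are Wald 95%. The interaction is
dropped and the model refitted when every interaction coefficient's
interval overlaps zero — the retention rule mirrors the
interval-excludes-zero criterion. Continuous predictors are standardized
internally (coefficients are on the standardized predictor scale; the
scaling is recorded in the fit object). Quadratic age terms are not
offered: the modelled ageing process is linear on the link scale by
construction.

Numerical behaviour is explicit: if the full random-effects structure does
not converge (typically a near-zero random-slope variance), the random
slope is dropped with a warning and the simplification is recorded in the
fit; if the simplified model also fails, the fit errors with diagnostics.

A `two_stage` method provides a fast fallback estimator of the
within-individual effect: transform the response per family, remove
group-year means, take per-individual OLS slopes, and pool them with
design-based weights (each female's slope information
$\sum (\Delta\text{age})^2$), with the pooled SE from a common residual
variance. Sampling-variance weights are unusable here — with 2–3
observations per female the per-slope variance estimates have 0–1 degrees
of freedom. The fallback agrees in sign with the hierarchical fit on
non-null data and is exactly invariant to row order and id relabelling.

**Limits of recovery at this design scale.** Rank-dependent slope
*ordering* (high declining faster than medium faster than low) is not
reliably recoverable from the indirect metrics at 19 networks: the
zero-inflated Poisson link inverts the betweenness interaction (the
collapse of high-rank betweenness is absorbed by the zero-inflation
component), and Beta-closeness interactions are power-starved. What is
testable: the interaction is *detected* (retained) for betweenness under
rank-dependent truth, and the generated ordering is visible in
within-individual degree slopes measured directly.

## Global-structure models

`fit_global_structure()` regresses one global metric on the proportion of
old individuals across networks, with average relatedness as a covariate
when available and non-constant, density as a covariate exactly for
diameter and transitivity (density mechanically drives both), diameter
log-transformed, and a Gaussian year random intercept when the records
carry years (simulated ensembles do not; they fall back to OLS). Constant
covariates are dropped with a warning; a constant response produces a
degenerate fit (zero coefficients) with a warning rather than an error, so
ensemble sweeps never die mid-loop.

At full range and large samples the model recovers the simulator's
declining mean degree decisively; restricted to the empirical band at 19
networks per fit, the proportion-old interval overlaps zero in most bouts.
Both behaviours are asserted in the acceptance tests — together they are
the package's statistical-detectability story: *absence of evidence at
empirical scale is the expected outcome even when the individual-level
mechanism is real.*

## Problem sizes used by the tests

The test suite and acceptance script run at the scales stated above:
10 000 verification replicates, 20 000 full-range replicates in 20 bins,
50 restricted bouts of 19 networks, 50 random oracle graphs (n ≤ 30), and
20 + 20 synthetic datasets (non-null and null) for recovery — these are the
package's chosen defaults for a desk-scale reproduction, and the curves
they produce are visually indistinguishable from larger runs.

## Known limitations

- The simulator is static per network; longitudinal structure exists only
  in the synthetic grooming generator's roster.
- The exact perturbation scheme behind published sensitivity analyses of
  this kind of model is rarely printed; the default ±10/±20% grid is this
  package's own and spans plausible estimation error in the linking table.
- Whether empirical betweenness should be computed on weighted or binary
  distances is unsettled; both are available (`weighted = FALSE`), weighted
  is the default.
- Wald intervals on variance-component-poor designs (6 groups, 8 years)
  are approximate; the recovery tests quantify their operating
  characteristics under the generator rather than assuming nominal
  coverage.
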