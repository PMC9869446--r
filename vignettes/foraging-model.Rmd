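---
title: "Colony-level optimal foraging on simple versus complex flowers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colony-level optimal foraging on simple versus complex flowers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiveforage)
```

## The model

A colony of `N` bees runs for a horizon of `T` discrete time steps. A
proportion `r` of bees is sedentary; the remaining
`N_f = N - round(N*r)` forage. Each forager spends each step on one of
two flower types:

* **simple** flowers pay a flat reward `s` per bee per step and need no
  skill;
* **complex** flowers pay according to a logistic learning curve of the
  bee's experience `e` (the number of steps it has already spent on
  complex flowers),

  $$c(e) = m + \frac{K}{1 + e^{-(\alpha e - \beta)}},$$

  rising from about `m` for a naive bee to `K + m` once learning is
  complete. The inflection sits at `e = beta/alpha`, so `beta` acts as an
  inverse learning rate. A meaningful trade-off requires `m < s < K + m`:
  a naive bee does worse on complex flowers, a trained bee better.

Every bee — sedentary or foraging — consumes `q` reward units per step,
and the colony's nectar stores must stay non-negative at every step. The
objective is the total net intake over the horizon. Foragers die with a
constant per-step hazard and are replaced immediately by naive
individuals; experience is never forgotten, but it dies with its bee.

The default parameter set is `T = 100`, `N = 100`, `K = 100`, `m = 10`,
`alpha = 0.45`, `beta = 10`, `s = 50`, `q = 30`, `r = 0`,
`survival = 1`.

### Conventions the results depend on

The model statement leaves a few conventions open; this package fixes
them as follows and treats them as part of its definition of the model:

* **Initial stores are 0** (configurable via `initial_stores`). With an
  empty larder the step-0 energy budget binds exactly: `m_0` naive
  switchers are affordable iff
  `(N_f - m_0) s + m_0 c(0) >= N q`. At the defaults this pins the
  first-step switch to exactly half the pool (50 of 100 foragers: 50
  switchers leave a margin of +0.23 reward units, 51 a deficit of −40).
* **Reward timing.** A bee's reward during a step is evaluated at its
  experience at the *start* of the step, so a first complex visit pays
  `c(0)`.
* **Within-step order of events**: allocate, earn intake, consume
  `N*q`, apply mortality and naive replacement, then increment the
  experience of complex-assigned survivors.
* **Survival semantics.** The survival-to-horizon probability is
  converted to a constant per-step hazard `mu = 1 - survival^(1/T)`
  (memoryless; reproduces the stated probability exactly at `t = T`).
  Expected-value (fractional-bee) dynamics are the default, so every
  headline run is deterministic; a seeded stochastic mode with binomial
  deaths is available and its mean tracks the expected-mode trajectory
  (checked at 1000 replicates in the tests).
* **Whole bees.** Switch counts are integers whenever `N_f >= 2`; a
  single-forager colony (the solitary-bee limit) is optimized in
  fractions of foraging time instead. `N*r` is rounded half away from
  zero.

## The optimizer

The decision object is a *switch schedule* `m_t`: how many foragers are
newly and permanently reassigned from simple to complex flowers at each
step. Restricting to permanent switches is justified by monotonicity —
`c` is increasing and experience is never forgotten, so interrupting a
bee's complex career can only delay its progress along the curve — and
is *validated*, not assumed: on small instances (`N_f <= 3`, `T <= 6`)
an exhaustive enumeration over the full unrestricted allocation space
confirms that permanent-switch schedules attain the global optimum on
every tested instance (50 seeded random instances in the test suite; no
counterexample is known).

Three solvers are provided:

* **greedy** (production method): at each step, switch the largest
  number of unswitched foragers such that (i) the colony stays solvent
  over the whole remaining horizon assuming no further switches, and
  (ii) the survival-discounted marginal value of switching now is
  positive, `sum_j (1-mu)^j (c(j) - s) > 0` over the remaining steps.
  The feasibility cap is computed in closed form from the cumulative
  marginal effect of one extra switcher on future stores.
* **lp**: the same policy class posed as a linear program (objective and
  stores constraints are linear in `m_t`), solved with a dense simplex.
  The continuous solutions of greedy and the LP agree to machine
  precision; with integer output requested, the cumulative switch curve
  is floored to whole bees, which keeps the integer schedule within one
  bee of the relaxation at every step. Flooring each `m_t` separately
  would discard late fractional switches and lose several per cent of
  the objective; flooring the cumulative curve loses under 0.1% at the
  defaults.
* **bruteforce**: exact forward dynamic programming over experience
  multisets. Because cumulative net intake equals the gain in stores,
  two histories reaching the same experience multiset at the same step
  are ranked by stores alone, so keeping the maximum-stores history per
  state enumerates the full policy space losslessly. A plain recursive
  enumeration cross-checks the dynamic program in the tests.

A note on integrality: the exhaustive oracle works in whole bees while
the LP is a continuous relaxation, and generic instances have a nonzero
integrality gap. The test suite therefore validates two exact pairs —
integer greedy against integer enumeration, and continuous greedy
against the LP — rather than pretending all three coincide.

### Headline behaviour at the defaults

Half the foragers switch at step 0, the stores hover near zero while the
pioneers learn, and the rest of the pool switches in an accelerating
wave as the pioneers' surplus finances it; the last simple forager
leaves at step 22, independently of colony size (the model is linear in
`N`). With a short horizon (`T = 50`) the late-switch wave never pays
for itself and the colony stays split roughly in half for the whole run.

## Parameter sweeps

`sweep_horizon()`, `sweep_sedentary()`, `sweep_colony_size()`,
`sweep_learning_rate()` and `sweep_survival()` re-optimize along one
axis each and return tidy summaries plus per-step trajectories;
`table2_report()` checks the five directional predictions (horizon up →
more complex foraging; sedentary fraction up → less and later; colony
size → no effect on fractions; `beta` up → less and later; survival up →
more). "Amount of complex foraging" is measured as complex bee-steps:
the sum over time of the expected number of foragers on complex
flowers.

The horizon grid `{50, 60, 80, 100}` and the learning-rate grid
`{10, 13, 16, 17}` are the standard ones for this model; the sedentary
grid `{0, 0.1, 0.2, 0.3}` and survival grid `{1, 0.9, 0.7, 0.5, 0.3}`
are this package's choices, spanning the feasible range (the sedentary
proportion is capped by the solvency bound `r <= 1 - q/s = 0.4` at the
defaults) and the range over which mortality visibly erodes the complex
workforce. All grids are arguments.

Two measurement choices deserve a note. First, colony-size invariance
is exact for the allocation *fractions* under continuous allocations;
with whole bees it holds up to one-bee rounding, so the report uses a
tolerance of one bee at the smallest colony in the grid (and the test
suite additionally checks exact invariance in continuous mode). Second,
under mortality one can count either bees *currently* on complex
flowers or bees *ever switched*; the two diverge when replacements
accumulate in the simple pool, so trajectories carry both columns
(`n_complex`, `cum_switched`).

## Interaction-table analytics

The descriptive layer consumes a visitation table with one row per
captured bee: `bee_species`, `sociality` (binary solitary/eusocial —
records with intermediate sociality are expected to be dropped
upstream, and `read_interactions()` drops any that remain, with a
count), `proboscis_mm`, `plant_species`, `symmetry` (radial/bilateral),
`corolla_mm`, plus `bee_genus`, `round`, `plot` labels.

Conventions:

* Bilateral symmetry is the binary complexity proxy; a corolla tube is
  "deep" when *strictly* longer than 3 mm (a 3 mm tube codes shallow).
  The threshold is an argument.
* Group summaries are species-level by default: each species
  contributes one proportion (or one mean depth), and the group mean and
  standard error (`sd/sqrt(n_species)`, sample standard deviation with
  divisor `n - 1`) are taken across species, so abundant species do not
  dominate. Visit-weighted versions are computed alongside
  (`group_mean_corolla(weighting = "both")`) because either convention
  is defensible for depth summaries; the population-sd variant of the
  standard error is also available. Species-level statistics are
  invariant to row order and to duplicating the table, which the tests
  exercise.
* Records missing the traits an analysis needs are excluded per
  analysis, with counts reported.

`fit_choice_regression()` is a deliberately simplified stand-in for a
phylogenetic generalized linear mixed model: a maximum-likelihood
binomial logit of the flower-choice flag on sociality, proboscis length
and their interaction, with *no* random effects. It does not reproduce
the Wald statistics a phylogenetic model would give. Its statistical
behaviour is characterized by simulation against the generator: with
independent species effects absent it is well calibrated (coefficient
coverage at the nominal level, type-I error near 5%), and with a
phylogenetically correlated species effect its standard errors become
anti-conservative — which is precisely why a phylogenetic model is the
right tool on real data.

## The synthetic generator

`generate_interactions()` emulates the statistical structure the
analytics assume, with every margin and distribution fixed once:

* 58 bee species (20 eusocial), 67 plant species, and a
  negative-binomial visit count per species with mean 187 and
  dispersion 1.2 — matching the margins of the field dataset this
  schema mirrors (about 10.8k rows).
* Proboscis length log-normal around 4 mm (`sdlog = 0.45`), the
  observed scale for temperate bee communities; corolla depth gamma
  with shape 2 and scale 1.8 mm (median near 3 mm, the depth-coding
  threshold).
* Per visit, the probability of choosing a bilateral (and,
  independently, a deep) flower is
  `plogis(b0 + b1*eusocial + b2*proboscis + b3*eusocial*proboscis + u)`,
  with `u` a per-species effect drawn from Brownian motion on a random
  coalescent phylogeny, scaled so `phylo_signal` is the tip variance.
  The visited plant is then sampled from the plants in the chosen
  symmetry-by-depth cell (the first four plant species are forced to
  cover all four cells so every outcome has a flower to land on).

What it does *not* emulate, and what passing tests therefore do not
show about real data: sampling-round and plot structure are labels
only, with no effect on choices; proboscis length has no within-species
variation; the bilateral and deep choices share one coefficient vector
and species effect and are conditionally independent given it, whereas
real symmetry and depth are correlated plant traits; and visit counts
are independent across species. The generator is a test harness for
the analytics, not a community model.

## Numerical choices

* Stores feasibility is checked to a tolerance of `1e-6` reward units
  (continuous solutions sit exactly on the constraint boundary);
  bookkeeping identities are asserted to `1e-9`.
* The greedy integer cap uses `floor(x + 1e-9)` so that an exactly
  affordable switch count is not lost to rounding error.
* The logistic curve saturates to `K + m` in double precision once
  `alpha*e - beta` exceeds about 36; property tests restrict strict
  monotonicity and strict bounds to the numerically meaningful domain.
* Oracle comparisons use an absolute tolerance of `1e-6` on objectives.

Problem sizes in the test suite are chosen to make every check exact or
statistically well-powered while keeping the whole suite fast: oracle
validation uses 50 random instances with `N_f <= 3`, `T <= 6`;
stochastic-versus-expected agreement uses 1000 replicates of a
30-bee, 10-step colony; regression calibration uses 200 replicates of
the full 58-species community at 200 visits per species.

## Known limitations

* The greedy solver's feasibility lookahead assumes no further switches;
  this is conservative and could in principle under-switch on exotic
  parameter sets. No instance where it loses to the exhaustive optimum
  has been found, but the oracle only covers tiny colonies.
* Expected-value control: the optimizer plans against mean mortality,
  not against the realized stochastic process (no stochastic dynamic
  programming).
* No travel costs, flower depletion, social learning, or interactions
  between colonies; the model is linear in the number of bees by
  construction.
* The regression stand-in must not be used for inference on data with
  phylogenetic structure; it exists to make the pipeline testable and to
  demonstrate the consequence of ignoring that structure.
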