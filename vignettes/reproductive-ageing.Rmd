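---
title: "Decomposing reproductive ageing in long-lived seabirds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing reproductive ageing in long-lived seabirds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(reprosen)
```

## The problem

Long-term colony monitoring of long-lived seabirds yields longitudinal
breeding histories: one row per bird per breeding season, with a binary
outcome (chick fledged or not). At the population level, breeding success
typically rises through early adulthood, peaks somewhere between the
mid-teens and mid-twenties, and then declines or plateaus. That
population-level trajectory confounds four distinct processes:

* **within-individual improvement** early in life (experience, foraging
  skill, mate familiarity);
* **within-individual senescence** late in life;
* **selective appearance** — birds that recruit at different ages may differ
  in average quality, changing the composition of young age classes;
* **selective disappearance** — birds that die young may differ in average
  quality, changing the composition of old age classes.

On top of these, performance can change discontinuously at the *first*
breeding attempt (inexperience) and at the *final* attempt before death
(terminal effects). `reprosen` implements the full analysis chain for
separating these processes, together with an individual-based simulator that
generates data with known truth so that every inference step can be
validated.

## The model

All models are Bernoulli GLMMs with a logit link and two crossed random
intercepts,

$$
\mathrm{logit}\,P(y_{it}=1) = \mathbf{x}_{it}^\top\beta
  + u_i + v_t,\qquad
u_i \sim N(0,\sigma^2_{\mathrm{ind}}),\quad
v_t \sim N(0,\sigma^2_{\mathrm{yr}}),
$$

where $i$ indexes birds and $t$ breeding seasons. Fitting uses the Laplace
approximation to the marginal likelihood via `lme4::glmer` (`nAGQ = 1`), the
standard approach for crossed binary mixed models; `fit_glmm()` wraps it
behind a design-matrix interface and enforces the package's conventions
(explicit intercept column, separation detection at $|\beta| > 15$, boundary
variances reported as 0 but still counted as parameters). AIC is
$-2\ell + 2k$ with $k$ = number of fixed effects + one per random-effect
variance, *including* variances estimated at the boundary — the count
matters because all model selection below is driven by $\Delta$AIC
thresholds.

Two independent likelihood evaluators exist purely for verification:
`laplace_loglik()` (a standalone Newton-mode Laplace evaluator that
reproduces the engine's `logLik` at the fitted optimum) and
`loglik_oracle()`, a dense Gauss–Hermite quadrature that is exact up to
quadrature error. With crossed factors the marginal likelihood does not
factorise; the oracle exploits the fact that *conditional on* the values of
one factor's effects, the other factor's levels are independent. It
therefore integrates the smaller factor on a dense product grid (one
dimension per level) and the larger one by factorised one-dimensional
quadrature. This is only feasible for a handful of levels, which is why it
is a test oracle and not a fitting engine. The Laplace approximation is
near-exact when each random-effect level carries reasonable information and
the variances are modest ($\sigma^2 \lesssim 0.1$ in our fixtures); with
only a few Bernoulli observations per bird and $\sigma^2 \approx 0.5$ the
approximation error grows to order $0.1$ on the log-likelihood. The test
suite asserts 1e-2 agreement in the well-supported regime and ties the
engine to the evaluator at the optimum.

## Population-level age functions

`scan_thresholds()` compares piecewise-linear ("broken-stick") age functions
across a grid of integer breakpoints; `make_age_basis()` constructs the
bases (continuous at the breakpoints by construction; ages are centred on
their mean before basis construction, which only reparameterises the
intercept). Null, linear and quadratic functions are fitted alongside. The
best model minimises AIC, with exact ties broken toward fewer parameters and
then the earlier breakpoint. The default candidate grid runs from
(min observed age + 2) to (max observed age − 2), requiring at least 25
observations on each side of the split so no hinge column degenerates.

A 95% confidence interval for the breakpoint (`threshold_ci()`) is the
contiguous run of candidates around the best one whose deviance lies within
$\chi^2_1(0.95) = 3.841$ of the minimum. Because the deviance is the Laplace
approximation, the interval inherits that approximation; it is also a
profile over a *discrete* grid, so its endpoints are integer ages.

When several candidates fall within $\Delta\mathrm{AIC} < 2$ (strictly) of
the best model, `select_and_average()` forms the top model set, assigns
Akaike weights $\omega_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$ over
that set, and averages the *predicted* age curves on the probability scale.
Averaging predictions rather than coefficients is deliberate: coefficient
averaging across different bases (linear vs quadratic vs piecewise) is not
well defined. Predictions and their delta-method standard errors come from
the fixed effects only — curves describe an average bird in an average year.

## Early/late decomposition

Each species × sex dataset is split at the best single-threshold breakpoint
(an explicit override map is supported — e.g. forcing the female
wandering-albatross split to 18 so that all birds have begun breeding during
"early adulthood"). Within each phase, within-group centring separates
within- from among-individual effects:

* **early** (known recruits only, so the first observed attempt is the true
  first attempt): `years_since_first` = age − age at first reproduction
  (within-individual improvement), `age_first` (selective appearance),
  `is_first_attempt` (first-attempt penalty);
* **late** (presumed-dead birds only, so the last observed attempt is the
  true last): `years_before_death` = age at last reproduction − age (a
  *positive* coefficient means success falls approaching death),
  `age_last` (selective disappearance; negative means good breeders die
  young), `is_last_attempt` (terminal effect).

Both counters are measured in calendar years, not attempt counts: biennial
breeders skip seasons, and the calendar interpretation keeps the slopes
comparable across breeding tactics. The death proxy is disappearance from
the colony for a species-specific number of years (4 for the annual breeder,
5 for the biennial ones, `default_gap_rule()`); birds failing the rule are
censored and excluded from late-phase models rather than imputed. A bird can
be eligible for both phases, either, or neither — the two filters are
independent.

Term importance is reported as $\Delta$AIC on removal (AIC without the term
minus AIC with it, positive = the term improves fit), always refitting on
identical rows with the identical random-effect structure. Robustness terms
(partner change, years since last attempt, previous outcome, and their
interaction) can be added to the late model without altering the headline
terms. `species_interaction_model()` fits the combined-species model with
species × term interactions (treatment contrasts, configurable reference),
and `compare_sex_ages()` asks which parent's age explains more variation in
nest outcome by dropping each sex's threshold basis in turn (random
structure: nest-pair identity plus year by default; the choice is
switchable because the field convention is not settled).

## What the simulator emulates — and what it does not

`simulate_population()` generates breeding histories from the same model
family the analysis assumes, plus the life-history structure that makes the
inference non-trivial:

* recruitment at a species-typical age (discretised normal, truncated at 5);
* a piecewise-linear age trajectory with known breakpoint and slopes,
  parameterised so `beta0` is the logit success at the peak;
* latent individual quality `u_ind` and shared year effects on the logit
  scale (defaults $\sigma_{\mathrm{ind}} = 0.5$,
  $\sigma_{\mathrm{yr}} = 0.3$);
* a first-attempt penalty and a terminal effect applied to the true final
  attempt before death;
* quality-dependent annual survival:
  $\mathrm{logit}\,P(\text{survive}) = \mathrm{logit}(s_0) + c\,u_{\mathrm{ind}}$,
  with $c < 0$ producing selective disappearance of good breeders. Driving
  disappearance from the *latent* quality rather than realised outcomes
  keeps the confounding interpretable and avoids feedback loops;
* breeding-tactic schedules: annual (gap 1 after either outcome), biennial
  (gap 2 after success, 1 after failure), each plus a geometric number of
  extra deferral years (capped at 3). The wandering-albatross-like profile
  uses the same structure with higher deferral (the observed "about a third
  of birds defer beyond the expected year"); the dependence of deferral on
  the *timing* of failure within a season is not modelled.

Default parameter values are anchored to the published descriptive
statistics of the three Bird Island study populations: recruitment ages near
the observed means (10, 13.4 and 10 years), intercepts calibrated once so
realised mean annual success matches the observed species means (0.317,
0.403 and 0.631), breakpoints and slopes in the range indicated by the
population-level threshold models, and first-attempt/terminal effects of the
magnitude seen in the decomposition tables. They were fixed before any
recovery experiment and are not tuned per test.

One structural point deserves emphasis, because it surfaced in validation
and mirrors a point the field literature makes about biennial breeders:
under a biennial tactic, a successful attempt is followed by a longer gap
(2+ years) than a failure (1 year), so a successful bird is *more* likely to
die before its next attempt. The final-attempt flag is therefore positively
associated with success even when the generative terminal effect is zero,
and fitted terminal effects in biennial populations are biased upward
relative to the structural parameter. Two consequences: terminal-effect
estimates from biennial simulations should be read as the *combined*
biological-plus-schedule effect, and null-calibration experiments (checking
that no headline term earns $\Delta$AIC > 2 when nothing is simulated) must
use the annual profile, whose gap is outcome-independent — the only
configuration in which all six headline terms are generatively null.

A related caveat concerns selective appearance. With an age-driven
trajectory, the within-group-centred design loads the early slope onto
*both* `years_since_first` and `age_first`: the no-appearance null is
"among-coefficient equals within-coefficient", not "among-coefficient is
zero". Near-zero `age_first` estimates in real data indicate that
improvement tracks breeding *experience* rather than age per se — a
distinction the simulator (which is age-driven) does not reproduce. Recovery
checks for `age_first`/`age_last` therefore assess sign consistency, not
magnitude.

Other things the simulator deliberately omits: density dependence, bycatch
mortality, pair-formation dynamics (partner identities are decorative labels
with a fixed change rate, used only to exercise the robustness terms), and
any quality–recruitment-age link. Passing recovery tests therefore show the
*estimators* work when the model family is correct; they say nothing about
model misspecification in field data.

## Numerical choices

* Optimiser: `lme4`'s default for `glmer`; derivative checks disabled for
  speed (`calc.derivs = FALSE`). Convergence flags are recorded on every
  fit.
* Separation: any fixed effect exceeding 15 on the logit scale raises an
  error rather than returning a silently divergent fit.
* Degenerate designs: constant or collinear columns in the decomposition
  models are dropped with a recorded warning (e.g. `age_last` when all birds
  share one age at last reproduction); the intercept is never removable.
* Quadrature: 25 Gauss–Hermite nodes per factorised dimension; the dense
  product grid's per-dimension order is reduced automatically to keep the
  grid below 2e5 points, and more than 6 levels in the smaller factor is
  refused.
* Ties: exact AIC ties break toward fewer parameters, then the earlier
  threshold.
* Missing values: robustness covariates that are undefined on first attempts
  (`years_since_last`, `previous_outcome`) drop those rows from the late
  model only when the terms are requested.
* All randomness flows from a single seed per simulation config; the
  analysis stages themselves are deterministic.

## Problem sizes used in validation

The bundled validation experiments use deliberately modest sizes chosen to
exercise the statistics rather than the hardware: oracle fixtures of 6–15
birds × 3–4 seasons; threshold recovery with 25 replicates of 800 birds
(true breakpoint at 20, slopes +0.15/−0.10 logits per year, scan grid
16–24); decomposition sign recovery with 25 replicates of 400 birds; null
calibration with 50 replicates of 250 birds. At these sizes the modal
recovered breakpoint is within ±2 years of truth, the profile CI covers the
true breakpoint in the large majority of replicates, the simulated
first-attempt, terminal and disappearance signs are recovered in ≥80% of
replicates, and null terms exceed $|\Delta\mathrm{AIC}| > 2$ at roughly the
nominal chi-square rate.

## Known limitations

* The Laplace likelihood (and hence AIC, the breakpoint CI and the model
  weights) is an approximation; its quality degrades with few observations
  per level and large variance components.
* The breakpoint CI treats the threshold as one parameter profiled on an
  integer grid; an alternative $\Delta\mathrm{AIC} \le 2$ rule is available
  via the scan's AIC profile but is not the default.
* Published coefficient values from the real colony data cannot be
  reproduced from this package alone — they require the archived field
  dataset and exact parity of the fitting software's approximation; the
  external-CSV ingestion path (`read_records()` on a deposited table) is
  supported and tested on synthetic stand-ins.
* Mark–recapture survival estimation, imputation of unobserved attempts and
  population trend modelling are out of scope.

## A worked run

```{r demo}
cfg <- read_analysis_config(
  system.file("extdata", "analysis_demo.yaml", package = "reprosen")
)
cfg$out_dir <- "reprosen_demo"
bundle <- run_analysis(cfg)
bundle$groups[["GHA.F"]]$scan      # breakpoint profile and CI
bundle$groups[["GHA.F"]]$late     # late-adulthood decomposition
```

The same pipeline is exposed on the command line by
`inst/cli/reprosen-pipeline` (subcommands `simulate`, `analyze`, `demo`).
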