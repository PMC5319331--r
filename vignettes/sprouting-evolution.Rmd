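---
title: "Modelling the evolution of sprouting probability under climate change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolution of sprouting probability under climate change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sproutess)
```

## The problem

Perennial herbs capable of vegetative dormancy face a yearly decision
that is not a decision at all but a heritable propensity: sprout above
ground — and pay the survival costs of growth and reproduction while
gaining the chance to flower — or remain below ground on stored
reserves. `sproutess` treats the intercept of the logistic sprouting
model as that propensity, asks what value of it natural selection
favours under given climatic conditions, and tracks how the favoured
value moves as climate changes.

## Vital-rate models

Every demographic rate is a generalized linear model with a year-level
intercept:

* **survival** from year *t* to *t*+1 (binomial, logit);
* **sprouting** in year *t*+1 conditional on survival (binomial); its
  intercept carries the evolving deviation `d_spr`;
* **size** in year *t*+1 conditional on sprouting (Poisson, log),
  truncated to `1..max_size` when used;
* **flowering** in year *t*+1 conditional on sprouting (binomial), as a
  function of the *target* size;
* **flower count** (and, where configured, fruiting probability and
  fruit count) in the same year (Poisson / binomial).

Covariates are raw-scale size and flowering status in year *t*; under
the *historical* design also size and flowering in year *t*−1 and the
growth increment `grw_t`; under the *age × stage* design, years since
first record; plus two climate covariates (for a continental-meadow
system: winter frost days and annual precipitation; for a chalk-grassland
system: April–May sunshine hours and February–May precipitation) and,
during screening, local conspecific density.

**Year effects.** The default backend fits shrunken per-year offsets:
raw year deviations are estimated against the fixed linear predictor,
the year variance is estimated by method of moments, deviations are
shrunk by `sigma2 / (sigma2 + se^2)` and the fixed effects refit with
the shrunken offsets. This preserves the year-deviation interface the
stochastic matrices need without requiring a mixed-model engine in the
inner loops; `backend = "glmm"` plugs in `lme4::glmer()` for the same
model, and the two agree closely on simulated data (see
`test-vital-rates.R`). AICc counts the fixed coefficients plus one
year-variance term.

**Model selection.** `enumerate_reduced_models()` lists every subset of
the global model respecting marginality; `select_model()` takes the
lowest AICc unless a model within 2 units has strictly fewer parameters.

**Truncated size fitting.** Sizes conditional on sprouting are at least
1, so the plain-Poisson score targets the wrong mean and the generating
coefficients are not recovered at realistic size means. For the size
response `fit_vital_rate(..., truncated = TRUE)` maximizes the
zero-truncated Poisson likelihood by Newton scoring; the matrix builder
still truncates and renormalizes the fitted Poisson over `1..max_size`
downstream. This is the one place the fitting likelihood deviates from
an ordinary GLM, and it exists to keep estimation consistent with the
conditional structure of the data.

## State spaces and matrices

Two designs are built in:

* `cypripedium_state_space()` — the historical stage-pair space: 19
  mature states (dormant, vegetative 1–9 sprouts, flowering 1–9) paired
  across consecutive years (361 pairs) plus a fixed juvenile pathway
  (seed→protocorm 1–3→new seedling, seedling years 1–2 with 0/1/2
  sprouts, and entry of year-2 seedlings into six designated adult entry
  stages), 34 juvenile pairs, 395 states in all. The printed total fixes
  the juvenile decomposition; the entry-stage set (dormant, V1, V2, F1,
  F2, V3) is the unique reading consistent with the stated stage lists
  and is overridable.
* `ophrys_state_space()` — the age × stage space: 10 adult age classes
  (the tenth absorbing, modelling stasis in old adults) × 17 mature
  states (dormant, vegetative 1–8, flowering 1–8) plus two protocorm
  stages and a seedling stage, 173 states.

Transitions obey the chaining rule ((i,j) can only reach (j,k)) or the
age-increment rule; fecundity arcs run from flowering states to the
first juvenile state, with seeds produced in year *t* entering it in
year *t*+1 (pre-breeding census). Matrix entries follow
`a_D = S(1-P)`, `a_k(V) = S P g_k (1-F_k)`, `a_k(F) = S P g_k F_k`, so
each adult column's transition mass sums exactly to its survival —
checked to 1e−12 across random builds. Growth mass beyond the size cap
is folded back by renormalizing the truncated Poisson. Juvenile-stage
rates are literature-style configuration (`fecundity_params()`), not
fitted constants, and the ±10% perturbation helper supports the
sensitivity harness. The optional `seedling_stasis` switch makes
unsprouted seedlings remain seedlings rather than entering the dormant
adult stage; the analogue fixtures use it because delayed emergence must
carry a real cost for juvenile sprouting suppression to matter.

Stochastic builds resample a monitored year — its fitted per-rate
deviations together with its climate values — when a fitted year table
is present, and otherwise draw year deviations from each rate's
year-effect standard deviation and climate values from their configured
normals (truncated at zero for precipitation, rounded for frost days).

## Density dependence

Adaptive dynamics needs competition, supplied by one negatively
density-dependent rate modified by a Ricker term. The modifier acts
*additively on the link scale*, `value + α − βN`: probabilities stay in
[0, 1] without clipping, and for a log-link scalar rate the model
reduces exactly to the classic Ricker map `N' = N exp(α − βN)` with
equilibrium `α/β`. Density is total individuals per square metre over
the plot area. Calibration profiles α exactly: the link offset `c*` at
which the modified matrix has λ = 1 is root-found, `α = c* + β ×
plateau`, making the stationary density equal the target for any
dynamically stable β; β is then reduced from `|c*|/plateau` until the
founder iteration (one plant in the first emergent entry state;
convergence when the relative density change stays below 1e−6 for 50
consecutive steps, cap 5000) settles within 2% of the target.
`select_dd_rate()` walks the negatively screened rates in a documented
priority order and returns the first that calibrates.

## Adaptive dynamics

The resident equilibrium solves λ(N) = 1 by Brent root-finding to near
machine precision; the stationary structure is the dominant right
eigenvector. A rare mutant with deviation `d_mut`, seeded proportional
to the resident structure, is projected in the resident's environment;
deterministic invasion fitness is the converged per-step log growth of
the mutant share, which equals the log dominant eigenvalue of the mutant
matrix at the resident density (rare-mutant linearity; verified to 1e−6)
and is exactly zero for a neutral clone. Fitness is measured on the
*log* scale of the mutant *share* averaged per step, the one convention
in which neutrality is exactly zero. Stochastic fitness projects
resident and mutant together through drawn years with shared deviations
and climate, density set by their combined total.

`find_ess()` brackets a sign change of the selection gradient (central
difference, step 1e−3), shrinking the user bounds inward to the viable
trait window when the resident has no equilibrium at the edges, and
classifies the root by the gradient slope (convergence stability) and
the mutant-direction curvature (local fitness maximum). `pip()` maps the
full fitness landscape; `bootstrap_ess()` resamples individuals with
replacement (whole life histories move together), refits, recalibrates
and relocates the ESS; failed replicates are excluded and more than 20%
failures raises a reliability warning. The full analysis uses 1000
replicates; the desk-scale default is 100.

**Why an interior optimum exists at all.** With the density modifier
acting additively on the same logit scale as the trait, a shift in the
resident's deviation is absorbed one-for-one by the equilibrium density
offset, so density dependence on adult sprouting alone adds no selection
on the intercept. Two ingredients break the translation: density also
suppresses *juvenile* sprouting, which the adult trait does not shift
(`d_spr` applies to adults only), and survival carries a cost of growth
across years (negative `grw_t` and consecutive-emergence effects) that
makes fitness non-monotone in the realized sprouting level. The fixtures
are built on exactly this structure. Numerical exploration during
development showed that an ahistorical age × stage model with an
additive-logit modifier on a rate unlinked to the trait (e.g. adult
survival) yields a boundary optimum — always-sprout — for every viable
parameterization tried; this is why all three trajectory fixtures use
the stage-pair design, and why the age × stage fixture is exercised for
equilibrium and neutrality rather than trajectory shape.

## Climate handling and forecasting

`bias_correct()` shifts each simulated variable by the difference of
overlap means (optionally a ratio for precipitation), so corrected
overlap means equal observed means exactly. `running_mean_inputs()`
averages each year with its 25 preceding years (26 values; incomplete
windows are omitted, and the off-by-one is pinned by an arithmetic-ramp
closed form in the tests). Derived predictors absent from simulated
output (frost days, sunshine hours) are imputed by least squares on
shared variables with physical-bound clipping, and monthly shortwave
radiation converts to sunshine hours through the Suehrcke relation
(squared clearness-index ratio × day length), with site constants as
configuration.

`optimal_trajectory()` re-optimizes the ESS per year under that year's
26-year mean climate, warm-starting from the previous optimum;
non-bracketing years are recorded as missing, never interpolated.
`lambda_series()` evaluates annual deterministic λ at each year's
*annual* climate values with `d_spr = d*(Y)` and 0, density-free
(asymptotic rates). Because the ESS maximizes density-coupled invasion
fitness rather than density-free λ, the evolved series can sit
marginally below the static one; on the fixtures the difference is
below 1e−3 and the tests assert exactly that. `ltre()` decomposes the
difference between two matrices through sensitivities of the dominant
eigenvalue at their element-wise mean, with category sums (stasis /
growth / shrinkage × dormancy / vegetative / flowering targets, plus
fecundity and juvenile arcs) that partition the contribution matrix.

## The synthetic-data module

`simulate_individuals()` draws each individual-year in the conditional
order survival → sprouting → size (truncated Poisson) → flowering →
flower count (→ fruiting chain), with shared per-year intercept
deviations, climate fed at the appropriate lags, uniform plot positions,
and optional density feedback when a generating spec uses it.
`censor_to_observed()` produces the observer's reconstruction:
individuals appear at first emergence, interior non-emergent years
become dormant rows, and a trailing unseen run of at least `k` years
(default 3) flags the individual ambiguous — under the default
`presume_dead` rule its last transition is scored as death, shorter
trailing gaps are right-censored. The generator emulates binomial and
Poisson vital-rate processes with year-level heterogeneity and
dormancy-driven censoring; it does not emulate spatial dispersal,
observation error in size, mycorrhizal dynamics or seed-bank genetics,
so passing tests speak to the estimation and projection machinery, not
to those field complications.

**Fixture conditions.** The three analogue fixtures share a compact
stage-pair space (maximum size 3, entries dormant/V1/V2) with a plateau
of 2 plants per m² on a 100 m² plot: survival intercepts near 0.9 for
dormant plants, a consecutive-emergence cost, germination rates of
order 1e−2 per seed with ~1000 seeds per fruit, and standardized climate
covariates. The scenarios hold a 26-year baseline and then ramp frost
days down by 2 standard units (warming analogue), run a completed
precipitation excursion of 1.5 units, or ramp sunshine and spring
precipitation up by 1 unit. These values were fixed while constructing
the fixtures — chosen so each analogue is viable with an interior ESS in
its sign structure — and are not tuned thereafter.

## Numerical choices and limitations

* Equilibrium densities are root-found to `.Machine$double.eps^0.75` so
  diagonal neutrality holds to 1e−8; power iteration stops at 1e−14 on
  successive log growth.
* Deterministic invasion fitness iterates past the nominal 100 steps to
  convergence; the `steps` argument governs the stochastic average.
* Problem sizes in the shipped tests (state spaces of order 4–395,
  500 × 20 recovery cohorts, 30-replicate screening, 61-year
  trajectories, 5-replicate bootstraps) were chosen as desk-scale
  defaults that keep the full suite in the low minutes.
* Separation in a year's data is capped (|offset| ≤ 8 with inflated SE)
  and shrunk toward zero; fits with any |coefficient| ≥ 25 are flagged
  non-converged and excluded from selection.
* Ties in model selection break by AICc then lexicographic term order,
  so selection is deterministic.
* The LTRE is first-order: on strongly nonlinear contrasts the category
  sums still partition the contribution matrix, but their total tracks
  Δλ only to within ~10%.
* No random slopes, spatial random effects, Bayesian fitting, integral
  projection variant, periodic seasonal matrices, multi-trait
  coevolution or stochastic-λ forecasting.
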