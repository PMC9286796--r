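---
title: "Waiting times to establishment: model, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Waiting times to establishment: model, simulator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`waitest` estimates, for every 5 × 5 km quadrat of an invasion monitoring
grid, the number of years between the first detection of the invader and
its establishment, and then asks which environmental and anthropogenic
characteristics of a quadrat speed establishment up or slow it down. This
vignette is the package's own account of the science: the probabilistic
establishment model, the regression stage, the synthetic data generator
used to verify both, and the design decisions taken where more than one
reasonable choice existed.

## The waiting-time statistic

Pheromone-trap networks over an invasion's transition zone — the band
between the fully infested area and uninvaded territory — yield yearly
trap catches. Aggregated to a quadrat grid, the yearly **median** catch
per quadrat (robust to trap number and skew) gives a per-quadrat time
series. Two events are read off it:

* **Detection** — the first year in which the quadrat's median catch
  reaches one moth.
* **Establishment** — the first year in which the posterior probability
  that the quadrat's median catch is zero falls below 0.01.

The waiting time is the difference. A fixed count threshold would flip
back and forth under measurement error and demographic noise; phrasing
establishment as a tail probability of a fitted time-series model absorbs
that uncertainty, at the cost of needing a full posterior per quadrat and
year.

Before any fitting, three data rules apply. Trap records within 1.5 km of
an area treated that same year are discarded (treatment suppresses
catches locally; the buffer also exceeds the insect's typical dispersal).
Quadrats with fewer than 10 moths caught in total over the whole record
are treated as never invaded. Quadrats whose very first recorded median
is already positive were likely established before monitoring began, and
are excluded as left-censored.

## The local-level model and its Gibbs sampler

Each quadrat series is modeled on the transformed scale
\(z_t = \log(1 + y_t)\) by the local-level structural form

\[
z_t = \mu_t + \varepsilon_t, \qquad
\mu_{t+1} = \mu_t + \eta_t, \qquad
\varepsilon_t \sim N(0, \sigma^2_\varepsilon),\;
\eta_t \sim N(0, \sigma^2_\eta),
\]

a Gaussian random-walk level observed with noise. The `log1p` transform is
the default because a Gaussian on raw counts puts mass below zero, which
makes "probability of zero moths" ill-defined; an identity transform is
available (`mcmc_config(transform = "identity")`) for sensitivity checks.

Fitting is by Gibbs sampling, alternating

1. a **forward-filter backward-sample** (FFBS) draw of the entire level
   path \(\mu_{1:T}\) given the variances — a Kalman forward pass
   followed by backward sampling from the exact conditional of each state
   given the next; and
2. conjugate inverse-gamma draws of \(\sigma^2_\varepsilon\) (given the
   observation residuals) and \(\sigma^2_\eta\) (given the level
   increments).

Missing years skip the measurement update, so the level diffuses through
gaps. In known-variance mode step 2 is skipped and the retained paths are
i.i.d. draws from the exact smoothing distribution — the package's test
suite exploits this to compare the sampler, point by point, against an
independently coded closed-form Kalman smoother.

**Priors.** Both variances get inverse-gamma(2, *c* · Var(*z*)) priors
with *c* = 0.5 for the observation variance and *c* = 0.05 for the level
innovation — weakly informative, scale-adaptive, and encoding that the
level drifts more slowly than the observations scatter. Var(*z*) is
floored at 0.5: yearly medians are discrete, and a quadrat that sits at a
nearly constant low median produces a transformed series whose sample
variance collapses, which would make the priors degenerate and the
forecasts overconfident — a small founder population oscillating between
median 0 and 1 would be declared "confidently present" on the strength of
essentially no variance information. The floor is the package's guard
against that failure mode; it is immaterial once a series has real
spread. Defaults are 2000 iterations with a 500-draw burn-in, and the
initial level is diffuse around the first observation.

**Forecast and probability of zero.** For target year *t*, the model is
refit on an expanding window of all years up to *t* − 1 (at least 10
observed years — the calibration minimum, so a series starting in 1985
yields establishment probabilities for 1995 onwards). Each retained draw
propagates the level one step, adds observation noise, and inverts the
transform; the probability of a zero-moth median is the fraction of
predictive draws below 0.5 — a median that rounds to zero. An alternative
latent-level criterion (posterior probability that the level itself is
below the one-moth line) is available via
`mcmc_config(criterion = "level")`. Establishment is the first year at or
after detection with probability strictly below 0.01 (ties at the
threshold do not establish).

The one-step-ahead design has a knowable consequence: the model can only
flag establishment the year *after* the catches have risen, so estimated
establishment lags truth by roughly one year on synthetic data. The
recovery tests account for this by checking mean absolute error, not
exactness.

## The regression stage

For the quadrats that transition from undetected to established inside
the study window, waiting time is regressed on ten drivers (seasonal
climate means, elevation, host basal area, human population density,
wood use, highway density, and two fragmentation measures) plus two
**background variables** forced into every model: the year of first
detection (absorbing the spatiotemporal structure of the spreading front)
and the mean waiting time of the surrounding 3 × 3 neighborhood
(absorbing propagule pressure from already-invaded neighbors). The
neighborhood mean excludes the focal quadrat — "surrounding" is read as
exclusive — and neighbors without a computed waiting time are ignored
rather than imputed; an inclusive variant is available via
`include_focal = TRUE`. Climate drivers are multi-year means over the
establishment window (`climate_average()`).

Models are linear mixed models with a random intercept per level-IV
eco-region (the fine nested classification; the coarser level-II
subregions define reporting strata), fitted by maximum likelihood —
required for AIC comparison across fixed-effect structures; a REML refit
of the winner is available for reporting. `all_subsets_aic()` enumerates
all \(2^k\) driver subsets, always retaining the background variables and
the random intercept, and picks the lowest AIC; ties break toward fewer
parameters, then lexicographic term order. Predictors are z-standardized
within each model's fitting subset so coefficients share an axis.
Collinearity among the selected terms is checked with variance inflation
factors computed from first principles, \(1/(1 - R^2_j)\).

Three variance-explained measures follow the mixed-model decomposition
with \(\sigma^2_f\) the variance of the fixed-effects linear predictor:
marginal \(R^2 = \sigma^2_f / (\sigma^2_f + \sigma^2_\alpha +
\sigma^2_\varepsilon)\), conditional \(R^2\) adds the random-intercept
variance \(\sigma^2_\alpha\) to the numerator, and the **driver-only**
marginal \(R^2\) restricts the linear predictor to the driver terms
(coefficients from the full fit) before taking its variance — exact when
predictors are orthogonal, and documented as an approximation otherwise,
chosen because it is reproducible from any fit without refitting.

## What the synthetic generator emulates

The simulator exists so that every stage can be verified against known
truth. It encodes:

* a **kinematic invasion wave**: arrival year = distance from the wave
  source / speed (6 km/yr by default, source placed beyond the grid
  corner so the front sweeps the monitored grid mid-study, 1992–2007
  under the defaults);
* an **additive lag model**: waiting time =
  \(\max(0, \text{round}(7 + \sum_j \beta_j x_j + b_{\text{level IV}} +
  e))\) years, with spatially smooth standardized driver fields \(x_j\)
  (Gaussian-kernel-smoothed noise at per-driver correlation lengths),
  nonzero default effects for winter temperature (−1.5 yr/SD), maximum
  spring temperature (+1) and anthropogenic fragmentation (+0.8),
  a 1-yr-SD level-IV random intercept and 1.5-yr residual noise —
  additive by design, because the downstream regression assumes
  additivity, which keeps recovery tests well-posed;
* **latent abundance** per cell: zero before arrival, a founder plateau
  of 1 expected moth per trap between arrival and establishment, then
  logistic growth to a carrying capacity of 100. The plateau level is
  deliberate: one expected moth is detectable (median reaches 1) yet
  keeps the probability of a zero median well above 0.01 indefinitely,
  so the detected-but-not-established phase of the generative model and
  the probabilistic criterion of the analysis model agree on what
  "not yet established" looks like. A plain logistic from arrival was
  rejected because its rise time is a constant, which would make every
  quadrat's observable waiting identical regardless of the planted
  covariate effects;
* **trapping**: negative-binomial counts with mean = detection scale ×
  abundance and dispersion size 5 (trap catches are overdispersed), three
  traps per cell at and ahead of the front, one behind it; and
* **treatments**: yearly discs (2 km radius) with total footprint capped
  at 1% of the area (2% is the hard ceiling), exercising the 1.5-km
  exclusion geometry without polygon clipping.

All randomness flows from one seed through documented per-stage
sub-seeds (`landscape`, `invasion`, `traps`, `counts`, `treatments`), so
any stage regenerates independently and the whole generator is
deterministic given (config, seed).

**What it does not emulate** — and hence what passing tests do not show
about real data: no Allee effects, no outbreak cycles, no wind-driven
dispersal kernel, no trap failure or relocation, no calibration of vital
rates to any real species. Effect sizes are chosen for statistical power,
not realism, since no natural-unit magnitudes were available to copy.

## Numerical choices and edge cases

* Grid cells are half-open, `[edge, edge + size)`; a point exactly on an
  interior boundary belongs to the higher-index cell.
* The treatment buffer uses distance to the disc *footprint* and a
  strictly-within rule: exactly 1.5 km survives.
* Yearly medians with an even trap count average the two middle values.
* The low-catch filter runs before the pre-established filter; both are
  idempotent. The 10-moth total is the sum of raw trap counts (a
  `use_medians = TRUE` switch sums yearly medians instead, since either
  reading of "moths caught" is defensible).
* Establishment requires `p < 0.01` strictly; an establishment year
  before detection is impossible by construction and treated as a hard
  error if ever presented.
* Sub-threshold fits (under 10 observed years) signal "insufficient
  calibration data" rather than returning a degenerate posterior.
* In `all_subsets_aic()`, a subset whose fit fails is logged in
  `$failures` and skipped — never silently dropped from the count.
* Perfectly collinear designs are rejected with the offending columns
  named (in `fit_lmm()`) or reported as infinite (in `vif()`).

## Problem sizes used in the checks

The shipped verification suite runs the full pipeline on a 20 × 20-cell
wave (400 quadrats, 31 years, ≈ 1 200 traps; several thousand expanding-
window Gibbs fits), calibration studies on 100 replicate series of
length 30, sign-recovery on 50 replicate 32 × 32 landscapes, and
selection-consistency on 100 replicates of n = 2000 with four candidate
drivers. These sizes give stable Monte-Carlo behavior for every claim
the tests make while completing a full run in a few minutes on one core;
the same quantities can be recomputed at any size through the exported
functions.

## Known limitations

* The establishment year inherits a ≈ +1 yr lag from one-step-ahead
  forecasting (see above); waiting times are correspondingly biased long
  by about one year, partially offset by detection occurring a fraction
  of a year after arrival.
* Quadrats whose true establishment falls outside the evaluated window
  (before the first target year or after the last observed year) are
  censored into the nearest evaluable year or excluded; interpreting
  waiting times near the window edges needs care.
* The driver-only \(R^2\) is a restricted-linear-predictor share, not a
  semi-partial correlation; with strongly correlated predictors the two
  diverge.
* No spatial pooling across quadrats during time-series fitting: each
  series is fitted independently, which is honest about the model but
  leaves power on the table for sparse series.
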