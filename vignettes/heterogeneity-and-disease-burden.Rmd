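---
title: "Individual heterogeneity and simulated disease burden: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual heterogeneity and simulated disease burden: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

Burden-of-disease studies summarise the consequences of an infection as
disability-adjusted life years, DALY = YLD + YLL, where YLD (years lived
with disability) weights time spent in each health state by a disability
weight in [0, 1], and YLL (years of life lost) counts the residual life
expectancy at the age of each disease death. The disease-progression models
behind such estimates almost always use *population-averaged* transition
probabilities: every person in a health state faces the same annual risk of
progressing. Real patient populations are heterogeneous — a minority of
fast-progressors and a majority of slow-progressors — and this unmeasured
variation ("frailty", used here as a fixed individual-level multiplier of
progression propensity, not the narrower survival-analysis term) cannot be
adjusted away with covariates.

`dalysim` quantifies what ignoring that heterogeneity does to DALY
estimates. It simulates cohorts of incident cases individually through an
outcome tree twice: once with population-averaged selection
(no-heterogeneity variant) and once with gamma-distributed individual
frailty values weighting *who* progresses, while the *number* progressing
each year stays constrained to the population-averaged expectation. The
ratio of the two burdens is the overestimation factor attributable to the
homogeneity assumption.

## Disease models

Two built-in outcome trees bracket the natural-history spectrum:

* **`builtin_model_x1()`** — short natural history. Acute infection turns
  chronic with probability 0.20, resolved immediately (within the infection
  year) and frailty-weighted. Death follows chronic infection immediately
  with age-banded case-fatality ratios of 5, 1, 2 and 15% for ages [0, 15),
  [15, 45), [45, 65) and [65, 86); this edge is *not* frailty-weighted —
  heterogeneity enters through an age-dependent frailty distribution that
  makes older cases likelier to become chronic.
* **`builtin_model_x2()`** — long natural history. The same 20% immediate
  acute-to-chronic step, then 2%/year chronic-to-severe-sequela and 4%/year
  sequela-to-death, all age-independent and all frailty-weighted. Everyone
  still alive leaves the model at their 86th birthday, with stage durations
  truncated there.

Disability weights and durations are calibration knobs, not authoritative
values: X1 uses acute 0.10 for 0.08 y and chronic 0.20 for 1.0 y; X2 uses
acute 0.10 for 0.25 y, chronic 0.15 and sequela 0.40 per year occupied.
Absolute YLD/DALY levels move with these knobs (and with the life table);
ratios and differences between the two variants, which share all of them,
are the supported comparisons. Custom trees can be supplied as validated
YAML/JSON configs (`read_model_config()`).

## Frailty distributions

Frailty values are dimensionless, nonnegative, assigned once per individual
("at birth": an individual keeps the value, and for the age-dependent
family the age group is fixed at infection) and used as sampling weights.

* `frailty_gamma(1, 1)` — the age-independent default for X2: unit mean and
  variance, rightward-skewed (few fast-progressors).
* `frailty_age_dependent(baseline_shape, growth_rate, variance)` — one
  gamma per 5-year age group (<1, 1–4, 5–9, …, 85+), with
  `shape_g = baseline_shape * exp(growth_rate * g)` and the scale adjusted
  so every group has the same variance; the group mean
  `sqrt(shape_g * variance)` then grows exponentially with age. The
  defaults (baseline 1, growth 0.25 per group, variance 1) are a package
  choice, not an authoritative calibration: they give a Gamma(2, 17.5)-aged
  incident cohort a mean frailty near 2.4, which is the qualitative regime
  the short-history analysis explores. Conclusions that depend on the exact
  growth rate (notably the absolute size of the X1 overestimation factor)
  should be treated as illustrative.
* `frailty_alternative()` — sensitivity shapes. `left_skew` reflects a
  gamma about an upper bound `b` and truncates at zero, with the gamma
  parameters calibrated numerically so the *post-truncation* mean and
  variance hit their targets; `symmetric` is a normal truncated
  symmetrically to [0, 2·mean].

One feasibility fact shapes the defaults here: a nonnegative random
variable whose standard deviation equals its mean has skewness at least
`sigma/mu - mu/sigma = 0`, so *no* left-skewed or symmetric distribution
exists at mean 1 and variance 1. The alternatives therefore default to
mean 1 and variance 0.25 (both moments shared between the two
alternatives), compared against the main-analysis Gamma(1, 1). Similarly,
reflecting a gamma about a bound far above the mean loses its left skew
once the reflection is truncated at zero, so the default bound is
`mean + 2*sd` and the constructor refuses calibrations whose resulting
skewness is nonnegative.

## The simulation cycle

Cohorts of `n` incident cases (default 5000) enter the model, one cohort
per simulation year for long natural histories; ages at infection are drawn
from Gamma(shape 2, scale 17.5) — mean 35 years, mode near 18 — rejecting
draws at or above 86 so every case is alive at infection. Each yearly cycle
applies, in order:

1. **Birthday-cap exits**: anyone at or past their 86th birthday leaves.
2. **Annual transitions**, most downstream edge first (death first), so no
   one makes two annual moves in one year. Each edge's count is
   `N = floor(occupancy * p + carry)` with the fraction carried forward —
   floor-with-carry keeps cumulative transitions within 1 of the cumulative
   expectation over any horizon, which plain rounding does not. The `N`
   transitioners are then drawn without replacement with probability
   proportional to frailty (heterogeneity variant) or uniformly
   (no-heterogeneity variant), via exponential-race keys, which is
   equivalent to successive probability-proportional-to-weight draws.
   Age-banded edges that are not frailty-weighted (the X1 case-fatality
   step) apply the count rule within each age band with uniform selection
   inside the band.
3. **Immediate transitions**, cascading downstream for this cycle's stage
   entrants; individuals left in a stage whose only exits are immediate
   recover at the end of their entry cycle.

`N` is always computed from the *current* occupancy of the run itself, not
from a pre-computed deterministic trajectory: this is the simplest reading
of a count "constrained to the population-averaged expectation", and it
makes the uniform stochastic mode reproduce the deterministic expected
counts exactly (up to the integerisation carry). Stage durations are
counted in whole simulated years (entry cycle to exit cycle), so a stage
occupied across k cycles contributes k years of YLD; the 86th-birthday
truncation is therefore resolved at cycle, not day, resolution —
consistently in both variants, which is what their comparison requires.

## Why multi-cohort pooling is the heterogeneity mechanism

With an *age-independent* frailty distribution and a *single* cohort, the
constrained-count design makes heterogeneity provably irrelevant to burden
totals: each year exactly `N` of the occupants move, frailty is independent
of age, so frailty-weighted selection merely permutes which
age-exchangeable individuals move. Counts, age compositions, and hence
YLD/YLL totals are distributionally identical to uniform selection; only
*who* carries the burden changes (the frailty-quartile decomposition).

The effect on totals appears when identically sized cohorts enter the model
every simulation year and compete *in one pooled weighted selection*. The
year-1 cohort's fast-progressors win selection early and die young; its
remaining members have below-average frailty and keep losing the yearly
draws to fresh cohorts' frail members, so they linger in chronic infection
and exit at the 86-year cap instead of dying. The year-1 cohort then
accrues fewer deaths (lower YLL) but more chronic/sequela person-years
(higher YLD) than under uniform selection — the YLD/YLL trade-off, with a
net DALY reduction. `run_stochastic()` keeps per-cohort accounting as its
default (that variant's year-1 burden is invariant to how many later
cohorts are simulated, which is the right default for a general tool), and
the experiment layer runs long natural histories with `pooling = "pooled"`
over 86 yearly cohorts, which is where the reported overestimation factors
come from. For the short natural history everything resolves within the
infection year, so a single cohort suffices and heterogeneity acts through
the age-dependence of frailty instead.

## Burden accounting

`compute_burden()` reports burden for the year-1 cohort only. Fixed-duration
stages contribute `DW * min(duration, time to the 86th birthday)` per
entrant; while-occupied stages contribute `DW * years occupied`. Deaths
contribute the life table's residual expectancy interpolated at the exact
age at death; cap exits contribute nothing. No discounting and no age
weighting are applied anywhere. A death just before the 86th birthday is
valued at the life table's own residual expectancy (about 6 years at age
85) even though the model would have removed the individual at 86 — the
life table, not the model's cap, defines the YLL reference.

The bundled life table is synthetic: a Gompertz hazard `mu(x) = A*exp(B*x)`
with the textbook adult mortality doubling time of 7 years (`B = ln 2 / 7`)
and `A` calibrated by root finding so that life expectancy at birth is
75.5 years. That slope also places the old-age expectancies close to
Western European male tables of the early 2000s (e(65) near 15, e(80) near
7), which is the regime the YLL comparisons live in. Any real table can be
supplied as an `age,ex` CSV; absolute YLL values are table-dependent and
the variant ratios are the supported outputs.

## Experiments and reporting

`run_replicates()` repeats the simulate-and-account cycle (1000 replicates
by default) and summarises YLD, YLL and DALY by median and 2.5/97.5%
quantiles, computed with inclusive linear interpolation (R's default
type-7 estimator; at 1000 replicates the extreme quantiles are sensitive to
the estimator in the third digit, so the choice is documented). Incident
ages are drawn once per experiment and shared across replicates and
variants, so comparisons are paired; frailty values and all selections are
redrawn each replicate. Seeding is hierarchical: a master seed spawns one
child seed per replicate through a fixed affine hash (`child_seed()`), so
replicates are independent and individually reproducible.

`overestimation_factor()` divides the no-heterogeneity median by the
heterogeneity median and brackets it with the reference divided by the
heterogeneity 97.5/2.5% quantiles — the interval convention that reproduces
published comparison tables of this design exactly from their printed
medians and quantiles. `vaccination_experiment()` removes 80% of potential
cases aged under 20 (each retained with probability 0.2; ages 20+ untouched
by default, with an optional herd-effect multiplier and a calibration
helper for a known target caseload) and reports DALYs averted and percent
averted per variant. `sensitivity_grid()` rebuilds the long-history model
over a grid of the two annual probabilities and tabulates the factors;
`frailty_shape_experiment()` swaps in the alternative frailty shapes.

## Problem sizes and what the tests show

The package's own test suite runs the full study conditions — 5000 cases
per cohort, 86 cohorts, 200 replicates per variant — for the headline YLL
comparison, and reduced conditions (1000–1500 cases per cohort, 25–150
replicates, repeated experiments) for the qualitative properties: the
direction of the DALY difference, the quartile and age-band decompositions,
the sensitivity-grid monotonicity and the frailty-shape ordering. The
reduced sizes are chosen so each property's Monte-Carlo error stays small
against the effect it checks (the heterogeneity effects are close to
scale-invariant in the cohort size, so smaller cohorts mainly cost
precision, not validity), while the whole suite still runs in minutes on a
laptop.

The synthetic-data generator emulates a stylised incidence process: a fixed
age distribution, no secular trend, no transmission dynamics, and cohorts
of identical size each year. It does not emulate case-count overdispersion,
seasonality, reporting error, or herd-immunity feedback (the vaccination
scenario filters incident cases, it does not model transmission — a
dynamic transmission model would be required for that). Passing tests
therefore demonstrate properties of the estimator under the stated
conditions, not calibration to any real disease.

## Known limitations

* Outcome trees must be acyclic with exactly one death stage; remission and
  competing non-disease mortality (other than the 86-year cap) are out of
  scope.
* Annual-cycle resolution: sub-year timing (and therefore sub-year
  truncation at the cap) is not modelled; the short-history model's
  immediate transitions all land in the infection year.
* Replicate intervals reflect only selection and frailty-sampling
  randomness, not uncertainty in incidence, transition probabilities,
  disability weights or the life table.
* The exponential growth rate of the age-dependent frailty family is a
  package default, not an estimate; quantitative X1 results depend on it.
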