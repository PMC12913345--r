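---
title: "Thermal development and demography of coffee berry borer parasitoids: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal development and demography of coffee berry borer parasitoids: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parasitherm)
```

parasitherm analyses constant-temperature life-history assays of two
coffee berry borer parasitoids, *Prorops nasuta* and *Phymastichus
coffea*. This vignette is the methods account: the models, the
assumptions behind them, the defaults and the numerical choices, and
what the synthetic cohorts do and do not establish about real data.

## The simulated study design

The assays the package emulates follow individual insects from
oviposition to death under one of eight constant temperatures (16, 19,
22, 25, 28, 30, 32, 35 °C), recording the duration of each life stage
(egg, larva, pupa), survival through each stage, sex at emergence,
adult longevity and eggs laid per observation interval.
`species_config()` encodes that design per species, and
`simulate_cohort()` draws one life history per individual from it.

Each configuration anchors every value that the motivating assays
report:

- **Sex ratio.** Female proportions per temperature (for *P. nasuta*
  falling from 0.96 at 16 °C to 0.21 at 30 °C; for *P. coffea* 0.51–0.52
  throughout), applied as a Bernoulli draw at emergence.
- **Development time.** Total egg-to-adult means pinned at the viability
  extremes (64.8 d at 16 °C and 19 d at 30 °C for *P. nasuta*; 87.35 d
  at 19 °C and 32.78 d at 28 °C for *P. coffea*). At the remaining
  temperatures the total follows the linear development-rate model for
  the species, and the split across stages follows the per-stage rate
  models, so the simulated cohorts are internally consistent with the
  thermal-model module they feed.
- **Survival.** Where only egg-to-adult survival is known, each of the
  four stage probabilities is its fourth root; the "adult" entry is
  emergence success, so the product of all four equals the egg-to-adult
  survival. Stage-level figures are used directly where known for
  *P. coffea* (e.g. 0.75 egg survival at 16 °C, 0.41 larval survival at
  32 °C, 0.87 adult survival at 25 °C). Temperatures where development
  halts are encoded as a zero survival probability at the stage where it
  halts (both species at 35 °C; past the egg at 32 °C for *P. nasuta*
  and past the larva at 32 °C for *P. coffea*; past the egg at 16 °C for
  *P. coffea*), not as missing temperatures.
- **Fecundity and longevity.** Mean eggs per female peak at 25 °C (27
  for *P. nasuta*, 38 for *P. coffea*) and collapse at the extremes;
  adult longevity peaks near 42 d at 16–25 °C for *P. nasuta* and is
  only 1–4 d for *P. coffea*. Survival, longevity and fecundity values
  between the published anchors were fixed once at values a rearing
  laboratory would consider plausible interpolations and are not tuned
  thereafter.

Distributional choices, each made because only a mean (or mean ± SD) is
reported:

- **Stage durations**: gamma with the configured mean and SD (shape
  `(mean/sd)²`), rounded to whole days and floored at one day, matching
  daily censusing. Gamma guarantees positivity; a zero SD short-circuits
  to the exact configured mean, which is what makes the noise-free
  recovery tests exact. The default SD is 10% of the mean (30% for adult
  longevity, which is far more variable in such assays).
- **Total fecundity**: negative binomial with dispersion (size) 3 —
  overdispersed relative to Poisson, as insect egg counts invariably
  are.
- **Egg timing**: no age-specific fecundity schedule is available for
  these species, only totals, so eggs are spread over the female's adult
  life along a symmetric triangular profile (ramp up, peak at mid-life,
  ramp down) and then summed into observation intervals: daily for
  *P. coffea*, 15-day for *P. nasuta*, whose host beans were dissected
  every 15 days. The triangular profile is an explicit assumption; any
  unimodal profile with the same total leaves `R₀` unchanged but shifts
  `r` slightly through the egg-age distribution.

Cohort sizes default to 200 per temperature for *P. nasuta* and 150 for
*P. coffea* (the assays followed 200 individuals and ~50 dissections per
day respectively).

What passing tests on these cohorts show: that the estimators recover
the parameters of a data-generating process with the study's structure,
at the study's sample sizes. What they cannot show: robustness to
features real cohorts have and the generator does not — fluctuating
temperatures, age-dependent survival within a stage, correlation between
development speed and subsequent fecundity, observation loss, and any
deviation from the assumed egg-age profile.

## Development-rate model

Over the favourable range, development rate is treated as linear in
temperature: `1/d = a + bT`, fitted by ordinary least squares to one
point per temperature, the reciprocal of the mean duration among the
individuals that completed the stage (`development_rates()`;
per-individual reciprocals are available as an option). One point per
temperature matches how such regressions are conventionally reported;
temperatures where no individual completes a stage contribute no point,
which is why different stages legitimately span different temperature
ranges. The lower developmental threshold `t = −a/b` and thermal
constant `K = 1/b` are derived only when `b > 0`; a non-positive slope
is reported as a biologically invalid fit rather than silently
producing a negative thermal constant.

No nonlinear (Brière/Lactin-type) models are offered: the linear model
is the one the degree-day machinery downstream consumes, and fitting an
upper-threshold model to 5–7 temperature means would be overfitting.
Reporting convention: coefficients to 4 decimals, `t` to 1 decimal, `K`
to whole degree-days; computation is always unrounded.

## Age-stage two-sex life table

Age 0 is the oviposition day; the age grid is integer days to the last
observed death. `s_xj` is the fraction of the initial cohort alive in
stage `j` at age `x`; `l_x = Σ_j s_xj`; `m_x` is the cohort's eggs laid
at age `x` divided by the number alive at `x`. Keeping males and
pre-adult deaths in the denominator is the two-sex convention: `R₀ =
Σ l_x m_x` then equals total eggs divided by initial cohort size
exactly, a conservation identity the tests assert to numerical
precision. Interval egg counts are spread uniformly across the days of
their interval; when the interval is not supplied it is inferred as the
smallest census interval consistent with every female's count vector (an
explicit `observation_interval` argument always takes precedence and is
what the pipeline passes).

**Euler–Lotka.** `r` solves `Σ e^{−r(x+1)} l_x m_x = 1`. The `x + 1`
exponent (rather than the classical `x`) is the convention of age-stage
two-sex life-table software, in which a newborn laid at age-0 parents
counts a full day of lag; with ages indexed from 0 the two conventions
differ by exactly one day of generation lag, and the package states its
choice explicitly. The left-hand side is strictly decreasing in `r`, so
the root is unique whenever `R₀ > 0`: it is bracketed by doubling,
narrowed by bisection to a 10⁻⁶ interval and polished by Newton steps to
`|Σ − 1| < 10⁻¹²`. A bisection-only mode exists solely as an independent
cross-check; the tests require agreement to 10⁻¹⁰. The construction
guarantees `sign(r) = sign(R₀ − 1)` and `λ = e^r` to machine precision.
`T = ln(R₀)/r` and `Dt = ln 2/r` are reported as `NA` when undefined
(`r = 0`, or `r ≤ 0` for `Dt`) rather than raising errors, since
declining cohorts are a legitimate assay outcome at extreme
temperatures.

**Bootstrap.** Individuals (not individual-day cells) are resampled with
replacement, `B = 2000` by default at desk scale (configurable; there is
no published value to match), and 95% percentile intervals are taken per
parameter. Percentile — not BCa — intervals are used because the
clamping behaviour being reproduced (a lower `R₀` bound truncated at 0)
is a percentile-interval phenomenon. Replicates in which no resampled
female reproduced have `R₀ = 0` and no Euler–Lotka root; they are
excluded from the rate-parameter percentiles and counted in
`n_excluded`. Temperature comparisons pair replicate `b` of one cohort
with replicate `b` of the other and use the small-sample-corrected
two-sided bootstrap p-value `2·min((c+1)/(B+1), …)`. Swapping the two
cohorts negates the estimated difference exactly; the replicate p-value
matches up to Monte-Carlo noise, since the resampling streams follow
argument order. All bootstrap functions are deterministic in
`(records, B, seed)`.

## Nonparametric comparisons and the survival model

Development time, longevity, fecundity and sex ratio are compared with
the tie-corrected Kruskal–Wallis test (computed via `stats::kruskal.test`)
and Dunn's post hoc z statistics with the pooled tie correction. The
default is **no** multiplicity adjustment on the Dunn p-values — the
procedure is conventionally run at a plain α = 0.05 unless an adjustment
is named — with Holm and Bonferroni available. Sex ratios enter as 0/1
female indicators, which makes the rank test a test of proportions.
Letter displays use the insert-and-absorb algorithm with letters
assigned in descending-median order; non-transitive significance
patterns are represented faithfully by overlapping letter sets.

Stage survival uses the saturated one-factor binomial model on the logit
scale, where the group MLE is `logit(p̂)` with standard error
`√(1/s + 1/f)`. Groups with zero survivors or zero failures get the
Anscombe +0.5 continuity correction and are flagged. Pairwise
differences are Wald z contrasts with Holm adjustment: a deliberate
substitution for single-step Tukey comparisons on the GLM scale, whose
multivariate-normal machinery buys little at 6–8 groups; Holm controls
the familywise error rate without it, at a small cost in power.

## Degree-day voltinism

`NG = (Tm − t)·d/K` per month and isotherm, with negative accumulation
clamped to zero (the model is silent below the threshold, and negative
generations are meaningless). The calendar is a 365-day civil year with
February at 28 days — the choice under which the monthly and annual
cells are mutually consistent, since the annual value then equals the
sum of the unrounded monthly values exactly. The four isotherms of the
Colombian coffee region (≤17, 17–20, 20–23, >23 °C) are evaluated at
their boundary temperatures: bounded bands report the range between
their two boundaries, open bands the single boundary value (17 and
23 °C). User-supplied isotherm tables with their own representative
temperatures are accepted; bands must partition the temperature axis
(left-open, right-closed) and validation rejects overlaps and gaps.
Rounding to 2 decimals is display-only.

## Pipeline and reproducibility

`run_pipeline()` chains all stages, derives one independent seed per
stage from the master seed (so a stage can be re-run in isolation), and
writes each table with a header comment recording the package version
and a hash of the analysis-relevant configuration (the output directory
is excluded from the hash so identical analyses produce byte-identical
tables anywhere). Stages that cannot run on a given cohort — a thermal
fit with fewer than two viable temperatures, a life table where nothing
reproduced — are skipped with logged warnings, because lethal
temperatures are expected study conditions, not errors.

## Problem sizes in the test suite

The suite exercises the estimators at sizes chosen to balance
resolution against desk-scale runtime: 10,000 individuals for Bernoulli
survival checks, 5,000 for closed-form `R₀` recovery (tolerance 5%),
100 simulation repeats at the default cohort size with `B = 2000` for
bootstrap coverage (≥90% required), 1,000 null simulations for the
Kruskal–Wallis type-I error (accepted band 0.03–0.07 at α = 0.05), and
100 random schedules for solver cross-checks at 10⁻¹⁰.

## Known limitations

- Constant temperatures only; no fluctuating or field regimes, and no
  single/double-sine degree-day accumulation from daily weather.
- The egg-age profile within adult life is assumed, not estimated;
  `r` (not `R₀`) is mildly sensitive to it, and more so for the 15-day
  census of *P. nasuta* than for daily counts.
- Within-stage mortality timing is not modelled: deaths are resolved at
  stage resolution, with the dying individual credited its drawn stage
  duration.
- The survival model treats temperature as categorical; no dose-response
  (e.g. probit-over-temperature) curve is fitted.
- Geographic output is tabular per isotherm; no map rendering.
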