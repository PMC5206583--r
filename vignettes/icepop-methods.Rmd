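---
title: "Methods: sea-ice habitat metrics and polar bear population projections"
author: "icepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sea-ice habitat metrics and polar bear population projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `icepop`, the choices made
where the design was genuinely open, the synthetic study world the
package uses in place of observational data, and the package's known
limitations.  It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The model

The pipeline assesses the change in mean global population size (MGPS)
of polar bears over three generations under the core assumption that
abundance *N* tracks environmental carrying capacity *K*, and that *K*
is indexed by sea-ice habitat.  The chain is:

1. **Habitat metric.**  Daily regional sea-ice area is
   `sum(conc * cell_area)` over grid cells with concentration strictly
   above 15 %, the conventional passive-microwave cutoff separating ice
   from open water.  Each region receives one fixed *midpoint*
   threshold — half the sum of its mean annual summer-minimum and mean
   annual winter-maximum areas — and the metric *ice* for a year is the
   count of days strictly above the midpoint.  A per-region ordinary
   least squares trend of *ice* on calendar year summarizes habitat
   change and is extrapolated for projections.
2. **Generation length (GL).**  The mean age of adult females with
   new cubs.  Mothers seen with yearlings in year *t* + 1 are
   back-dated to a reproductive event in year *t* at age − 1
   (pseudo-observations), recovering litters whose birth year was not
   sampled.  GL sets the horizon: `round_half_up(3 * GL)` years.
3. **Ice–abundance relations.**  Approach 1 assumes ΔN/N equals the
   projected ice ratio − 1.  Approaches 2 and 3 regress the annualized
   log change `r_n = log(N2/N1) / dt` on the annual change in
   ice-covered days, globally (approach 2) or per ecoregion
   (approach 3), with no intercept so that zero ice change predicts
   stable N.
4. **Stochastic projection.**  Monte Carlo replicates draw
   coefficients from their estimated sampling distributions, compound
   the annual log change over the horizon
   (`exp(beta * slope * h) - 1`, floored at −1), and aggregate
   subpopulations weighted by their most recent abundance estimate.
   The replicate distribution of per cent MGPS change yields the
   median ("most likely") change, a 95 % percentile interval, and the
   probabilities that the reduction exceeds 0 / 30 / 50 / 80 % — the
   IUCN Red List criterion A3 thresholds.  The category assigned is
   the highest threshold whose exceedance probability reaches the risk
   tolerance (default 0.5).

The assumptions worth keeping in view: N/K is taken as stable relative
to other factors (harvest managed, other stressors secondary);
relations are linear on the log scale with no density dependence,
thresholds or lags; and subpopulations respond independently except for
the shared scope-level coefficient.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| concentration cutoff | 0.15, strict | fraction | field convention for ice presence; applied per cell before area weighting |
| minimum day coverage | 300 | days/yr | a year mostly missing cannot support extremes or counts |
| `max_gap` in `fill_gaps()` | 5 | days | early passive-microwave records are alternate-day; longer gaps should fail loudly |
| adult age threshold | 5 | years | mothers of cubs-of-the-year are at least 4 at conception |
| bootstrap replicates | 5000 | — | percentile stability at two decimals |
| minimum pair span (approach 2) | 10 | years | short intervals are dominated by estimation noise |
| `n_sims` | 62 500 | replicates | reported probabilities stable to ±0.004 |
| risk tolerance | 0.5 | probability | Red List guidance for an even risk attitude |
| projection start | 2015 | year | first year after the 1979–2014 observation record |

The midpoint is computed once per region, pooled over the full observed
record rather than per year: a fixed threshold is what makes yearly
counts comparable, which the trend analysis requires.  "Above" is
strict; ties have measure zero on real data and the degenerate constant
series then counts zero ice-covered days, which is the right answer for
a region with no seasonal signal.

## The synthetic study world

`gen_study_world()` builds the complete input set from one seed.  Its
defaults are the study conditions, chosen once:

* **Ice fields.**  Nineteen regions on a 25 × 25 grid of 2500 km²
  cells; daily total area follows
  `450000 + 300000 * cos(2 * pi * (doy - 75) / 365) + trend * t + noise`
  (km²), i.e. a mid-March winter maximum of 750 000 km² and a summer
  minimum of 150 000 km², typical of a mid-sized subpopulation region,
  with daily Gaussian noise of 20 000 km² (≈ 5 %).  The daily total is
  spread over cells by a fixed smooth gradient so that low-ice days
  leave some cells below the 15 % cutoff, exercising the cutoff rule.
  Near the midpoint the sinusoid crosses at `2 * pi * A / 365` km² per
  day, so an area trend of `day_trend * pi * A / 365` km²/yr produces a
  chosen trend in ice-covered days; per-region multipliers (fixed, not
  seeded) give the 19 trends a median of −1.26 days/yr and a spread of
  roughly −0.7 to −3.4 days/yr.
* **Abundance.**  Latent log-linear dynamics
  `log N(t+1) = log N(t) + beta * (ice(t+1) - ice(t))` with ecoregion
  slopes 0.013 (seasonal), 0.032 (divergent), −0.008 (convergent) and
  −0.029 (archipelago); observations are mean-unbiased lognormal with
  CV 0.15, a typical mark–recapture precision.  Nine subpopulations
  carry data: four long series (estimates every 5 years, 1981–2011),
  three widely spaced pairs (1986/2011) and two pairs too short for the
  two-point rule (8-year spans), mirroring the sparse and uneven real
  availability: seven subpopulations qualify for the global two-point
  fit and all four ecoregions are estimable from consecutive pairs.
  Subpopulation sizes are plausible synthetic values summing to about
  26 000 bears, the rough global total.
* **Captures.**  3374 cub-of-year litters across 11 subpopulations,
  mother ages normal with mean 11.5 and sd 3 years (truncated below
  age 5), 30 % of litters re-observed as yearlings the following year.

What the world does *not* emulate: spatial sea-ice physics (drift,
thickness, coastlines), leap years (synthetic years have 365 days; the
readers handle real calendars), age-structured demography, harvest,
observation-effort patterns, and — importantly — the particular joint
composition of per-subpopulation trends, abundance series and weights
behind the published global assessment.  Passing tests therefore show
that the estimators recover known generating parameters under
realistic noise, not that any real subpopulation behaves this way.

## Numerical choices

* OLS is computed on centred years for conditioning and reported on the
  calendar scale with the exactly transformed covariance.
* Projected ice-covered days are clamped to [0, 366]; proportional
  changes are floored at −1; an approach-1 draw whose baseline ice is
  non-positive counts as complete habitat loss.
* `d_ice` for an estimate pair is the OLS slope of *ice* over the
  pair's calendar window (the endpoint difference divided by the span
  when only two ice years are available), which is robust to
  single-year ice noise.
* Quantiles are empirical with linear interpolation (R type 7)
  everywhere: bootstrap percentiles, projection intervals, medians.
  The median of an even number of scenarios is the mean of the two
  central values.
* Monte Carlo streams: every uncertain quantity (each scope-level
  slope, each subpopulation trend) has its own seeded normal stream,
  indexed in a fixed order; bivariate trend draws use the Cholesky
  factor of the coefficient covariance.  Reruns are bit-identical and a
  run with more replicates extends a shorter one, so convergence can be
  checked by doubling `n_sims`.  Zero standard errors give degenerate
  draws, so the engine reduces exactly to the deterministic projection.
* A scope-level coefficient draw is shared by all subpopulations of the
  scope within a replicate (one global slope for approach 2, one per
  ecoregion for approach 3): the coefficient is a single uncertain
  quantity, and sharing it preserves the between-subpopulation
  correlation that drives tail probabilities.
* Truncating synthetic mother ages at 5 raises the realized mean age
  slightly above the nominal value (≈ +0.1 yr at sd 3, negligible at
  sd 2); recovery tests use the CLT-scale tolerances this implies.

## Open design decisions

* **GL averaging.**  The point estimate averages per-subpopulation mean
  ages rather than pooling events, so heavily sampled subpopulations do
  not dominate; pooling is available via `method = "pooled"`.  The
  bootstrap resamples events within subpopulation and re-averages.
* **No intercept in the relation fits.**  Zero ice change predicting
  stable N is the substantive hypothesis; an intercept mode
  (`intercept = TRUE`) exists for sensitivity analysis.
* **Proportional change on the log scale.**  `r_n` is symmetric and
  composable over time, and compounding `beta * d_ice` annually equals
  `exp(beta * slope * h) - 1` over the horizon — e.g. slope 0.013,
  trend −1.26 days/yr and a 35-year horizon give −43.6 %.
* **"Most likely" = Monte Carlo median.**  No mode estimation is
  attempted.
* **Unweighted relation fits** by default; inverse-variance weighting
  of `r_n` via the delta method from the N standard errors is a
  documented extension point, not enabled, because the real
  observation-error structure is unknown.

## Known limitations

* The global and ecoregion fits rest on very few observations (two per
  ecoregion in the worst case); their standard errors are accordingly
  large and the projection tails are sensitive to them.
* A fitted *negative* slope (convergent, archipelago) combined with
  declining ice projects exponential abundance *increase*; over a
  35–41-year horizon this compounds strongly.  In the synthetic world
  these increases largely offset the seasonal and divergent declines,
  so the approach-3 MGPS aggregate sits near zero even though every
  generating slope is recovered: the aggregate depends on the joint
  composition of trends, slopes and weights, not only on the headline
  slope values.  The robustly anchored approach-3 quantity is the
  seasonal-ecoregion three-generation change (≈ −43 % at the median
  trend), which the acceptance script recomputes from recovered
  estimates.
* Approach 1 inherits every weakness of linear extrapolation of
  ice-covered days, mitigated only by the [0, 366] clamp and the −1
  floor.
* No density dependence, harvest interaction, nonlinear or spatial
  responses; criterion A3 only (no quasi-extinction analysis).

## Problem sizes

The test suite runs the full-resolution generators only where the check
needs them; elsewhere it uses 6 × 6 to 10 × 10 grids (36–100 cells per
region), 400–3000 capture events, bootstrap reps of 400–5000 and
scenario runs of 500–20 000 replicates, keeping the whole suite under
half a minute.  `scripts/acceptance.R` uses the full defaults: 19
regions × 36 years × 365 days × 625 cells, 3374 events, 5000 bootstrap
replicates and six scenarios of 62 500 replicates.
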