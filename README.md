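# icepop

Sea-ice habitat metrics and stochastic projections of polar bear
population change.

Polar bears (*Ursus maritimus*) depend on sea ice for essentially every
part of their life history, and Arctic sea-ice loss is the primary
threat to the species.  `icepop` implements, as a tested and reusable R
pipeline, a global population assessment that links a standardized
sea-ice habitat metric to subpopulation abundance and projects the
change in mean global population size (MGPS) over three generations,
scoring the outcome against IUCN Red List criterion A3 reduction
thresholds (≥ 30 % vulnerable, ≥ 50 % endangered, ≥ 80 % critically
endangered).  It is aimed at quantitative ecologists and conservation
assessors who want each stage of such an assessment — habitat metric,
generation length, ice–abundance relations, Monte Carlo projection — as
an inspectable, seedable function.

## The method

**Habitat metric.**  For each of the 19 subpopulation regions, daily
sea-ice area is the sum of concentration × cell area over grid cells
with concentration > 15 %.  Each region gets a fixed *midpoint*
threshold, ½(mean annual summer minimum + mean annual winter maximum),
and the metric *ice* for a year is the number of days whose area exceeds
that midpoint ("ice-covered days").  Ordinary least squares of *ice* on
year gives a per-region trend that is extrapolated (clamped to
[0, 366] days) to project future habitat.

**Generation length.**  GL is the mean age of adult females with new
cubs, estimated from live-capture records; females seen with yearlings
in year *t* + 1 are back-dated as pseudo-observations at year *t*, age
− 1.  Uncertainty comes from a stratified bootstrap over subpopulations.
GL sets the projection horizon: 3 GL years, rounded half up.

**Ice–abundance relations.**  Three approaches relate *ice* to
abundance *N*:

1. one-to-one proportionality: ΔN/N equals the projected ice ratio − 1;
2. a global no-intercept regression of the annualized log change
   r&#8342; = ln(N₂/N₁)/Δt on the annual ice change d·ice, from at most
   two estimates per subpopulation at least 10 years apart;
3. the same regression fitted separately per ecoregion (convergent,
   divergent, archipelago, seasonal), using all consecutive estimate
   pairs.

**Projection.**  Each of 62 500 Monte Carlo replicates draws regression
coefficients from their estimated sampling distributions (normal at the
point estimate with the standard error; jointly, with covariance, for
trend lines), compounds the annual log change over the horizon
(exp(β · slope · h) − 1, floored at −1), aggregates subpopulations
weighted by their latest *N*, and the replicate distribution yields the
median change in MGPS, a 95 % interval, and the probabilities of
exceeding the Red List reduction thresholds.

Because no observational data ship with the package, a first-class
synthetic-data module generates all inputs with the statistical
structure the analysis assumes (seasonal sinusoidal ice with linear
decline, log-linear abundance dynamics, capture records with known mean
mother age), so every stage is testable end to end.

## Worked example

```r
library(icepop)

world <- gen_study_world(seed = 2026, grid_shape = c(10L, 10L),
                         cell_area = 15000, n_events = 1200)

events <- build_pseudo_observations(world$captures)
bootstrap_gl(events, reps = 2000, seed = 2026)
#> Generation length: 11.47 years (5th-95th pct: 11.36-11.59; 1569 events, 2000 bootstrap reps)

world$trends[["WH"]]
#> Ice-covered-day trend for region 'WH' (1979-2014, n = 36)
#>   slope: -2.163 days/yr (se 0.034), residual sd 2.14 days

median(sapply(world$trends, function(t) coef(t)[["slope"]]))
#> [1] -1.26

obs <- paired_changes(world$estimates, world$annual_ice, mode = "series")
fit_relations_by_ecoregion(obs)$seasonal
#> Ice-abundance relation [seasonal]: beta = 0.0115 (se 0.0041), n = 18

trends <- world$trends[names(world$weights)]   # drops the Arctic Basin
run_scenario(scenario(1, gl = 11.5, n_sims = 10000, seed = 2026),
             trends, world$weights)
#> Approach 1, GL 11.5 yr (horizon 35 yr, 10000 sims):
#>   MGPS change: -48.8% (95% CI -49.4 to -48.1)
#>   P(reduction >= 0/30/50/80%): 1.00 / 1.00 / 0.00 / 0.00
```

The generation length of ~11.5 years sets a 35-year horizon; Western
Hudson Bay loses ice-covered days at about −2.2 days/yr while the
19-region median decline is −1.26 days/yr; the fitted seasonal-ecoregion
slope says each lost ice-covered day per year costs about 1.2 % of
abundance per year; and the habitat-proportional scenario projects
roughly a halving of MGPS, a reduction that is practically certain to
exceed 30 % but not 50 %.

Given per-scenario threshold probabilities (here, the published
six-scenario set), the cross-scenario summary and Red List call are:

```r
published <- rbind(c(1.00, 0.56, 0.00, 0.00), c(1.00, 0.95, 0.00, 0.00),
                   c(0.55, 0.20, 0.06, 0.00), c(0.55, 0.24, 0.08, 0.00),
                   c(1.00, 0.86, 0.30, 0.01), c(1.00, 0.88, 0.35, 0.02))
colnames(published) <- c("0", "30", "50", "80")
(cs <- summarize_scenarios(published))
#> Across 6 scenarios, P(MGPS reduction >= threshold):
#>  threshold median  min  max
#>          0   1.00 0.55 1.00
#>         30   0.71 0.20 0.95
#>         50   0.07 0.00 0.35
#>         80   0.00 0.00 0.02
red_list_category(cs)
#> Red List criterion A3 category: vulnerable
#>   rule: P(reduction >= 30%) = 0.71 >= tolerance 0.50
```

A whole run — synthetic inputs (or CSV files) through ice metrics, GL,
relation fits, six scenarios and the Red List call, with all stage
outputs written as CSV/JSON — is `run_pipeline(config)`; see
`?run_pipeline`.

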