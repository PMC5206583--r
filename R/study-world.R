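# A complete seeded synthetic study world: 19 subpopulations in four
# ecoregions with declining sea ice, abundance estimates for nine of
# them, and capture records -- the conditions the projection pipeline is
# designed for, reproducible without any external data.

#' The 19 polar bear subpopulations and their ecoregions
#'
#' The standard subpopulation/ecoregion layout used for global polar
#' bear assessments: convergent (EG, NB), divergent (SB, CS, LP, KS,
#' BS), archipelago (MC, VM, NW, KB, LS, GB) and seasonal (WH, FB, BB,
#' DS, SH) ecoregions, plus the Arctic Basin (AB), which has few
#' year-round resident bears and is excluded from projections.
#'
#' \code{trend_multiplier} scales each region's synthetic ice decline
#' relative to the across-region median of -1.26 ice-covered days per
#' year; the multipliers have median 1 and span the across-region spread
#' of observed declines (roughly -0.7 to -3.4 days per year).
#' \code{n_latest} is a plausible synthetic most-recent abundance
#' estimate (the 18 analysed subpopulations sum to about 26000 bears,
#' the rough size of the global population).
#'
#' @return data frame with columns \code{subpopulation},
#'   \code{ecoregion}, \code{trend_multiplier}, \code{n_latest},
#'   \code{excluded}.
#' @export
study_regions <- function() {
  data.frame(
    subpopulation = c("EG", "NB", "SB", "CS", "LP", "KS", "BS",
                      "MC", "VM", "NW", "KB", "LS", "GB",
                      "WH", "FB", "BB", "DS", "SH", "AB"),
    ecoregion = c("convergent", "convergent",
                  "divergent", "divergent", "divergent", "divergent",
                  "divergent",
                  "archipelago", "archipelago", "archipelago", "archipelago",
                  "archipelago", "archipelago",
                  "seasonal", "seasonal", "seasonal", "seasonal", "seasonal",
                  NA),
    trend_multiplier = c(0.90, 0.78, 1.52, 1.22, 0.94, 1.35, 2.05,
                         0.63, 0.70, 0.56, 0.85, 0.97, 0.99,
                         1.75, 1.12, 2.35, 2.67, 1.05, 1.00),
    n_latest = c(2000, 980, 900, 3000, 1000, 1000, 2650,
                 280, 160, 200, 360, 2540, 1590,
                 1030, 2580, 2830, 2150, 780, NA),
    excluded = c(rep(FALSE, 18), TRUE))
}

# true ecoregion slopes of the synthetic ice-abundance relation
# (proportional change in N per ice-covered-day change per year)
study_true_betas <- function() {
  c(convergent = -0.008, divergent = 0.032, archipelago = -0.029,
    seasonal = 0.013)
}

# subpopulations with synthetic abundance data and their estimate years:
# four long series, three widely spaced pairs, two pairs too short for
# the two-point (>= 10 yr) rule
study_abundance_years <- function() {
  series <- seq(1981L, 2011L, by = 5L)
  list(SB = series, WH = series, SH = series, DS = series,
       BS = c(1986L, 2011L), GB = c(1986L, 2011L), NB = c(1986L, 2011L),
       MC = c(1998L, 2006L), EG = c(1999L, 2007L))
}

#' Generate the full synthetic study world
#'
#' Builds, from one seed, the complete set of inputs the projection
#' pipeline consumes: per-region daily concentration fields (365-day
#' calendar, seasonal sinusoid with winter maximum in March, linear
#' decline calibrated so the across-region median trend in ice-covered
#' days is about -1.26 days per year), annual ice series and fitted
#' trends; abundance estimate series for nine subpopulations generated
#' from the ecoregion-specific log-linear relations; and capture records
#' with true generation length 11.5 years.
#'
#' @param seed integer master seed; all region, abundance and capture
#'   streams are derived from it.
#' @param n_years years of daily ice data (default 36, a 1979-2014
#'   analogue).
#' @param start_year first ice year.
#' @param grid_shape,cell_area per-region synthetic grid (default 25x25
#'   cells of 2500 km^2).
#' @param mean_area,seasonal_amplitude,noise_sd ice-area climate shared
#'   by all regions, km^2.
#' @param day_trend_median target across-region median trend in
#'   ice-covered days per year (default -1.26).
#' @param n_events,age_sd,p_yearling capture-record parameters (defaults:
#'   3374 events, age sd 3 yr, 30\% yearling re-observation).
#' @param true_gl true mean mother age, years (default 11.5).
#' @param obs_cv coefficient of variation of abundance estimates.
#' @return list with elements \code{regions}, \code{annual_ice} (stacked
#'   \code{annual_ice} data frame), \code{trends} (named list of
#'   \code{ice_trend}), \code{estimates} (abundance estimates with
#'   ecoregion), \code{captures}, \code{weights} (latest N for the 18
#'   analysed subpopulations), \code{ecoregions} (named map) and
#'   \code{truth} (the generating parameter values).
#' @export
gen_study_world <- function(seed, n_years = 36L, start_year = 1979L,
                            grid_shape = c(25L, 25L), cell_area = 2500,
                            mean_area = 450000, seasonal_amplitude = 300000,
                            noise_sd = 20000, day_trend_median = -1.26,
                            n_events = 3374L, age_sd = 3, p_yearling = 0.3,
                            true_gl = 11.5, obs_cv = 0.15) {
  regions <- study_regions()
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L,
                          nrow(regions) + length(study_abundance_years()) + 1L)
  # area trend giving the target day trend: near the midpoint the
  # sinusoid crosses at rate 2*pi*A/365 km^2/day, so d(days)/dt =
  # 365 * area_trend / (pi * A)
  area_trend_unit <- day_trend_median * pi * seasonal_amplitude / 365
  annual <- vector("list", nrow(regions))
  trends <- vector("list", nrow(regions))
  names(trends) <- regions$subpopulation
  for (i in seq_len(nrow(regions))) {
    sp <- ice_field_spec(regions$subpopulation[i], n_years = n_years,
                         start_year = start_year, mean_area = mean_area,
                         seasonal_amplitude = seasonal_amplitude,
                         trend = area_trend_unit * regions$trend_multiplier[i],
                         noise_sd = noise_sd, grid_shape = grid_shape,
                         cell_area = cell_area)
    field <- gen_ice_concentration(sp, seed = sub_seeds[i])
    ann <- annual_ice_series(daily_ice_series(field))
    annual[[i]] <- ann
    trends[[i]] <- fit_ice_trend(ann)
  }
  annual_ice <- do.call(rbind, annual)
  betas <- study_true_betas()
  est_years <- study_abundance_years()
  est <- vector("list", length(est_years))
  for (j in seq_along(est_years)) {
    sp <- names(est_years)[j]
    eco <- regions$ecoregion[regions$subpopulation == sp]
    spec <- abundance_sim_spec(
      true_beta = betas[[eco]],
      n0 = regions$n_latest[regions$subpopulation == sp],
      obs_cv = obs_cv, est_years = est_years[[j]], subpopulation = sp)
    e <- gen_abundance_series(spec, annual_ice[annual_ice$region_id == sp, ],
                              seed = sub_seeds[nrow(regions) + j])
    e$ecoregion <- eco
    est[[j]] <- e
  }
  captures <- gen_capture_data(
    capture_sim_spec(true_gl = true_gl, age_sd = age_sd,
                     n_events = n_events, p_yearling = p_yearling),
    seed = sub_seeds[length(sub_seeds)])
  keep <- !regions$excluded
  weights <- stats::setNames(regions$n_latest[keep],
                             regions$subpopulation[keep])
  ecoregions <- stats::setNames(regions$ecoregion[keep],
                                regions$subpopulation[keep])
  list(regions = regions, annual_ice = annual_ice, trends = trends,
       estimates = do.call(rbind, est), captures = captures,
       weights = weights, ecoregions = ecoregions,
       truth = list(true_gl = true_gl, betas = betas,
                    day_trend = day_trend_median * regions$trend_multiplier,
                    day_trend_median = day_trend_median))
}
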