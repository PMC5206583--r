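# Seeded generators for synthetic sea-ice fields, abundance series and
# capture records.  They emulate the statistical structure the downstream
# analysis assumes -- seasonal sinusoidal ice-area cycles with a linear
# decline, log-linear abundance dynamics driven by changes in ice-covered
# days, and reproductive events whose mothers' ages have a known mean --
# so every stage of the pipeline is testable without external data.

#' Specification of a synthetic daily sea-ice concentration field
#'
#' Describes one subpopulation region's synthetic ice climate: a seasonal
#' sinusoid (winter maximum, summer minimum) around a mean daily ice area,
#' a linear trend applied to the daily area, and i.i.d. Gaussian noise.
#' The daily target area is spread over a rectangular grid of equal-area
#' cells by a smooth spatial gradient, so that on any given day some cells
#' sit below the 15\% concentration cutoff used by
#' \code{\link{daily_ice_area}}.
#'
#' @param region_id character scalar naming the region.
#' @param n_years number of 365-day years to generate.
#' @param start_year first calendar year.
#' @param mean_area mean daily ice area, km^2.
#' @param seasonal_amplitude amplitude of the seasonal cycle, km^2
#'   (winter maximum is \code{mean_area + seasonal_amplitude} at trend 0).
#' @param trend linear trend in daily area, km^2 per year.
#' @param noise_sd standard deviation of daily Gaussian noise, km^2.
#' @param grid_shape integer vector \code{c(rows, cols)}.
#' @param cell_area area of one grid cell, km^2.
#' @param peak_doy day-of-year of the winter maximum (default 75,
#'   mid-March, typical of Arctic sea ice).
#' @return an object of class \code{ice_field_spec}.
#' @seealso \code{\link{gen_ice_concentration}}
#' @export
ice_field_spec <- function(region_id, n_years, start_year = 1979,
                           mean_area = 450000, seasonal_amplitude = 300000,
                           trend = 0, noise_sd = 0,
                           grid_shape = c(25L, 25L), cell_area = 2500,
                           peak_doy = 75L) {
  stopifnot(is.character(region_id), length(region_id) == 1L)
  assert_scalar_number(n_years, "n_years", lo = 1)
  assert_scalar_number(mean_area, "mean_area", lo = 0)
  assert_scalar_number(seasonal_amplitude, "seasonal_amplitude", lo = 0)
  assert_scalar_number(noise_sd, "noise_sd", lo = 0)
  assert_scalar_number(cell_area, "cell_area")
  if (cell_area <= 0) stopf("'cell_area' must be > 0")
  if (mean_area <= seasonal_amplitude)
    stopf("'mean_area' (%g) must exceed 'seasonal_amplitude' (%g)",
          mean_area, seasonal_amplitude)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stopf("'grid_shape' must be two positive integers (rows, cols)")
  total <- prod(grid_shape) * cell_area
  if (mean_area > total)
    stopf("invalid spec: mean_area (%g km^2) exceeds total grid area (%g km^2)",
          mean_area, total)
  structure(list(region_id = region_id, n_years = as.integer(n_years),
                 start_year = as.integer(start_year), mean_area = mean_area,
                 seasonal_amplitude = seasonal_amplitude, trend = trend,
                 noise_sd = noise_sd, grid_shape = grid_shape,
                 cell_area = cell_area, peak_doy = as.integer(peak_doy)),
            class = "ice_field_spec")
}

# Smooth spatial gradient used to spread a daily total over cells.
# Fixed range (0.08, 1] keeps low-gradient cells below the concentration
# cutoff on low-ice days, exercising the cutoff rule.
cell_gradient <- function(n_cells) seq(0.08, 1, length.out = n_cells)

# Allocate one day's target total area over cells as conc = s * gradient,
# clipping saturated cells at concentration 1 (exact water-filling).
allocate_concentration <- function(target, gradient, cell_area) {
  n <- length(gradient)
  denom <- sum(gradient) * cell_area
  s <- target / denom
  if (s * max(gradient) <= 1) return(s * gradient)
  # some cells saturate: fill from the highest gradient down
  ord <- order(gradient, decreasing = TRUE)
  g <- gradient[ord]
  for (k in seq_len(n)) {
    rem <- target - k * cell_area
    if (k == n || rem <= 0) { s2 <- 0 } else {
      s2 <- rem / (sum(g[(k + 1):n]) * cell_area)
    }
    if (k == n || s2 * g[min(k + 1, n)] <= 1) {
      conc <- numeric(n)
      conc[seq_len(k)] <- 1
      if (k < n) conc[(k + 1):n] <- pmin(1, s2 * g[(k + 1):n])
      out <- numeric(n)
      out[ord] <- conc
      return(out)
    }
  }
  stop("allocation failed")  # unreachable: target <= total grid area
}

#' Generate a synthetic daily sea-ice concentration field
#'
#' Produces one concentration grid per day over \code{n_years} 365-day
#' years.  The area-weighted total concentration (summed over all cells
#' without any cutoff) follows
#' \deqn{mean\_area + A\cos(2\pi(d - peak)/365) + trend\,(t - start) + \epsilon}
#' clipped to \code{[0, total grid area]}, with \eqn{\epsilon \sim
#' N(0, noise\_sd^2)} i.i.d. by day.  Per-cell concentrations lie in
#' \code{[0, 1]}.  Identical seeds give identical output.
#'
#' @param spec an \code{\link{ice_field_spec}}.
#' @param seed integer seed.
#' @return an object of class \code{ice_field}: a list with elements
#'   \code{conc} (days x cells matrix), \code{cell_id}, \code{cell_area},
#'   \code{year}, \code{doy}, \code{target_area} (the clipped daily
#'   totals before spatial allocation), and \code{spec}.
#' @examples
#' f <- gen_ice_concentration(ice_field_spec("WH", n_years = 2), seed = 1)
#' dim(f$conc)
#' @export
gen_ice_concentration <- function(spec, seed) {
  stopifnot(inherits(spec, "ice_field_spec"))
  set.seed(seed)
  n_cells <- prod(spec$grid_shape)
  total_area <- n_cells * spec$cell_area
  doy <- rep(seq_len(365L), times = spec$n_years)
  year <- rep(spec$start_year + seq_len(spec$n_years) - 1L, each = 365L)
  tfrac <- (year - spec$start_year) + (doy - 1) / 365
  target <- spec$mean_area +
    spec$seasonal_amplitude * cos(2 * pi * (doy - spec$peak_doy) / 365) +
    spec$trend * tfrac
  if (spec$noise_sd > 0)
    target <- target + rnorm(length(target), 0, spec$noise_sd)
  target <- clamp(target, 0, total_area)
  g <- cell_gradient(n_cells)
  ga <- sum(g) * spec$cell_area
  conc <- outer(target / ga, g)            # linear regime
  over <- which(target / ga * max(g) > 1)  # rare saturated days
  for (d in over)
    conc[d, ] <- allocate_concentration(target[d], g, spec$cell_area)
  cell_id <- sprintf("%s_c%04d", spec$region_id, seq_len(n_cells))
  colnames(conc) <- cell_id
  structure(list(conc = conc, cell_id = cell_id,
                 cell_area = rep(spec$cell_area, n_cells),
                 year = year, doy = doy, target_area = target,
                 calendar = "365_day", spec = spec),
            class = "ice_field")
}

#' Specification of a synthetic abundance-estimate series
#'
#' Latent abundance follows log-linear dynamics driven by year-to-year
#' changes in ice-covered days:
#' \eqn{\ln N_{t+1} = \ln N_t + \beta\,\Delta ice_t}.  Observed estimates
#' are the latent abundance with multiplicative lognormal error of
#' coefficient of variation \code{obs_cv}, mean-unbiased on the natural
#' scale.
#'
#' @param true_beta proportional change in N per unit change in
#'   ice-covered days (per day).
#' @param n0 initial abundance (bears) in the first ice year.
#' @param obs_cv coefficient of variation of the observation error.
#' @param est_years calendar years in which estimates are observed.
#' @param subpopulation label carried into the output records.
#' @return an object of class \code{abundance_sim_spec}.
#' @export
abundance_sim_spec <- function(true_beta, n0, obs_cv, est_years,
                               subpopulation = "S1") {
  assert_scalar_number(true_beta, "true_beta")
  assert_scalar_number(n0, "n0")
  if (n0 <= 0) stopf("'n0' must be > 0")
  assert_scalar_number(obs_cv, "obs_cv", lo = 0)
  if (length(est_years) < 1L) stopf("'est_years' must be non-empty")
  structure(list(true_beta = true_beta, n0 = n0, obs_cv = obs_cv,
                 est_years = as.integer(sort(est_years)),
                 subpopulation = subpopulation),
            class = "abundance_sim_spec")
}

#' Generate synthetic abundance estimates from an annual ice series
#'
#' @param spec an \code{\link{abundance_sim_spec}}.
#' @param ice annual ice series: a data frame with columns \code{year}
#'   and \code{ice} (ice-covered days), as returned by
#'   \code{\link{annual_ice_series}}.
#' @param seed integer seed.
#' @return data frame with columns \code{subpopulation}, \code{year},
#'   \code{n}, \code{se}; the latent (error-free) series is attached as
#'   attribute \code{"latent"}.
#' @export
gen_abundance_series <- function(spec, ice, seed) {
  stopifnot(inherits(spec, "abundance_sim_spec"))
  if (length(spec$est_years) == 0L) stopf("'est_years' is empty")
  years <- ice$year
  if (!all(spec$est_years %in% years))
    stopf("est_years not covered by the ice series: %s",
          paste(setdiff(spec$est_years, years), collapse = ", "))
  set.seed(seed)
  o <- order(years)
  years <- years[o]
  icev <- ice$ice[o]
  ln_n <- log(spec$n0) + c(0, cumsum(spec$true_beta * diff(icev)))
  latent <- data.frame(year = years, n_latent = exp(ln_n))
  idx <- match(spec$est_years, years)
  n_lat <- latent$n_latent[idx]
  if (spec$obs_cv > 0) {
    sdlog <- sqrt(log(1 + spec$obs_cv^2))
    # mean -sdlog^2/2 makes the observed estimate mean-unbiased for latent N
    eps <- rnorm(length(idx), -sdlog^2 / 2, sdlog)
    n_obs <- n_lat * exp(eps)
  } else n_obs <- n_lat
  out <- data.frame(subpopulation = spec$subpopulation,
                    year = spec$est_years, n = n_obs,
                    se = spec$obs_cv * n_obs)
  attr(out, "latent") <- latent
  out
}

#' Specification of synthetic live-capture records
#'
#' @param true_gl mean age (years) of mothers with cubs-of-the-year; the
#'   quantity generation-length estimation should recover.
#' @param age_sd standard deviation of mothers' ages, years.
#' @param n_events number of cub-of-year litters to generate.
#' @param p_yearling probability a litter is re-observed as 1-year-olds
#'   in the following year (with the mother one year older).
#' @param n_subpops number of subpopulations the events are spread over.
#' @param year_range calendar years events may fall in.
#' @param n_none number of non-reproductive ("none") capture records to
#'   add; these are ignored by the generation-length estimator.
#' @param adult_age minimum mother age (resampled below this).
#' @return an object of class \code{capture_sim_spec}.
#' @export
capture_sim_spec <- function(true_gl, age_sd, n_events, p_yearling,
                             n_subpops = 11L, year_range = c(1985L, 2010L),
                             n_none = 0L, adult_age = 5) {
  assert_scalar_number(true_gl, "true_gl")
  if (true_gl <= 0) stopf("'true_gl' must be > 0")
  assert_scalar_number(age_sd, "age_sd", lo = 0)
  assert_scalar_number(n_events, "n_events", lo = 1)
  assert_scalar_number(p_yearling, "p_yearling", lo = 0, hi = 1)
  structure(list(true_gl = true_gl, age_sd = age_sd,
                 n_events = as.integer(n_events), p_yearling = p_yearling,
                 n_subpops = as.integer(n_subpops),
                 year_range = as.integer(year_range),
                 n_none = as.integer(n_none), adult_age = adult_age),
            class = "capture_sim_spec")
}

#' Generate synthetic capture records of females with and without cubs
#'
#' Each litter yields a cub-of-year record at the mother's age of first
#' observation; with probability \code{p_yearling} the same litter is
#' re-observed as yearlings one year later with the mother one year
#' older.  Records share a \code{litter_id} so pseudo-observation pairing
#' can be verified.
#'
#' @param spec a \code{\link{capture_sim_spec}}.
#' @param seed integer seed.
#' @return data frame with columns \code{subpopulation}, \code{year},
#'   \code{age}, \code{cub_class} (\code{"coy"}, \code{"yearling"} or
#'   \code{"none"}) and \code{litter_id} (\code{NA} for \code{"none"}).
#' @export
gen_capture_data <- function(spec, seed) {
  stopifnot(inherits(spec, "capture_sim_spec"))
  if (spec$n_events < 1L) stopf("'n_events' must be at least 1")
  set.seed(seed)
  n <- spec$n_events
  sp <- sprintf("SP%02d", sample.int(spec$n_subpops, n, replace = TRUE))
  yr <- sample(seq(spec$year_range[1], spec$year_range[2]), n, replace = TRUE)
  age <- rnorm(n, spec$true_gl, spec$age_sd)
  while (any(bad <- age < spec$adult_age))   # truncate at adulthood
    age[bad] <- rnorm(sum(bad), spec$true_gl, spec$age_sd)
  coy <- data.frame(subpopulation = sp, year = yr, age = age,
                    cub_class = "coy", litter_id = seq_len(n))
  resee <- runif(n) < spec$p_yearling
  yl <- coy[resee, , drop = FALSE]
  if (nrow(yl)) {
    yl$year <- yl$year + 1L
    yl$age <- yl$age + 1
    yl$cub_class <- "yearling"
  }
  out <- rbind(coy, yl)
  if (spec$n_none > 0L) {
    m <- spec$n_none
    none <- data.frame(
      subpopulation = sprintf("SP%02d",
                              sample.int(spec$n_subpops, m, replace = TRUE)),
      year = sample(seq(spec$year_range[1], spec$year_range[2]), m,
                    replace = TRUE),
      age = pmax(spec$adult_age, rnorm(m, spec$true_gl, spec$age_sd)),
      cub_class = "none", litter_id = NA_integer_)
    out <- rbind(out, none)
  }
  rownames(out) <- NULL
  out
}
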