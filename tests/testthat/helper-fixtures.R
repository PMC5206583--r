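# Shared fixtures, built in code.

# A noise-free sinusoidal daily series: area = mean + A*cos(2*pi*(d - peak)/365)
make_sine_series <- function(n_years = 3, mean_area = 1000, amplitude = 400,
                             start_year = 2000, peak_doy = 75,
                             region_id = "R1") {
  doy <- rep(1:365, n_years)
  year <- rep(start_year + seq_len(n_years) - 1L, each = 365L)
  out <- data.frame(region_id = region_id, year = year, doy = doy,
                    area = mean_area +
                      amplitude * cos(2 * pi * (doy - peak_doy) / 365))
  attr(out, "calendar") <- "365_day"
  class(out) <- c("daily_ice", "data.frame")
  out
}

# daily series from explicit per-day areas for one year
make_daily <- function(area, year = 2000, region_id = "R1") {
  out <- data.frame(region_id = region_id, year = year,
                    doy = seq_along(area), area = area)
  attr(out, "calendar") <- "365_day"
  class(out) <- c("daily_ice", "data.frame")
  out
}

# an ice_trend with exactly chosen coefficients and covariance, for
# projection tests that need full control of the sampling distribution
make_trend <- function(intercept, slope, V = matrix(0, 2, 2),
                       region_id = "R1") {
  dimnames(V) <- list(c("intercept", "slope"), c("intercept", "slope"))
  structure(list(region_id = region_id,
                 coefficients = c(intercept = intercept, slope = slope),
                 vcov = V, sigma = 0, n = 0L, year_range = c(NA, NA),
                 data = NULL),
            class = "ice_trend")
}

make_relation <- function(beta, beta_se, scope = "global") {
  structure(list(scope = scope, beta = beta, beta_se = beta_se,
                 n_obs = NA_integer_, sigma = NA_real_, intercept = 0),
            class = "relation_fit")
}

# one small study world shared across test files (built once per run)
get_test_world <- local({
  w <- NULL
  function() {
    if (is.null(w))
      w <<- gen_study_world(seed = 7011, grid_shape = c(6L, 6L),
                            cell_area = 45000, n_events = 600)
    w
  }
})

# Table 1's printed probability columns (six scenarios: approaches 1-3
# at GL 11.5 and 13.6 years)
table1_probs <- function() {
  m <- rbind(c(1.00, 0.56, 0.00, 0.00),
             c(1.00, 0.95, 0.00, 0.00),
             c(0.55, 0.20, 0.06, 0.00),
             c(0.55, 0.24, 0.08, 0.00),
             c(1.00, 0.86, 0.30, 0.01),
             c(1.00, 0.88, 0.35, 0.02))
  colnames(m) <- c("0", "30", "50", "80")
  m
}
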