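# The standardized habitat metric: per region and year, the number of
# days the region's daily sea-ice area exceeds the midpoint between its
# mean summer-minimum and mean winter-maximum areas ("ice-covered days").

#' Define a subpopulation region on the concentration grid
#'
#' @param region_id character scalar.
#' @param ecoregion one of \code{"convergent"}, \code{"divergent"},
#'   \code{"archipelago"}, \code{"seasonal"}.
#' @param cell_ids character vector of grid cell identifiers.
#' @param cell_areas cell areas in km^2, recycled if scalar.
#' @return an object of class \code{region_definition}.
#' @export
region_definition <- function(region_id, ecoregion, cell_ids, cell_areas) {
  ecoregion <- match.arg(ecoregion,
                         c("convergent", "divergent", "archipelago", "seasonal"))
  if (length(cell_ids) == 0L) stopf("region '%s' has no cells", region_id)
  if (length(cell_areas) == 1L) cell_areas <- rep(cell_areas, length(cell_ids))
  if (any(cell_areas <= 0)) stopf("cell areas must be > 0")
  structure(list(region_id = region_id, ecoregion = ecoregion,
                 cell_ids = as.character(cell_ids), cell_areas = cell_areas),
            class = "region_definition")
}

#' Daily sea-ice area of a region from one day's concentration grid
#'
#' Sums concentration times cell area over the region's cells whose
#' concentration strictly exceeds the cutoff (default 15\%), the standard
#' passive-microwave convention for separating ice from open water.
#'
#' @param conc named numeric vector of per-cell ice concentration
#'   fractions in \code{[0, 1]} (names are cell ids).
#' @param region a \code{\link{region_definition}}.
#' @param cutoff concentration cutoff, strict (default 0.15).
#' @return ice area in km^2 (0 when no cell exceeds the cutoff).
#' @examples
#' r <- region_definition("A", "seasonal", c("c1", "c2", "c3"), 625)
#' daily_ice_area(c(c1 = 0.10, c2 = 0.50, c3 = 0.80), r)  # 812.5
#' @export
daily_ice_area <- function(conc, region, cutoff = 0.15) {
  stopifnot(inherits(region, "region_definition"))
  miss <- setdiff(region$cell_ids, names(conc))
  if (length(miss))
    stopf("concentration grid is missing region cells: %s",
          paste(miss, collapse = ", "))
  v <- conc[region$cell_ids]
  if (any(!is.finite(v)) || any(v < 0 | v > 1))
    stopf("concentrations must be finite and in [0, 1]")
  sum(v * region$cell_areas * (v > cutoff))
}

#' Daily ice-area series of a region from a concentration field
#'
#' Applies \code{\link{daily_ice_area}} to every day of an
#' \code{ice_field} (from \code{\link{gen_ice_concentration}} or
#' \code{\link{read_concentration}}).
#'
#' @param field an \code{ice_field}.
#' @param region a \code{\link{region_definition}}; defaults to all cells
#'   of the field grouped as one region.
#' @param cutoff concentration cutoff, strict.
#' @return a \code{daily_ice} data frame with columns \code{region_id},
#'   \code{year}, \code{doy}, \code{area}; the field's calendar
#'   (\code{"365_day"} or \code{"gregorian"}) is kept as an attribute.
#' @export
daily_ice_series <- function(field, region = NULL, cutoff = 0.15) {
  stopifnot(inherits(field, "ice_field"))
  if (is.null(region))
    region <- region_definition(field$spec$region_id %||% "all", "seasonal",
                                field$cell_id, field$cell_area)
  miss <- setdiff(region$cell_ids, colnames(field$conc))
  if (length(miss))
    stopf("field is missing region cells: %s", paste(miss, collapse = ", "))
  m <- field$conc[, region$cell_ids, drop = FALSE]
  area <- as.numeric((m * (m > cutoff)) %*% region$cell_areas)
  out <- data.frame(region_id = region$region_id, year = field$year,
                    doy = field$doy, area = area)
  attr(out, "calendar") <- field$calendar %||% "365_day"
  class(out) <- c("daily_ice", "data.frame")
  out
}

#' Fill short gaps in a daily ice-area series
#'
#' Interior runs of missing days (absent rows or \code{NA} areas) of
#' length at most \code{max_gap} are filled by linear interpolation
#' between their neighbours; leading/trailing gaps take the nearest
#' observed value.  Longer gaps are an error.
#'
#' @param series a \code{daily_ice} data frame.
#' @param max_gap longest fillable run of consecutive missing days.
#' @return the gap-free series.
#' @export
fill_gaps <- function(series, max_gap = 5L) {
  cal <- attr(series, "calendar") %||% "365_day"
  series <- series[order(series$year, series$doy), , drop = FALSE]
  years <- seq(min(series$year), max(series$year))
  diy <- days_in_year(years, cal)
  grid <- data.frame(year = rep(years, diy),
                     doy = unlist(lapply(diy, seq_len), use.names = FALSE))
  # continuous day index across the whole record
  off <- c(0L, cumsum(diy))[match(grid$year, years)]
  grid$t <- off + grid$doy
  key_g <- paste(grid$year, grid$doy)
  key_s <- paste(series$year, series$doy)
  grid$area <- series$area[match(key_g, key_s)]
  missing <- !is.finite(grid$area)
  if (any(missing)) {
    r <- rle(missing)
    # interior gaps only; leading/trailing handled by rule = 2 below
    inner <- r$values & seq_along(r$values) > 1 &
      seq_along(r$values) < length(r$values)
    if (any(r$lengths[inner] > max_gap))
      stopf("gap of %d consecutive missing days exceeds max_gap = %d",
            max(r$lengths[inner]), max_gap)
    ok <- !missing
    if (sum(ok) < 2L) stopf("fewer than 2 observed days; cannot interpolate")
    grid$area[missing] <- approx(grid$t[ok], grid$area[ok],
                                 xout = grid$t[missing], rule = 2)$y
  }
  out <- data.frame(region_id = series$region_id[1], year = grid$year,
                    doy = grid$doy, area = grid$area)
  attr(out, "calendar") <- cal
  class(out) <- c("daily_ice", "data.frame")
  out
}

#' Annual summer-minimum and winter-maximum ice areas
#'
#' @param series a (gap-filled) \code{daily_ice} data frame.
#' @param year calendar year.
#' @param min_days minimum day coverage required in the year.
#' @return named numeric vector \code{c(summer_min =, winter_max =)}.
#' @export
annual_extremes <- function(series, year, min_days = 300L) {
  a <- series$area[series$year == year]
  a <- a[is.finite(a)]
  if (length(a) < min_days)
    stopf("year %d has only %d days with data (need >= %d)",
          year, length(a), min_days)
  c(summer_min = min(a), winter_max = max(a))
}

#' Midpoint ice-area threshold of a region
#'
#' The threshold above which a day counts as ice-covered: half the sum of
#' the mean annual summer minimum and the mean annual winter maximum over
#' the baseline years.  One fixed threshold per region makes the yearly
#' counts comparable across the record, which the trend analysis
#' requires.
#'
#' @param series a \code{daily_ice} data frame.
#' @param baseline_years years entering the baseline means; default all
#'   years present.
#' @return midpoint area, km^2.
#' @export
compute_midpoint <- function(series, baseline_years = NULL) {
  baseline_years <- baseline_years %||% sort(unique(series$year))
  if (length(baseline_years) == 0L) stopf("empty baseline")
  ext <- vapply(baseline_years, function(y) annual_extremes(series, y),
                numeric(2))
  (mean(ext["summer_min", ]) + mean(ext["winter_max", ])) / 2
}

#' Ice-covered days in one year
#'
#' Counts the days of the calendar year whose daily ice area is strictly
#' greater than the midpoint threshold.
#'
#' @param series a (gap-filled) \code{daily_ice} data frame.
#' @param midpoint threshold area, km^2.
#' @param year calendar year.
#' @param min_days minimum day coverage required.
#' @return integer day count.
#' @export
ice_covered_days <- function(series, midpoint, year, min_days = 300L) {
  a <- series$area[series$year == year]
  a <- a[is.finite(a)]
  if (length(a) < min_days)
    stopf("year %d has only %d days with data (need >= %d)",
          year, length(a), min_days)
  sum(a > midpoint)
}

#' Annual ice-covered-day series of a region
#'
#' Computes the region's midpoint threshold once over the baseline years,
#' then the per-year count of ice-covered days.
#'
#' @param series a (gap-filled) \code{daily_ice} data frame.
#' @param baseline_years years for the midpoint baseline; default all.
#' @return an \code{annual_ice} data frame with columns \code{region_id},
#'   \code{year}, \code{ice}, \code{midpoint}.
#' @export
annual_ice_series <- function(series, baseline_years = NULL) {
  mid <- compute_midpoint(series, baseline_years)
  years <- sort(unique(series$year))
  out <- data.frame(region_id = series$region_id[1], year = years,
                    ice = vapply(years, function(y)
                      ice_covered_days(series, mid, y), numeric(1)),
                    midpoint = mid)
  class(out) <- c("annual_ice", "data.frame")
  out
}

#' Fit a linear trend to an annual ice-covered-day series
#'
#' Ordinary least squares of ice-covered days on calendar year.  The year
#' is centred internally for numerical stability; coefficients and their
#' covariance are reported on the calendar scale.
#'
#' @param annual an \code{annual_ice} data frame (columns \code{year},
#'   \code{ice}; \code{region_id} optional).
#' @return an object of class \code{ice_trend}: coefficients
#'   \code{(intercept, slope)}, their 2x2 covariance matrix, residual
#'   standard deviation \code{sigma}, and the data.
#' @export
fit_ice_trend <- function(annual) {
  n <- nrow(annual)
  if (n < 3L) stopf("need at least 3 years to fit a trend, got %d", n)
  ybar <- mean(annual$year)
  fit <- lm(ice ~ I(year - ybar), data = annual)
  b <- unname(coef(fit))
  # summary.lm warns on exact fits (residual sd 0); those are legitimate
  # degenerate inputs here
  V <- unname(suppressWarnings(vcov(fit)))
  # back-transform intercept to calendar scale: a = a_c - b*ybar
  a_cal <- b[1] - b[2] * ybar
  V_cal <- matrix(c(V[1, 1] + ybar^2 * V[2, 2] - 2 * ybar * V[1, 2],
                    V[1, 2] - ybar * V[2, 2],
                    V[1, 2] - ybar * V[2, 2],
                    V[2, 2]), 2, 2)
  dimnames(V_cal) <- list(c("intercept", "slope"), c("intercept", "slope"))
  structure(list(region_id = annual$region_id[1] %||% NA_character_,
                 coefficients = c(intercept = a_cal, slope = b[2]),
                 vcov = V_cal, sigma = suppressWarnings(summary(fit)$sigma),
                 n = n,
                 year_range = range(annual$year), data = annual),
            class = "ice_trend")
}

#' @export
coef.ice_trend <- function(object, ...) object$coefficients

#' @export
vcov.ice_trend <- function(object, ...) object$vcov

#' Predict mean ice-covered days from a fitted trend
#'
#' @param object an \code{ice_trend}.
#' @param year calendar years to predict at.
#' @param se.fit also return the standard error of the mean prediction.
#' @param ... unused.
#' @return numeric vector of unclamped predictions, or a list with
#'   \code{fit} and \code{se.fit}.
#' @export
predict.ice_trend <- function(object, year, se.fit = FALSE, ...) {
  b <- object$coefficients
  fit <- b[["intercept"]] + b[["slope"]] * year
  if (!se.fit) return(fit)
  V <- object$vcov
  se <- sqrt(V[1, 1] + year^2 * V[2, 2] + 2 * year * V[1, 2])
  list(fit = fit, se.fit = se)
}

#' Project ice-covered days to a future year
#'
#' Point prediction from the fitted linear trend, clamped to the feasible
#' day-count range \code{[0, 366]}, with the standard error of the mean
#' prediction.
#'
#' @param trend an \code{ice_trend}.
#' @param year calendar year (at or beyond the fitted record).
#' @return named vector \code{c(fit =, se =)}; \code{fit} is clamped.
#' @export
project_ice <- function(trend, year) {
  p <- predict(trend, year, se.fit = TRUE)
  c(fit = unname(clamp(p$fit, 0, 366)), se = unname(p$se.fit))
}

#' @export
print.ice_trend <- function(x, ...) {
  cat(sprintf("Ice-covered-day trend for region '%s' (%d-%d, n = %d)\n",
              x$region_id, x$year_range[1], x$year_range[2], x$n))
  cat(sprintf("  slope: %.3f days/yr (se %.3f), residual sd %.2f days\n",
              coef(x)[["slope"]], sqrt(x$vcov[2, 2]), x$sigma))
  invisible(x)
}

#' Plot an annual ice series with its fitted trend
#'
#' @param x an \code{ice_trend}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.ice_trend <- function(x, ...) {
  d <- x$data
  plot(d$year, d$ice, xlab = "year", ylab = "ice-covered days",
       main = sprintf("%s: %.2f days/yr", x$region_id, coef(x)[["slope"]]),
       pch = 16, ...)
  abline(coef(x)[["intercept"]], coef(x)[["slope"]], col = "steelblue")
  invisible(x)
}
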