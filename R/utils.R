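# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going up (away from zero for
#' positive input), so that three generations of 11.5 years gives a
#' 35-year horizon and three of 13.6 years gives 41.  Base R's
#' \code{round()} rounds half to even, which would give 34.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) as.integer(floor(x + 0.5))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 365-day synthetic calendar vs. real (Gregorian) year lengths
days_in_year <- function(year, calendar = c("365_day", "gregorian")) {
  calendar <- match.arg(calendar)
  if (calendar == "365_day") return(rep(365L, length(year)))
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  ifelse(leap, 366L, 365L)
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lo || x > hi)
    stopf("'%s' must be in [%s, %s], got %s", name, format(lo), format(hi),
          format(x))
  invisible(x)
}
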