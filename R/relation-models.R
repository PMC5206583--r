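# Three ways of relating the habitat metric to abundance:
#   approach 1 -- one-to-one proportionality between ice-covered days
#                 and abundance (habitat-only projection);
#   approach 2 -- a single global fitted relation between the annual
#                 change in ice-covered days and the annualized
#                 proportional (log-scale) change in N;
#   approach 3 -- the same relation fitted separately per ecoregion.

#' Paired ice/abundance changes for relation fitting
#'
#' For each subpopulation, converts abundance estimates and the matching
#' annual ice series into observations of annualized proportional change
#' in N (\eqn{r_N = \ln(N_2/N_1)/\Delta t}) against the annual change in
#' ice-covered days over the same interval (\code{d_ice}, the OLS slope
#' of ice on year over the interval -- robust to single-year ice noise).
#'
#' \code{"two-point"} mode uses only the earliest and latest estimates
#' and requires them to be at least \code{min_span} years apart
#' (subpopulations failing this are skipped with a message);
#' \code{"series"} mode uses every consecutive pair of estimates at any
#' span.
#'
#' @param estimates data frame with columns \code{subpopulation},
#'   \code{year}, \code{n} and optionally \code{ecoregion}.
#' @param annual_ice an \code{annual_ice} data frame covering all
#'   subpopulations in \code{estimates} (matched on
#'   \code{region_id == subpopulation}).
#' @param mode \code{"two-point"} or \code{"series"}.
#' @param min_span minimum span in years for two-point pairs.
#' @return data frame with columns \code{subpopulation},
#'   \code{ecoregion}, \code{r_n}, \code{d_ice}, \code{span}.
#' @export
paired_changes <- function(estimates, annual_ice,
                           mode = c("two-point", "series"), min_span = 10) {
  mode <- match.arg(mode)
  stopifnot(all(c("subpopulation", "year", "n") %in% names(estimates)))
  has_eco <- "ecoregion" %in% names(estimates)
  out <- list()
  for (sp in unique(estimates$subpopulation)) {
    est <- estimates[estimates$subpopulation == sp, , drop = FALSE]
    est <- est[order(est$year), , drop = FALSE]
    if (nrow(est) < 2L) next
    ice <- annual_ice[annual_ice$region_id == sp, , drop = FALSE]
    if (nrow(ice) == 0L)
      stopf("no ice series for subpopulation '%s'", sp)
    pairs <- if (mode == "two-point") {
      p <- est[c(1L, nrow(est)), ]
      if (diff(p$year) < min_span) {
        message(sprintf(
          "skipping '%s': largest span %d yr < %g yr required", sp,
          diff(p$year), min_span))
        next
      }
      list(p)
    } else {
      lapply(seq_len(nrow(est) - 1L), function(i) est[i:(i + 1L), ])
    }
    for (p in pairs) {
      span <- p$year[2] - p$year[1]
      win <- ice[ice$year >= p$year[1] & ice$year <= p$year[2], , drop = FALSE]
      if (nrow(win) < 2L)
        stopf("ice series for '%s' does not cover %d-%d", sp,
              p$year[1], p$year[2])
      d_ice <- if (nrow(win) == 2L) diff(win$ice) / diff(win$year)
               else unname(coef(lm(ice ~ year, data = win))[2])
      out[[length(out) + 1L]] <- data.frame(
        subpopulation = sp,
        ecoregion = if (has_eco) p$ecoregion[1] else NA_character_,
        r_n = log(p$n[2] / p$n[1]) / span, d_ice = d_ice, span = span)
    }
  }
  if (length(out) == 0L)
    return(data.frame(subpopulation = character(), ecoregion = character(),
                      r_n = numeric(), d_ice = numeric(), span = numeric()))
  do.call(rbind, out)
}

#' Fit an ice-abundance relation
#'
#' No-intercept least squares of the annualized proportional change in N
#' on the annual change in ice-covered days, so that zero ice change
#' predicts stable N.  The slope \eqn{\beta} is the proportional change
#' in N per ice-covered-day change per year.
#'
#' @param observations data frame from \code{\link{paired_changes}}.
#' @param scope \code{"global"} or an ecoregion name; a non-global scope
#'   filters \code{observations} by their \code{ecoregion} column.
#' @param intercept fit an intercept as well (off by default).
#' @return an object of class \code{relation_fit} with fields
#'   \code{scope}, \code{beta}, \code{beta_se}, \code{n_obs},
#'   \code{sigma}, \code{data}.
#' @export
fit_relation <- function(observations, scope = "global", intercept = FALSE) {
  obs <- if (identical(scope, "global")) observations
         else observations[observations$ecoregion %in% scope, , drop = FALSE]
  n <- nrow(obs)
  if (n < 2L)
    stopf("need at least 2 observations for scope '%s', got %d", scope, n)
  if (all(obs$d_ice == 0))
    stopf("all d_ice are 0 for scope '%s': slope unidentifiable", scope)
  fit <- if (intercept) lm(r_n ~ d_ice, data = obs)
         else lm(r_n ~ 0 + d_ice, data = obs)
  sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  co <- sm$coefficients
  i <- if (intercept) 2L else 1L
  structure(list(scope = scope, beta = unname(co[i, 1]),
                 beta_se = unname(co[i, 2]), n_obs = n,
                 sigma = sm$sigma,
                 intercept = if (intercept) unname(co[1, 1]) else 0,
                 data = obs, lm = fit),
            class = "relation_fit")
}

#' Fit one relation per ecoregion
#'
#' @param observations data frame from \code{\link{paired_changes}} with
#'   an \code{ecoregion} column.
#' @param ... passed to \code{\link{fit_relation}}.
#' @return named list of \code{relation_fit} objects, one per ecoregion
#'   present in the observations.
#' @export
fit_relations_by_ecoregion <- function(observations, ...) {
  ecos <- sort(unique(observations$ecoregion))
  fits <- lapply(ecos, function(e) fit_relation(observations, scope = e, ...))
  names(fits) <- ecos
  fits
}

#' @export
coef.relation_fit <- function(object, ...) c(beta = object$beta)

#' @export
vcov.relation_fit <- function(object, ...)
  matrix(object$beta_se^2, dimnames = list("beta", "beta"))

#' @export
print.relation_fit <- function(x, ...) {
  cat(sprintf("Ice-abundance relation [%s]: beta = %.4f (se %.4f), n = %d\n",
              x$scope, x$beta, x$beta_se, x$n_obs))
  invisible(x)
}

#' Habitat-proportional change in abundance (approach 1)
#'
#' Under one-to-one proportionality between abundance and ice-covered
#' days, the proportional change in N from \code{start_year} over
#' \code{horizon_years} is the ratio of projected ice-covered days minus
#' one, floored at -1 (extirpation).
#'
#' @param trend an \code{\link{fit_ice_trend}} object.
#' @param start_year projection start.
#' @param horizon_years projection length in years.
#' @return proportional change in N (e.g. -0.25 for a 25\% decline).
#' @export
approach1_change <- function(trend, start_year, horizon_years) {
  base <- project_ice(trend, start_year)[["fit"]]
  if (base <= 0)
    stopf("projected ice at start year %d is %g days; proportional change undefined",
          start_year, base)
  fut <- project_ice(trend, start_year + horizon_years)[["fit"]]
  max(fut / base - 1, -1)
}
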