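# Stochastic projection of per cent change in mean global population
# size (MGPS) over three generations.  Each Monte Carlo replicate draws
# regression coefficients from their estimated sampling distributions,
# projects every subpopulation, aggregates to MGPS weighted by the most
# recent abundance estimates, and the replicate distribution is scored
# against the IUCN Red List criterion A3 reduction thresholds.

#' Define a projection scenario
#'
#' A scenario is one combination of relation approach and generation
#' length.  The projection horizon is three generations, rounded half up
#' to whole years (3 x 11.5 = 34.5 -> 35; 3 x 13.6 = 40.8 -> 41).
#'
#' @param approach 1 (habitat-proportional), 2 (global fitted relation)
#'   or 3 (ecoregion-specific fitted relations).
#' @param gl generation length in years.
#' @param n_sims Monte Carlo replicates (default 62500).
#' @param seed integer seed for the scenario's draw streams.
#' @return an object of class \code{scenario}.
#' @export
scenario <- function(approach, gl, n_sims = 62500L, seed = 1L) {
  approach <- as.integer(approach)
  if (!approach %in% 1:3) stopf("'approach' must be 1, 2 or 3")
  assert_scalar_number(gl, "gl")
  if (gl <= 0) stopf("'gl' must be > 0")
  assert_scalar_number(n_sims, "n_sims", lo = 1)
  structure(list(approach = approach, gl = gl,
                 horizon = round_half_up(3 * gl),
                 n_sims = as.integer(n_sims), seed = as.integer(seed)),
            class = "scenario")
}

#' Draw coefficients from a fitted object's sampling distribution
#'
#' Coefficient uncertainty is propagated by simulation: draws are normal
#' with mean equal to the point estimate and standard deviation equal to
#' the standard error (jointly normal with the full estimated covariance
#' for an ice trend's slope and intercept).  Zero standard errors give
#' degenerate draws at the point estimate.
#'
#' @param fit a \code{relation_fit} or \code{ice_trend}.
#' @param n_sims number of draws.
#' @param seed integer seed.
#' @return for a \code{relation_fit}, a numeric vector of beta draws; for
#'   an \code{ice_trend}, an \code{n_sims} x 2 matrix with columns
#'   \code{intercept}, \code{slope}.
#' @export
simulate_coefficients <- function(fit, n_sims, seed) {
  set.seed(seed)
  draw_coefficients(fit, n_sims)
}

draw_coefficients <- function(fit, n_sims) UseMethod("draw_coefficients")

#' @export
draw_coefficients.relation_fit <- function(fit, n_sims) {
  if (!is.finite(fit$beta_se)) stopf("relation fit has no standard error")
  if (fit$beta_se == 0) rep(fit$beta, n_sims)
  else rnorm(n_sims, fit$beta, fit$beta_se)
}

#' @export
draw_coefficients.ice_trend <- function(fit, n_sims) {
  V <- fit$vcov
  if (any(!is.finite(V))) stopf("ice trend has no coefficient covariance")
  m <- if (all(V == 0)) {
    matrix(rep(fit$coefficients, each = n_sims), n_sims, 2)
  } else {
    MASS::mvrnorm(n_sims, mu = fit$coefficients, Sigma = V)
  }
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  colnames(m) <- c("intercept", "slope")
  m
}

#' Terminal proportional change of one subpopulation per draw
#'
#' Approaches 2-3 compound the annual log-change \eqn{\beta \Delta ice}
#' over the horizon: \eqn{\exp(\beta\,slope\,h) - 1}.  Approach 1 takes
#' the ratio of projected ice-covered days (clamped to \code{[0, 366]})
#' at the end versus the start of the horizon, under the drawn trend
#' line.  All changes are floored at -1; an approach-1 draw whose
#' baseline ice is non-positive is taken as complete habitat loss (-1).
#'
#' @param approach 1, 2 or 3.
#' @param horizon projection length in years.
#' @param trend_draws matrix of \code{(intercept, slope)} draws
#'   (approach 1 uses both columns; approaches 2-3 use \code{slope}).
#' @param beta_draws vector of relation-slope draws (approaches 2-3).
#' @param start_year projection start (approach 1).
#' @return numeric vector of proportional changes, one per draw.
#' @export
project_subpopulation <- function(approach, horizon, trend_draws,
                                  beta_draws = NULL, start_year = NULL) {
  slope <- unname(trend_draws[, "slope"])
  if (approach == 1L) {
    if (is.null(start_year)) stopf("approach 1 needs 'start_year'")
    a <- unname(trend_draws[, "intercept"])
    base <- clamp(a + slope * start_year, 0, 366)
    fut <- clamp(a + slope * (start_year + horizon), 0, 366)
    ch <- ifelse(base > 0, fut / base - 1, -1)
  } else {
    if (is.null(beta_draws)) stopf("approaches 2-3 need 'beta_draws'")
    ch <- exp(beta_draws * slope * horizon) - 1
  }
  pmax(ch, -1)
}

#' Aggregate subpopulation changes to per cent change in MGPS
#'
#' Weighted mean of proportional changes, weighted by each
#' subpopulation's most recent abundance estimate, expressed in per
#' cent.
#'
#' @param changes named numeric vector (one change per subpopulation) or
#'   a draws x subpopulations matrix with column names.
#' @param weights named positive weights (latest N per subpopulation);
#'   names must match those of \code{changes} exactly.
#' @return per cent change in MGPS (vector of length 1 or \code{nrow(changes)}).
#' @export
aggregate_mgps <- function(changes, weights) {
  nm <- if (is.matrix(changes)) colnames(changes) else names(changes)
  if (is.null(nm) || !setequal(nm, names(weights)) ||
      length(nm) != length(weights))
    stopf("subpopulation sets of 'changes' and 'weights' do not match")
  if (any(weights <= 0)) stopf("weights must be > 0")
  w <- weights[nm]
  if (is.matrix(changes)) 100 * as.numeric(changes %*% w) / sum(w)
  else 100 * sum(changes * w) / sum(w)
}

#' Run one projection scenario
#'
#' Draws coefficients, projects every subpopulation, and aggregates to
#' the Monte Carlo distribution of per cent change in MGPS.  Within a
#' replicate a single coefficient draw is shared by all subpopulations of
#' a scope (one global beta for approach 2, one per ecoregion for
#' approach 3) because the scope-level coefficient is a single uncertain
#' quantity, while ice-trend draws are per-subpopulation.  Each uncertain
#' quantity gets its own seeded stream derived from \code{scenario$seed}
#' and a fixed stream index (sorted scope names, then sorted
#' subpopulation names), so a rerun is bit-identical and a run with more
#' replicates extends, rather than reshuffles, a shorter one.
#'
#' @param scn a \code{\link{scenario}}.
#' @param trends named list of \code{ice_trend} objects, one per
#'   subpopulation to project.
#' @param weights named vector of latest abundance per subpopulation.
#' @param global_fit \code{relation_fit} (approach 2).
#' @param eco_fits named list of \code{relation_fit} by ecoregion
#'   (approach 3).
#' @param ecoregions named character vector mapping subpopulation ->
#'   ecoregion (approach 3).
#' @param start_year projection start year.
#' @param keep_draws keep the replicate MGPS changes in the result.
#' @return an object of class \code{projection_summary}: median change,
#'   95\% percentile interval, and probabilities that the reduction in
#'   MGPS is at least 0\%, 30\%, 50\% and 80\%.
#' @export
run_scenario <- function(scn, trends, weights, global_fit = NULL,
                         eco_fits = NULL, ecoregions = NULL,
                         start_year = 2015L, keep_draws = FALSE) {
  stopifnot(inherits(scn, "scenario"))
  sps <- sort(names(trends))
  if (!setequal(sps, names(weights)))
    stopf("subpopulations of 'trends' and 'weights' do not match")
  n <- scn$n_sims
  # one seeded normal stream per uncertain quantity (common random
  # numbers: the first m draws of every stream are the same for any run
  # with n_sims >= m)
  stream_id <- 0L
  next_stream <- function(sd_val, mean_val = 0) {
    stream_id <<- stream_id + 1L
    set.seed(scn$seed %% 1000000L + 104729L * stream_id)
    if (sd_val == 0) rep(mean_val, n) else rnorm(n, mean_val, sd_val)
  }
  draw_trend <- function(tr) {
    V <- tr$vcov
    if (any(!is.finite(V))) stopf("ice trend has no coefficient covariance")
    if (all(V == 0)) {
      z1 <- next_stream(0); z2 <- next_stream(0)
      m <- matrix(rep(tr$coefficients, each = n), n, 2)
    } else {
      L <- t(chol(V))
      z1 <- next_stream(1); z2 <- next_stream(1)
      m <- cbind(tr$coefficients[1] + L[1, 1] * z1,
                 tr$coefficients[2] + L[2, 1] * z1 + L[2, 2] * z2)
    }
    colnames(m) <- c("intercept", "slope")
    m
  }
  beta_by_sp <- NULL
  if (scn$approach == 2L) {
    if (is.null(global_fit)) stopf("approach 2 needs 'global_fit'")
    if (!is.finite(global_fit$beta_se))
      stopf("relation fit has no standard error")
    b <- next_stream(global_fit$beta_se, global_fit$beta)
    beta_by_sp <- lapply(stats::setNames(sps, sps), function(s) b)
  } else if (scn$approach == 3L) {
    if (is.null(eco_fits) || is.null(ecoregions))
      stopf("approach 3 needs 'eco_fits' and 'ecoregions'")
    miss <- setdiff(unique(ecoregions[sps]), names(eco_fits))
    if (length(miss))
      stopf("no ecoregion fit for: %s", paste(miss, collapse = ", "))
    eco_draws <- lapply(stats::setNames(sort(names(eco_fits)),
                                        sort(names(eco_fits))),
                        function(e) next_stream(eco_fits[[e]]$beta_se,
                                                eco_fits[[e]]$beta))
    beta_by_sp <- lapply(stats::setNames(sps, sps),
                         function(s) eco_draws[[ecoregions[[s]]]])
  }
  changes <- matrix(NA_real_, n, length(sps), dimnames = list(NULL, sps))
  for (s in sps) {
    td <- draw_trend(trends[[s]])
    changes[, s] <- project_subpopulation(scn$approach, scn$horizon, td,
                                          beta_draws = beta_by_sp[[s]],
                                          start_year = start_year)
  }
  mgps <- aggregate_mgps(changes, weights)
  q <- unname(quantile(mgps, c(0.025, 0.5, 0.975), type = 7))
  p <- reduction_probabilities(mgps)
  structure(list(scenario = scn, median_change = q[2], ci_low = q[1],
                 ci_high = q[3], p_decline = p, start_year = start_year,
                 draws = if (keep_draws) mgps else NULL),
            class = "projection_summary")
}

#' Reduction-threshold exceedance probabilities
#'
#' Fraction of Monte Carlo replicates whose reduction in MGPS
#' (\code{-change}) is at least each threshold.
#'
#' @param changes_pct replicate per cent changes in MGPS.
#' @param thresholds reduction thresholds in per cent.
#' @return named probability vector.
#' @export
reduction_probabilities <- function(changes_pct, thresholds = c(0, 30, 50, 80)) {
  p <- vapply(thresholds, function(k) mean(-changes_pct >= k), numeric(1))
  stats::setNames(p, as.character(thresholds))
}

#' @export
print.projection_summary <- function(x, ...) {
  s <- x$scenario
  cat(sprintf(
    "Approach %d, GL %.1f yr (horizon %d yr, %d sims):\n", s$approach, s$gl,
    s$horizon, s$n_sims))
  cat(sprintf("  MGPS change: %.1f%% (95%% CI %.1f to %.1f)\n",
              x$median_change, x$ci_low, x$ci_high))
  cat(sprintf("  P(reduction >= 0/30/50/80%%): %s\n",
              paste(sprintf("%.2f", x$p_decline), collapse = " / ")))
  invisible(x)
}

#' Summarize threshold probabilities across scenarios
#'
#' For each Red List reduction threshold, the median, minimum and
#' maximum of the per-scenario exceedance probabilities (the median of
#' an even number of scenarios is the mean of the two central values).
#'
#' @param summaries list of \code{projection_summary} objects, or a
#'   numeric matrix of probabilities with one row per scenario and one
#'   column per threshold (named \code{"0"}, \code{"30"}, \code{"50"},
#'   \code{"80"}).
#' @return an object of class \code{scenario_summary}: a data frame
#'   (\code{threshold}, \code{median}, \code{min}, \code{max}) plus the
#'   per-scenario probability matrix.
#' @export
summarize_scenarios <- function(summaries) {
  pm <- if (is.matrix(summaries)) summaries
  else {
    if (length(summaries) == 0L) stopf("no scenario summaries")
    do.call(rbind, lapply(summaries, function(s) s$p_decline))
  }
  if (nrow(pm) == 0L) stopf("no scenario summaries")
  tab <- data.frame(threshold = as.numeric(colnames(pm)),
                    median = apply(pm, 2, median),
                    min = apply(pm, 2, min),
                    max = apply(pm, 2, max), row.names = NULL)
  structure(list(table = tab, probabilities = pm), class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf("Across %d scenarios, P(MGPS reduction >= threshold):\n",
              nrow(x$probabilities)))
  print(format(x$table, digits = 3), row.names = FALSE)
  invisible(x)
}

#' IUCN Red List criterion A3 category from reduction probabilities
#'
#' Criterion A3 classifies a taxon by projected population reduction
#' over three generations: >= 30\% vulnerable, >= 50\% endangered,
#' >= 80\% critically endangered.  Following the Red List risk-tolerance
#' guidance, the category assigned is the highest one whose reduction
#' threshold is exceeded with probability at least \code{tolerance}.
#'
#' @param x a \code{projection_summary}, a \code{scenario_summary}
#'   (cross-scenario medians are used), or a named probability vector
#'   with names \code{"0"}, \code{"30"}, \code{"50"}, \code{"80"}.
#' @param tolerance probability required to assign a category
#'   (default 0.5).
#' @return an object of class \code{red_list_result} with fields
#'   \code{category}, \code{rule}, \code{tolerance},
#'   \code{probabilities}.
#' @export
red_list_category <- function(x, tolerance = 0.5) {
  p <- if (inherits(x, "projection_summary")) x$p_decline
  else if (inherits(x, "scenario_summary"))
    stats::setNames(x$table$median, as.character(x$table$threshold))
  else x
  need <- c("30", "50", "80")
  if (!all(need %in% names(p)))
    stopf("need probabilities named %s", paste(need, collapse = ", "))
  ord <- p[intersect(c("0", "30", "50", "80"), names(p))]
  if (is.unsorted(rev(ord), strictly = FALSE))
    stopf("threshold probabilities must be non-increasing in the threshold")
  cat_def <- c("80" = "critically-endangered", "50" = "endangered",
               "30" = "vulnerable")
  category <- "least-concern-range"
  rule <- sprintf("no reduction threshold reached P >= %.2f", tolerance)
  for (k in names(cat_def)) {
    if (p[[k]] >= tolerance) {
      category <- cat_def[[k]]
      rule <- sprintf("P(reduction >= %s%%) = %.2f >= tolerance %.2f",
                      k, p[[k]], tolerance)
      break
    }
  }
  structure(list(category = category, rule = rule, tolerance = tolerance,
                 probabilities = p), class = "red_list_result")
}

#' @export
print.red_list_result <- function(x, ...) {
  cat(sprintf("Red List criterion A3 category: %s\n  rule: %s\n",
              x$category, x$rule))
  invisible(x)
}
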