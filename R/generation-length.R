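# Generation length (GL): the mean age of adult females with new cubs,
# the quantity that sets the three-generation assessment horizon.

#' Build reproductive events from capture records
#'
#' Cub-of-year captures become observed reproductive events at the year
#' and age of capture.  Females seen with 1-year-old cubs in year t+1 are
#' back-dated to pseudo-observations of a reproductive event in year t at
#' age minus one, recovering litters whose birth year was not sampled.
#' Records whose implied event age falls below the adult threshold are
#' dropped with a warning; \code{"none"} records are ignored.
#'
#' @param captures data frame with columns \code{year}, \code{age},
#'   \code{cub_class} (\code{"coy"}, \code{"yearling"}, \code{"none"})
#'   and optionally \code{subpopulation}.
#' @param adult_age minimum age of an adult mother (default 5: age >= 4
#'   at conception).
#' @return data frame of events with columns \code{subpopulation} (if
#'   present in the input), \code{year}, \code{mother_age},
#'   \code{source} (\code{"observed"} or \code{"pseudo"}).
#' @export
build_pseudo_observations <- function(captures, adult_age = 5) {
  stopifnot(all(c("year", "age", "cub_class") %in% names(captures)))
  has_sp <- "subpopulation" %in% names(captures)
  coy <- captures[captures$cub_class == "coy", , drop = FALSE]
  yl <- captures[captures$cub_class == "yearling", , drop = FALSE]
  sp_of <- function(d) if (has_sp) d$subpopulation else rep(NA_character_, nrow(d))
  ev <- rbind(
    data.frame(subpopulation = sp_of(coy), year = coy$year,
               mother_age = coy$age,
               source = rep("observed", nrow(coy))),
    data.frame(subpopulation = sp_of(yl), year = yl$year - 1L,
               mother_age = yl$age - 1, source = rep("pseudo", nrow(yl))))
  young <- ev$mother_age < adult_age
  if (any(young)) {
    warnf("dropping %d event(s) with mother age below the adult threshold (%g)",
          sum(young), adult_age)
    ev <- ev[!young, , drop = FALSE]
  }
  if (!has_sp) ev$subpopulation <- NULL
  rownames(ev) <- NULL
  ev
}

per_subpop_means <- function(events) {
  tapply(events$mother_age, events$subpopulation, mean)
}

#' Point estimate of generation length
#'
#' With subpopulation labels (the default \code{"subpopulation"} method),
#' GL is the mean of per-subpopulation mean mother ages, so that heavily
#' sampled subpopulations do not dominate; \code{"pooled"} averages over
#' all events directly.  Without labels the pooled mean is used.
#'
#' @param events event data frame from
#'   \code{\link{build_pseudo_observations}}.
#' @param method \code{"subpopulation"} or \code{"pooled"}.
#' @return GL in years.
#' @export
estimate_gl <- function(events, method = c("subpopulation", "pooled")) {
  method <- match.arg(method)
  if (nrow(events) == 0L) stopf("no reproductive events")
  if (method == "subpopulation" && "subpopulation" %in% names(events))
    mean(per_subpop_means(events))
  else mean(events$mother_age)
}

#' Bootstrap uncertainty in generation length
#'
#' Resamples events with replacement, stratified by subpopulation when
#' labels are present (each subpopulation resampled at its own size, then
#' per-subpopulation means averaged), and reports the empirical 5th and
#' 95th percentiles of the bootstrap distribution around the point
#' estimate.
#'
#' @param events event data frame.
#' @param reps bootstrap replicates (default 5000).
#' @param seed integer seed.
#' @param method passed to \code{\link{estimate_gl}}.
#' @param probs lower/upper percentile probabilities.
#' @return an object of class \code{gl_estimate} with fields
#'   \code{gl_mean}, \code{percentile_5}, \code{percentile_95},
#'   \code{n_events}, \code{bootstrap_reps}, \code{seed} and the
#'   bootstrap \code{draws}.
#' @export
bootstrap_gl <- function(events, reps = 5000L, seed = 1L,
                         method = c("subpopulation", "pooled"),
                         probs = c(0.05, 0.95)) {
  method <- match.arg(method)
  n <- nrow(events)
  if (n < 2L) stopf("need at least 2 events to bootstrap, got %d", n)
  if (reps < 100L) warnf("reps = %d is very small for percentile estimates", reps)
  set.seed(seed)
  stratified <- method == "subpopulation" && "subpopulation" %in% names(events)
  if (stratified) {
    by_sp <- split(events$mother_age, events$subpopulation)
    draws <- vapply(seq_len(reps), function(i)
      mean(vapply(by_sp, function(a)
        mean(a[sample.int(length(a), replace = TRUE)]), numeric(1))),
      numeric(1))
  } else {
    ages <- events$mother_age
    draws <- vapply(seq_len(reps), function(i)
      mean(ages[sample.int(n, replace = TRUE)]), numeric(1))
  }
  q <- unname(quantile(draws, probs, type = 7))
  structure(list(gl_mean = estimate_gl(events, method),
                 percentile_5 = q[1], percentile_95 = q[2],
                 n_events = n, bootstrap_reps = as.integer(reps),
                 seed = as.integer(seed), draws = draws),
            class = "gl_estimate")
}

#' @export
print.gl_estimate <- function(x, ...) {
  cat(sprintf(
    "Generation length: %.2f years (5th-95th pct: %.2f-%.2f; %d events, %d bootstrap reps)\n",
    x$gl_mean, x$percentile_5, x$percentile_95, x$n_events, x$bootstrap_reps))
  invisible(x)
}
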