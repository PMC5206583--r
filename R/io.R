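# File readers/writers (UTF-8 comma-separated CSV, '.' decimal,
# ISO-8601 dates) and the end-to-end pipeline driver.

#' Read a daily concentration field from long CSV
#'
#' Expects columns \code{date} (ISO-8601), \code{cell_id},
#' \code{concentration}, and optionally \code{cell_area_km2}.  Values on
#' a 0-100 scale are rescaled to fractions with a message.  Duplicate
#' (date, cell) entries, non-finite values and out-of-range
#' concentrations are errors.
#'
#' @param path CSV file.
#' @param cell_area cell area in km^2 when the file has no
#'   \code{cell_area_km2} column.
#' @return an \code{ice_field} (Gregorian calendar).
#' @export
read_concentration <- function(path, cell_area = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "cell_id", "concentration")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("'%s' lacks columns: %s", path,
                          paste(miss, collapse = ", "))
  if (any(!is.finite(d$concentration)))
    stopf("non-finite concentrations in '%s'", path)
  if (max(d$concentration) > 1.5) {
    message("concentrations look 0-100 scaled; dividing by 100")
    d$concentration <- d$concentration / 100
  }
  if (any(d$concentration < 0 | d$concentration > 1))
    stopf("concentrations outside [0, 1] in '%s'", path)
  dup <- duplicated(d[c("date", "cell_id")])
  if (any(dup))
    stopf("duplicated date/cell entries, first at date %s", d$date[dup][1])
  dates <- as.Date(d$date)
  if (any(is.na(dates))) stopf("unparseable dates in '%s'", path)
  cells <- sort(unique(d$cell_id))
  udates <- sort(unique(dates))
  conc <- matrix(NA_real_, length(udates), length(cells),
                 dimnames = list(NULL, cells))
  conc[cbind(match(dates, udates), match(d$cell_id, cells))] <- d$concentration
  areas <- if ("cell_area_km2" %in% names(d)) {
    a <- tapply(d$cell_area_km2, d$cell_id, function(x) x[1])
    as.numeric(a[cells])
  } else {
    if (is.null(cell_area)) stopf("no cell_area_km2 column and no 'cell_area'")
    rep(cell_area, length(cells))
  }
  yr <- as.integer(format(udates, "%Y"))
  doy <- as.integer(format(udates, "%j"))
  structure(list(conc = conc, cell_id = cells, cell_area = areas,
                 year = yr, doy = doy, dates = udates,
                 calendar = "gregorian", spec = NULL),
            class = "ice_field")
}

#' Write a concentration field as long CSV
#'
#' @param field an \code{ice_field}.
#' @param path output CSV file.
#' @export
write_concentration <- function(field, path) {
  dates <- if (!is.null(field$dates)) as.character(field$dates)
  else as.character(as.Date(sprintf("%04d-01-01", field$year)) + field$doy - 1L)
  long <- data.frame(
    date = rep(dates, times = length(field$cell_id)),
    cell_id = rep(field$cell_id, each = length(dates)),
    concentration = as.vector(field$conc),
    cell_area_km2 = rep(field$cell_area, each = length(dates)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a region definition table
#'
#' @param path CSV with columns \code{region_id}, \code{ecoregion},
#'   \code{cell_id}, \code{cell_area_km2}.
#' @return named list of \code{\link{region_definition}} objects.
#' @export
read_regions <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region_id", "ecoregion", "cell_id", "cell_area_km2")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("'%s' lacks columns: %s", path,
                          paste(miss, collapse = ", "))
  ids <- unique(d$region_id)
  out <- lapply(ids, function(r) {
    dd <- d[d$region_id == r, ]
    region_definition(r, dd$ecoregion[1], dd$cell_id, dd$cell_area_km2)
  })
  stats::setNames(out, ids)
}

#' Read capture records
#' @param path CSV with columns \code{subpopulation}, \code{year},
#'   \code{age}, \code{cub_class}.
#' @return data frame.
#' @export
read_captures <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "age", "cub_class")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("'%s' lacks columns: %s", path,
                          paste(miss, collapse = ", "))
  bad <- setdiff(unique(d$cub_class), c("coy", "yearling", "none"))
  if (length(bad)) stopf("unknown cub_class values: %s",
                         paste(bad, collapse = ", "))
  d
}

#' Read abundance estimates
#' @param path CSV with columns \code{subpopulation}, \code{year},
#'   \code{n}, and optionally \code{se} and \code{ecoregion}.
#' @return data frame.
#' @export
read_abundance <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subpopulation", "year", "n")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("'%s' lacks columns: %s", path,
                          paste(miss, collapse = ", "))
  if (any(!is.finite(d$n) | d$n <= 0)) stopf("abundance 'n' must be > 0")
  d
}

write_annual_ice <- function(annual, path) {
  utils::write.csv(data.frame(region_id = annual$region_id,
                              year = annual$year, ice_days = annual$ice,
                              midpoint_km2 = annual$midpoint),
                   path, row.names = FALSE)
  invisible(path)
}

write_ice_trends <- function(trends, path) {
  rows <- lapply(trends, function(t) data.frame(
    region = t$region_id, slope = coef(t)[["slope"]],
    se = sqrt(t$vcov[2, 2]), intercept = coef(t)[["intercept"]],
    residual_sd = t$sigma, n_years = t$n))
  utils::write.csv(do.call(rbind, c(rows, make.row.names = FALSE)), path,
                   row.names = FALSE)
  invisible(path)
}

write_relation_fits <- function(fits, path) {
  rows <- lapply(fits, function(f) data.frame(
    approach = f$approach %||% NA, scope = f$scope, beta = f$beta,
    se = f$beta_se, n_obs = f$n_obs))
  utils::write.csv(do.call(rbind, c(rows, make.row.names = FALSE)), path,
                   row.names = FALSE)
  invisible(path)
}

write_scenario_table <- function(summaries, path) {
  rows <- lapply(summaries, function(s) data.frame(
    approach = s$scenario$approach, gl = s$scenario$gl,
    horizon = s$scenario$horizon, median = s$median_change,
    ci_low = s$ci_low, ci_high = s$ci_high,
    p0 = s$p_decline[["0"]], p30 = s$p_decline[["30"]],
    p50 = s$p_decline[["50"]], p80 = s$p_decline[["80"]]))
  utils::write.csv(do.call(rbind, c(rows, make.row.names = FALSE)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Run the whole pipeline from a configuration
#'
#' Executes synthetic-data generation (or file ingestion), ice metrics
#' and trends, generation-length estimation, relation fitting and the
#' stochastic projections, and writes the stage outputs (annual ice,
#' trends, GL, relation fits, a six-row scenario table and a JSON
#' summary with the cross-scenario medians and Red List category) to the
#' configured output directory.  Reruns with the same configuration and
#' seed are byte-identical.
#'
#' @param config a list, or the path of a YAML file holding one.
#'   Recognised fields: \code{seed}; either \code{simulate} (a list of
#'   arguments for \code{\link{gen_study_world}}) or input paths
#'   \code{concentration}, \code{regions}, \code{captures},
#'   \code{abundance}; \code{approaches} (default \code{1:3});
#'   \code{gl_values} (numeric, or \code{"estimated"} to use the GL
#'   point estimate and its bootstrap 95th percentile); \code{n_sims}
#'   (default 62500); \code{start_year} (default 2015);
#'   \code{tolerance} (default 0.5); \code{min_span} (default 10);
#'   \code{exclude} (subpopulations dropped from projection, default
#'   \code{"AB"}); \code{output_dir}.
#' @return (invisibly) a list with all stage results: \code{annual_ice},
#'   \code{trends}, \code{gl}, \code{fits}, \code{scenarios},
#'   \code{summaries}, \code{cross}, \code{red_list}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  approaches <- as.integer(config$approaches %||% 1:3)
  n_sims <- config$n_sims %||% 62500L
  start_year <- config$start_year %||% 2015L
  exclude <- config$exclude %||% "AB"

  if (!is.null(config$simulate)) {
    world <- do.call(gen_study_world,
                     c(list(seed = seed), config$simulate))
    annual_ice <- world$annual_ice
    trends <- world$trends
    captures <- world$captures
    estimates <- world$estimates
    weights <- world$weights
    ecoregions <- world$ecoregions
  } else {
    for (f in c("concentration", "regions", "captures"))
      if (is.null(config[[f]]))
        stopf("config is missing required input '%s'", f)
    if (is.null(config$abundance)) {
      if (any(approaches >= 2L))
        stopf("approaches 2-3 requested but config is missing input 'abundance'")
      stopf("config is missing input 'abundance' (needed for MGPS weights)")
    }
    for (f in c("concentration", "regions", "captures", "abundance")) {
      if (!file.exists(config[[f]]))
        stopf("input file for '%s' does not exist: %s", f, config[[f]])
    }
    field <- read_concentration(config$concentration,
                                cell_area = config$cell_area)
    regions <- read_regions(config$regions)
    annual_ice <- do.call(rbind, lapply(regions, function(r)
      annual_ice_series(fill_gaps(daily_ice_series(field, r)))))
    trends <- lapply(split(annual_ice, annual_ice$region_id), fit_ice_trend)
    captures <- read_captures(config$captures)
    estimates <- read_abundance(config$abundance)
    if (!"ecoregion" %in% names(estimates)) {
      eco <- vapply(regions, function(r) r$ecoregion, character(1))
      estimates$ecoregion <- eco[estimates$subpopulation]
    }
    latest <- lapply(split(estimates, estimates$subpopulation),
                     function(d) d$n[which.max(d$year)])
    weights <- unlist(latest)
    miss <- setdiff(names(weights), names(trends))
    if (length(miss))
      stopf("abundance subpopulations without an ice series: %s",
            paste(miss, collapse = ", "))
    trends <- trends[names(weights)]
    ecoregions <- vapply(regions, function(r) r$ecoregion,
                         character(1))[names(weights)]
  }
  trends <- trends[setdiff(names(trends), exclude)]
  weights <- weights[setdiff(names(weights), exclude)]
  ecoregions <- ecoregions[names(trends)]

  events <- build_pseudo_observations(captures)
  gl_boot <- bootstrap_gl(events, reps = config$gl_reps %||% 5000L,
                          seed = seed)
  gl_values <- config$gl_values %||% "estimated"
  if (identical(gl_values, "estimated"))
    gl_values <- c(gl_boot$gl_mean, gl_boot$percentile_95)
  gl_values <- as.numeric(gl_values)

  global_fit <- NULL; eco_fits <- NULL; fits <- list()
  if (any(approaches >= 2L)) {
    if (is.null(estimates))
      stopf("approaches 2-3 requested but no abundance estimates available")
    obs2 <- paired_changes(estimates, annual_ice, mode = "two-point",
                           min_span = config$min_span %||% 10)
    global_fit <- fit_relation(obs2, scope = "global")
    global_fit$approach <- 2L
    obs3 <- paired_changes(estimates, annual_ice, mode = "series")
    eco_fits <- fit_relations_by_ecoregion(obs3)
    for (e in names(eco_fits)) eco_fits[[e]]$approach <- 3L
    fits <- c(list(global = global_fit), eco_fits)
  }

  summaries <- list()
  idx <- 0L
  for (ap in approaches) for (gl in gl_values) {
    idx <- idx + 1L
    scn <- scenario(ap, gl, n_sims = n_sims, seed = seed + 7919L * idx)
    summaries[[idx]] <- run_scenario(
      scn, trends, weights, global_fit = global_fit, eco_fits = eco_fits,
      ecoregions = ecoregions, start_year = start_year)
  }
  cross <- summarize_scenarios(summaries)
  rl <- red_list_category(cross, tolerance = config$tolerance %||% 0.5)

  out <- list(annual_ice = annual_ice, trends = trends, gl = gl_boot,
              fits = fits, summaries = summaries, cross = cross,
              red_list = rl, gl_values = gl_values, seed = seed)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$output_dir, f)
    write_annual_ice(annual_ice, p("annual_ice.csv"))
    write_ice_trends(trends, p("ice_trends.csv"))
    utils::write.csv(data.frame(
      gl = gl_boot$gl_mean, percentile_5 = gl_boot$percentile_5,
      percentile_95 = gl_boot$percentile_95, n_events = gl_boot$n_events,
      reps = gl_boot$bootstrap_reps), p("gl.csv"), row.names = FALSE)
    if (length(fits)) write_relation_fits(fits, p("relation_fits.csv"))
    write_scenario_table(summaries, p("scenarios.csv"))
    summary_json <- list(
      seed = seed, n_sims = n_sims, start_year = start_year,
      gl_values = gl_values,
      scenario_seeds = vapply(summaries, function(s) s$scenario$seed,
                              integer(1)),
      cross_scenario = cross$table,
      red_list = list(category = rl$category, rule = rl$rule,
                      tolerance = rl$tolerance))
    jsonlite::write_json(summary_json, p("summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  invisible(out)
}
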