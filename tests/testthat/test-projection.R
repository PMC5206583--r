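# Monte Carlo projection engine and Red List scoring.

test_that("scenario horizons are three generations rounded half up", {
  expect_equal(scenario(1, 11.5)$horizon, 35L)
  expect_equal(scenario(1, 13.6)$horizon, 41L)
  expect_equal(scenario(1, 12)$horizon, 36L)
  expect_error(scenario(4, 11.5), "approach")
})

test_that("coefficient draws follow the estimated sampling distribution", {
  f <- make_relation(0.013, 0)
  expect_equal(simulate_coefficients(f, 100, seed = 1), rep(0.013, 100))

  f2 <- make_relation(0.013, 0.002)
  d1 <- simulate_coefficients(f2, 20000, seed = 2)
  d2 <- simulate_coefficients(f2, 20000, seed = 2)
  expect_identical(d1, d2)
  expect_lt(abs(mean(d1) - 0.013), 4 * 0.002 / sqrt(20000))
  expect_lt(abs(sd(d1) - 0.002), 4 * 0.002 / sqrt(20000))

  tr <- make_trend(200, -1.26,
                   V = matrix(c(4, -0.02, -0.02, 0.0004), 2, 2))
  m <- simulate_coefficients(tr, 20000, seed = 3)
  expect_equal(colnames(m), c("intercept", "slope"))
  expect_lt(abs(mean(m[, "slope"]) + 1.26), 4 * 0.02 / sqrt(20000))
  # degenerate covariance pins the draws at the point estimate
  tr0 <- make_trend(200, -1.26)
  m0 <- simulate_coefficients(tr0, 50, seed = 4)
  expect_true(all(m0[, "intercept"] == 200 & m0[, "slope"] == -1.26))
})

test_that("fitted-relation projection compounds the annual log change", {
  td <- matrix(c(150, -1.26), 1, 2,
               dimnames = list(NULL, c("intercept", "slope")))
  ch <- project_subpopulation(3, 35, td, beta_draws = 0.013)
  # 35-step annual recursion oracle
  n <- 1
  for (i in 1:35) n <- n * exp(0.013 * -1.26)
  expect_equal(ch, n - 1, tolerance = 1e-12)
  expect_equal(ch, exp(0.013 * -1.26 * 35) - 1, tolerance = 1e-12)

  expect_equal(project_subpopulation(2, 35, td, beta_draws = 0), 0)
  expect_equal(project_subpopulation(2, 35, td, beta_draws = 50), -1)
})

test_that("habitat-proportional projection uses clamped ice ratios", {
  td <- rbind(c(200, 0), c(200, -2), c(100, -10))
  colnames(td) <- c("intercept", "slope")
  ch <- project_subpopulation(1, 35, td, start_year = 0)
  expect_equal(ch[1], 0)
  expect_equal(ch[2], (200 - 2 * 35) / 200 - 1)
  expect_equal(ch[3], -1)  # baseline already at the zero-day clamp
})

test_that("MGPS aggregation is the abundance-weighted mean in per cent", {
  expect_equal(aggregate_mgps(c(a = -0.10, b = -0.50), c(a = 1000, b = 3000)),
               -40)
  expect_equal(aggregate_mgps(c(a = -0.30), c(a = 2000)), -30)
  w <- c(a = 123, b = 4567)
  expect_equal(aggregate_mgps(c(a = -0.2, b = -0.2), w), -20)
  m <- matrix(c(-0.1, -0.2, -0.5, -0.6), 2, 2,
              dimnames = list(NULL, c("a", "b")))
  expect_equal(aggregate_mgps(m, c(a = 1000, b = 3000)),
               c(-40, -50))
  expect_error(aggregate_mgps(c(a = -0.1), c(b = 100)), "do not match")
})

test_that("threshold probabilities follow the exhaustive replicate count", {
  p <- reduction_probabilities(c(-10, -35, -55, -90))
  expect_equal(unname(p), c(1.00, 0.75, 0.50, 0.25))
  expect_equal(names(p), c("0", "30", "50", "80"))
})

test_that("zero-uncertainty scenarios collapse to the deterministic point", {
  trends <- list(A = make_trend(120, -1.26), B = make_trend(250, -2))
  weights <- c(A = 1000, B = 3000)
  eco <- c(A = "seasonal", B = "divergent")
  fits <- list(seasonal = make_relation(0.013, 0),
               divergent = make_relation(0.032, 0))
  scn <- scenario(3, 11.5, n_sims = 500, seed = 1)
  s <- run_scenario(scn, trends, weights, eco_fits = fits, ecoregions = eco,
                    start_year = 2015)
  det <- 100 * (1000 * (exp(0.013 * -1.26 * 35) - 1) +
                3000 * (exp(0.032 * -2 * 35) - 1)) / 4000
  expect_lt(abs(s$median_change - det), 1e-10)
  expect_lt(abs(s$ci_low - det), 1e-10)
  expect_lt(abs(s$ci_high - det), 1e-10)

  # beta = 0 everywhere: no change, no declines beyond the 0% tie
  fits0 <- list(seasonal = make_relation(0, 0), divergent = make_relation(0, 0))
  s0 <- run_scenario(scn, trends, weights, eco_fits = fits0, ecoregions = eco)
  expect_equal(s0$median_change, 0)
  expect_equal(unname(s0$p_decline), c(1, 0, 0, 0))
})

test_that("scenario reruns are identical and thresholds are nested", {
  trends <- list(A = make_trend(150, -1.5,
                                V = matrix(c(25, -0.1, -0.1, 0.09), 2, 2)),
                 B = make_trend(220, -2.5,
                                V = matrix(c(16, -0.05, -0.05, 0.16), 2, 2)))
  weights <- c(A = 500, B = 1500)
  eco <- c(A = "seasonal", B = "divergent")
  fits <- list(seasonal = make_relation(0.013, 0.004),
               divergent = make_relation(0.032, 0.012))
  gfit <- make_relation(0.01, 0.02)
  for (ap in 1:3) {
    scn <- scenario(ap, 11.5, n_sims = 2000, seed = 42 + ap)
    s1 <- run_scenario(scn, trends, weights, global_fit = gfit,
                       eco_fits = fits, ecoregions = eco)
    s2 <- run_scenario(scn, trends, weights, global_fit = gfit,
                       eco_fits = fits, ecoregions = eco)
    expect_identical(s1$p_decline, s2$p_decline)
    expect_identical(s1$median_change, s2$median_change)
    expect_true(all(diff(s1$p_decline) <= 0))
  }
})

test_that("a scope-level coefficient draw is shared within the replicate", {
  # two subpopulations with identical deterministic trends and a common
  # global beta: their per-replicate changes must be identical draws
  trends <- list(A = make_trend(150, -1.26), B = make_trend(150, -1.26))
  weights <- c(A = 1, B = 1)
  gfit <- make_relation(0.013, 0.005)
  scn <- scenario(2, 11.5, n_sims = 200, seed = 9)
  s <- run_scenario(scn, trends, weights, global_fit = gfit,
                    keep_draws = TRUE)
  # if betas were drawn independently per subpopulation the MGPS draws
  # would average two independent streams and shrink the spread by ~1/sqrt(2)
  one <- run_scenario(scenario(2, 11.5, n_sims = 200, seed = 9),
                      trends[1], weights[1], global_fit = gfit,
                      keep_draws = TRUE)
  expect_equal(sort(s$draws), sort(one$draws), tolerance = 1e-9)
})

test_that("doubling the replicates moves probabilities within Monte Carlo error", {
  trends <- list(A = make_trend(150, -1.5,
                                V = matrix(c(9, -0.03, -0.03, 0.04), 2, 2)))
  weights <- c(A = 1000)
  fits <- list(seasonal = make_relation(0.013, 0.004))
  eco <- c(A = "seasonal")
  n <- 4000
  checks <- 0L; ok <- 0L
  for (s in 1:10) {
    p1 <- run_scenario(scenario(3, 11.5, n_sims = n, seed = s),
                       trends, weights, eco_fits = fits,
                       ecoregions = eco)$p_decline
    p2 <- run_scenario(scenario(3, 11.5, n_sims = 2L * n, seed = s),
                       trends, weights, eco_fits = fits,
                       ecoregions = eco)$p_decline
    for (k in names(p1)) {
      checks <- checks + 1L
      if (abs(p1[[k]] - p2[[k]]) < 2 * sqrt(p1[[k]] * (1 - p1[[k]]) / n) + 1e-12)
        ok <- ok + 1L
    }
  }
  expect_gte(ok / checks, 0.95)
})

test_that("the Monte Carlo median matches the analytic aggregation", {
  # all subpopulations share one uncertain beta and fixed slopes, so
  # MGPS change is monotone in beta and its median is the plug-in value
  trends <- list(A = make_trend(150, -1.26), B = make_trend(150, -2.0))
  weights <- c(A = 1000, B = 2000)
  gfit <- make_relation(0.013, 0.002)
  scn <- scenario(2, 11.5, n_sims = 20000, seed = 77)
  s <- run_scenario(scn, trends, weights, global_fit = gfit)
  analytic <- 100 * (1000 * (exp(0.013 * -1.26 * 35) - 1) +
                     2000 * (exp(0.013 * -2.0 * 35) - 1)) / 3000
  expect_lt(abs(s$median_change - analytic), 0.5)
})

test_that("cross-scenario summaries take per-threshold medians and ranges", {
  cs <- summarize_scenarios(table1_probs())
  expect_equal(cs$table$median[cs$table$threshold == 30], 0.71)
  expect_equal(cs$table$median[cs$table$threshold == 50], 0.07)
  expect_equal(cs$table$min[cs$table$threshold == 30], 0.20)
  expect_equal(cs$table$max[cs$table$threshold == 30], 0.95)

  one <- summarize_scenarios(table1_probs()[3, , drop = FALSE])
  expect_equal(one$table$median, one$table$min)
  expect_equal(one$table$median, one$table$max)
  expect_error(summarize_scenarios(list()), "no scenario")
})

test_that("Red List categories follow the tolerance rule", {
  vu <- red_list_category(c("0" = 1, "30" = 0.71, "50" = 0.07, "80" = 0.005))
  expect_equal(vu$category, "vulnerable")
  lc <- red_list_category(c("0" = 0, "30" = 0, "50" = 0, "80" = 0))
  expect_equal(lc$category, "least-concern-range")
  cr <- red_list_category(c("0" = 1, "30" = 0.9, "50" = 0.8, "80" = 0.6))
  expect_equal(cr$category, "critically-endangered")
  en <- red_list_category(c("0" = 1, "30" = 0.9, "50" = 0.55, "80" = 0.1))
  expect_equal(en$category, "endangered")
  expect_error(red_list_category(c("0" = 0.2, "30" = 0.9, "50" = 0.1,
                                   "80" = 0)),
               "non-increasing")
})
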