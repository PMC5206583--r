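# Habitat metric: daily areas, midpoint threshold, ice-covered days,
# trend fitting and projection.

test_that("daily ice area applies the strict 15% cutoff per cell", {
  r <- region_definition("A", "seasonal", c("c1", "c2", "c3"), 625)
  expect_equal(daily_ice_area(c(c1 = 0, c2 = 0, c3 = 0), r), 0)
  expect_equal(daily_ice_area(c(c1 = 1, c2 = 0, c3 = 0), r), 625)
  expect_equal(daily_ice_area(c(c1 = 0.10, c2 = 0.50, c3 = 0.80), r),
               0.50 * 625 + 0.80 * 625)
  # exactly at the cutoff does not count (strict inequality)
  expect_equal(daily_ice_area(c(c1 = 0.15, c2 = 0, c3 = 0), r), 0)
  expect_error(daily_ice_area(c(c1 = 0.2, c2 = 0.2), r), "c3")
  expect_error(daily_ice_area(c(c1 = 1.2, c2 = 0, c3 = 0), r), "\\[0, 1\\]")
})

test_that("annual extremes recover the sinusoid and react to spikes", {
  s <- make_daily(rep(500, 365))
  expect_equal(annual_extremes(s, 2000),
               c(summer_min = 500, winter_max = 500))
  sine <- make_sine_series(n_years = 1, mean_area = 1000, amplitude = 400)
  ex <- annual_extremes(sine, 2000)
  # enumeration oracle over all days
  days <- 1000 + 400 * cos(2 * pi * ((1:365) - 75) / 365)
  expect_equal(unname(ex), c(min(days), max(days)))
  spiked <- make_daily(c(rep(100, 200), 900, rep(100, 164)))
  expect_equal(annual_extremes(spiked, 2000)[["winter_max"]], 900)
  short <- make_daily(rep(1, 100))
  expect_error(annual_extremes(short, 2000), "2000.*100 days")
})

test_that("midpoint is the mean-of-extremes average over baseline years", {
  expect_equal(compute_midpoint(make_daily(rep(42, 365))), 42)
  sine <- make_sine_series(n_years = 2, mean_area = 1000, amplitude = 400)
  expect_equal(compute_midpoint(sine), 1000, tolerance = 1e-4)
  # hand arithmetic: extremes (100, 300) and (80, 320) -> 200
  y1 <- c(100, 300, rep(200, 363))
  y2 <- c(80, 320, rep(200, 363))
  s <- make_daily(c(y1, y2))
  s$year <- rep(c(2000L, 2001L), each = 365L)
  s$doy <- rep(1:365, 2)
  expect_equal(compute_midpoint(s), ((100 + 80) / 2 + (300 + 320) / 2) / 2)
  expect_error(compute_midpoint(s, baseline_years = integer(0)), "baseline")
})

test_that("ice-covered days counts strictly-above days", {
  s <- make_daily(rep(500, 365))
  expect_equal(ice_covered_days(s, 500, 2000), 0)
  step <- make_daily(c(rep(2000, 100), rep(0, 265)))
  expect_equal(ice_covered_days(step, 1000, 2000), 100)
  sine <- make_sine_series(n_years = 1, mean_area = 1000, amplitude = 400)
  mid <- compute_midpoint(sine)
  days <- 1000 + 400 * cos(2 * pi * ((1:365) - 75) / 365)
  expect_equal(ice_covered_days(sine, mid, 2000), sum(days > mid))
  # about half the year; the exact count depends on how the integer-day
  # grid falls against the two crossings
  expect_true(ice_covered_days(sine, 1000, 2000) %in% c(182L, 183L))
})

test_that("ice-covered days equals a brute-force day count on random series", {
  set.seed(401)
  for (i in 1:1000) {
    n <- sample(300:365, 1)
    a <- pmax(0, cumsum(rnorm(n, 0, 50)) + runif(1, 100, 2000))
    s <- make_daily(a)
    mid <- runif(1, 0, 1500)
    cnt <- 0L
    for (d in seq_len(n)) if (a[d] > mid) cnt <- cnt + 1L
    expect_identical(ice_covered_days(s, mid, 2000), as.integer(cnt))
  }
})

test_that("translation of daily areas leaves the metric unchanged", {
  set.seed(42)
  a <- 500 + 300 * cos(2 * pi * (1:730) / 365) + rnorm(730, 0, 40)
  s <- make_daily(pmax(a, 0) + 50)
  s$year <- rep(c(2000L, 2001L), each = 365L)
  s$doy <- rep(1:365, 2)
  shifted <- s
  shifted$area <- s$area + 777
  expect_equal(annual_ice_series(s)$ice, annual_ice_series(shifted)$ice)
})

test_that("the day count is monotone in pointwise area increases", {
  set.seed(43)
  for (i in 1:20) {
    a <- runif(365, 0, 1000)
    s <- make_daily(a)
    bump <- make_daily(a + runif(365, 0, 200))
    mid <- runif(1, 0, 1000)
    expect_gte(ice_covered_days(bump, mid, 2000),
               ice_covered_days(s, mid, 2000))
  }
})

test_that("gap filling interpolates interior gaps and rejects long ones", {
  s <- make_daily(1:365)
  expect_equal(fill_gaps(s)$area, s$area)
  g <- s[-2, ]
  g$area[1] <- 100; g$area[2] <- 200  # days 1 and 3
  filled <- fill_gaps(g)
  expect_equal(filled$area[2], 150)
  # alternate-day sampling of a sinusoid reconstructs it closely
  sine <- make_sine_series(n_years = 1)
  alt <- sine[seq(1, 365, by = 2), ]
  filled <- fill_gaps(alt)
  max_step <- max(abs(diff(sine$area)))
  expect_lt(max(abs(filled$area - sine$area)), max_step)
  long_gap <- s[-(10:17), ]
  expect_error(fill_gaps(long_gap, max_gap = 5), "max_gap")
})

test_that("trend fitting matches the normal equations", {
  lin <- data.frame(region_id = "R", year = 1979:2014,
                    ice = 250 - 1.26 * (0:35))
  t1 <- fit_ice_trend(lin)
  expect_equal(coef(t1)[["slope"]], -1.26, tolerance = 1e-12)
  expect_lt(t1$sigma, 1e-10)

  flat <- data.frame(region_id = "R", year = 2000:2009, ice = rep(120, 10))
  t2 <- fit_ice_trend(flat)
  expect_equal(coef(t2)[["slope"]], 0, tolerance = 1e-12)
  expect_equal(unname(sqrt(t2$vcov[2, 2])), 0, tolerance = 1e-12)

  # five-point fit against hand-computed normal equations
  d <- data.frame(region_id = "R", year = 1:5, ice = c(10, 8, 9, 5, 3))
  tf <- fit_ice_trend(d)
  sxy <- sum((d$year - 3) * (d$ice - 7)); sxx <- sum((d$year - 3)^2)
  expect_equal(coef(tf)[["slope"]], sxy / sxx, tolerance = 1e-12)     # -1.7
  expect_equal(coef(tf)[["intercept"]], 7 - sxy / sxx * 3,
               tolerance = 1e-12)                                     # 12.1

  expect_error(fit_ice_trend(d[1:2, ]), "at least 3 years")

  # random small inputs vs. a brute-force closed-form solver
  set.seed(77)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    dd <- data.frame(region_id = "R", year = sort(sample(1980:2014, n)),
                     ice = runif(n, 0, 365))
    ft <- fit_ice_trend(dd)
    xb <- mean(dd$year); yb <- mean(dd$ice)
    b <- sum((dd$year - xb) * (dd$ice - yb)) / sum((dd$year - xb)^2)
    a <- yb - b * xb
    res <- dd$ice - a - b * dd$year
    s2 <- sum(res^2) / (n - 2)
    expect_equal(coef(ft)[["slope"]], b, tolerance = 1e-10)
    expect_equal(coef(ft)[["intercept"]], a, tolerance = 1e-10)
    expect_equal(unname(ft$vcov[2, 2]), s2 / sum((dd$year - xb)^2),
                 tolerance = 1e-10)
  }
})

test_that("projection is linear, clamped, and passes through the centroid", {
  flat <- fit_ice_trend(data.frame(region_id = "R", year = 2000:2005,
                                   ice = rep(150, 6)))
  expect_equal(project_ice(flat, 2300)[["fit"]], 150)

  lin <- fit_ice_trend(data.frame(region_id = "R", year = 0:4,
                                  ice = 200 - 2 * (0:4)))
  expect_equal(project_ice(lin, 35)[["fit"]], 130, tolerance = 1e-9)

  steep <- fit_ice_trend(data.frame(region_id = "R", year = 0:4,
                                    ice = 50 - 10 * (0:4)))
  expect_equal(project_ice(steep, 40)[["fit"]], 0)  # clamped at zero days

  set.seed(8)
  d <- data.frame(region_id = "R", year = 1990:2003,
                  ice = runif(14, 50, 300))
  ft <- fit_ice_trend(d)
  expect_equal(predict(ft, mean(d$year)), mean(d$ice), tolerance = 1e-10)
})

test_that("synthetic negative area trends yield negative estimated ice trends", {
  # paper-like noise level, 100 seeded replicates
  neg <- 0L
  for (seed in 1:100) {
    sp <- ice_field_spec("A", n_years = 15, mean_area = 450000,
                         seasonal_amplitude = 300000, trend = -3250,
                         noise_sd = 20000, grid_shape = c(4, 4),
                         cell_area = 120000)
    f <- gen_ice_concentration(sp, seed = seed)
    ann <- annual_ice_series(daily_ice_series(f))
    if (coef(fit_ice_trend(ann))[["slope"]] < 0) neg <- neg + 1L
  }
  expect_gte(neg, 95L)
})
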