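# Synthetic pellet-deposition generator: deterministic arithmetic, seed
# determinism, deposition conservation, and parameter recovery.

test_that("annual roe densities follow the lagged competition equation", {
  tr <- simulation_truth(process_sd = 0,
                         fallow_trajectory = rep(20, 5))
  dens <- simulate_annual_densities(tr, years = 5, seed = 1)
  expect_equal(dens$roe_density, rep(10.341 - 0.326 * 20, 5), tolerance = 1e-12)
  expect_equal(dens$roe_density[2], 3.821, tolerance = 1e-9)

  tr0 <- simulation_truth(slope_b = 0, process_sd = 0)
  dens0 <- simulate_annual_densities(tr0, years = 6, seed = 1)
  expect_equal(dens0$roe_density, rep(10.341, 6))

  expect_error(simulate_annual_densities(tr, years = 2), "years")
  expect_error(simulation_truth(fallow_trajectory = c(1, NA, 3)), "finite")
})

test_that("OLS on replicate density series recovers the competition slope", {
  tr <- simulation_truth(process_sd = 1,
                         fallow_trajectory = c(20, 14, 22, 12, 24, 10, 26, 8, 28))
  slopes <- vapply(1:500, function(i) {
    d <- simulate_annual_densities(tr, years = 9, seed = i)
    x <- d$fallow_density[-9]
    y <- d$roe_density[-1]
    unname(stats::coef(stats::lm(y ~ x))[2])  # independent OLS oracle
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-0.326)), 0.05)
})

test_that("expected deposition equals density x area x days x defecation rate", {
  land <- flat_landscape(n_plots = 20000L)
  tr <- quiet_truth(accumulation_days = 36)
  sv <- simulate_survey(c(roe = 53.0516, fallow = 0), land, tr, seed = 3)
  per_plot <- 53.0516 * pi * 25e-6 * 36 * 20
  expect_equal(per_plot, 3.0, tolerance = 1e-4)
  expect_lt(abs(mean(sv$roe_pg) / per_plot - 1), 0.02)
  # zero density gives identically zero counts
  expect_true(all(sv$fallow_pg == 0))
})

test_that("plot-level suppression slope is recovered by log-linear regression", {
  land <- flat_landscape(n_plots = 5000L)
  tr <- quiet_truth(occupancy_suppression = -0.35)
  sv <- simulate_survey(c(roe = 50, fallow = 15), land, tr, seed = 11)
  fit <- stats::glm(roe_pg ~ fallow_pg, data = sv, family = stats::poisson())
  expect_lt(abs(unname(stats::coef(fit)[2]) - (-0.35)), 0.05)
})

test_that("stronger suppression never increases roe counts where fallow occur", {
  land <- flat_landscape(n_plots = 4000L)
  mean_roe <- vapply(c(0, -0.4, -0.8), function(s) {
    tr <- quiet_truth(occupancy_suppression = s)
    sv <- simulate_survey(c(roe = 50, fallow = 15), land, tr, seed = 5)
    mean(sv$roe_pg[sv$fallow_pg > 0])
  }, numeric(1))
  expect_true(all(diff(mean_roe) < 0))
})

test_that("weather generator hits its growing-season rainfall targets", {
  w0 <- simulate_weather(3, seed = 2, mean_growing_rain_mm = 306,
                         sd_growing_rain_mm = 0)
  wy0 <- weather_year_table(w0)
  expect_equal(wy0$growing_rain_mm, rep(306, 3), tolerance = 1e-9)

  expect_identical(simulate_weather(2, seed = 9), simulate_weather(2, seed = 9))
  expect_error(simulate_weather(2, seed = 1, sd_growing_rain_mm = -1), "sd")

  w <- simulate_weather(11, seed = 4, mean_growing_rain_mm = 300,
                        sd_growing_rain_mm = 80)
  wy <- weather_year_table(w)
  se <- 80 / sqrt(11)
  expect_lt(abs(mean(wy$growing_rain_mm) - 300), 3 * se)
  expect_true(all(w$rain_mm >= 0))
})

test_that("fixtures are deterministic and round-trip through the readers", {
  cfg <- list(years = 3L)
  d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
  p1 <- generate_fixture(cfg, seed = 21, out_dir = d1)
  p2 <- generate_fixture(cfg, seed = 21, out_dir = d2)
  expect_identical(readLines(p1$survey), readLines(p2$survey))
  expect_identical(readLines(p1$weather), readLines(p2$weather))

  sv <- read_survey(p1$survey)
  expect_equal(nrow(sv), 258L * 3L)
  ds <- simulate_dataset(years = 3L, seed = 21)
  expect_equal(sum(sv$roe_pg), sum(ds$survey$roe_pg))
  expect_equal(sum(sv$fallow_pg), sum(ds$survey$fallow_pg))
  wt <- read_weather(p1$weather)
  expect_s3_class(wt$date, "Date")
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("simulated surveys are pure functions of their seed", {
  land <- landscape_config()
  tr <- simulation_truth()
  a <- simulate_survey(c(roe = 5, fallow = 15), land, tr, seed = 7,
                       interval_range = c(35L, 40L))
  b <- simulate_survey(c(roe = 5, fallow = 15), land, tr, seed = 7,
                       interval_range = c(35L, 40L))
  expect_identical(a, b)
  ds1 <- simulate_dataset(years = 3, seed = 13)
  ds2 <- simulate_dataset(years = 3, seed = 13)
  expect_identical(ds1$survey, ds2$survey)
  expect_identical(ds1$weather, ds2$weather)
})
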