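# Fecal-accumulation-rate density estimation.

hand_records <- function(counts, days = 36, radius = 5) {
  data.frame(plot_id = seq_along(counts), habitat = "ecotone",
             radius_m = radius, interval_days = days, roe_pg = counts)
}

test_that("the hand example and rate scaling are exact", {
  rec <- hand_records(rep(3L, 10))
  est <- estimate_density(rec, 20, seed = 1)
  # 30 groups / (10 plots x 78.5398 m^2) / 36 d / 20 groups/d
  expect_equal(est$density, 53.0516, tolerance = 1e-4)
  est25 <- estimate_density(rec, 25, seed = 1)
  expect_equal(est25$density, 42.4413, tolerance = 1e-4)
  expect_equal(est25$density, est$density * 20 / 25, tolerance = 1e-12)
})

test_that("density is equivariant in counts and inverse in the rate", {
  rec <- hand_records(c(0L, 2L, 5L, 1L, 3L, 0L))
  est <- estimate_density(rec, 20, seed = 4)
  rec2 <- rec; rec2$roe_pg <- rec$roe_pg * 2L
  expect_equal(estimate_density(rec2, 20, seed = 4)$density, 2 * est$density)
  expect_equal(estimate_density(rec, 40, seed = 4)$density, est$density / 2)
})

test_that("all-zero counts give a degenerate zero estimate", {
  rec <- hand_records(rep(0L, 8))
  est <- estimate_density(rec, 20, seed = 2)
  expect_equal(est$density, 0)
  expect_equal(c(est$ci_low, est$ci_high), c(0, 0))
  expect_true(is.na(est$weight))
  expect_error(precision_weight(est), "zero-width")
})

test_that("input contracts are enforced", {
  expect_error(estimate_density(hand_records(3L)[1, ], 20), "2 plots")
  expect_error(estimate_density(hand_records(c(1L, 2L)), 0), "positive")
  expect_error(estimate_density(hand_records(c(1L, 2.5)), 20), "integers")
})

test_that("the stratified estimator weights habitat means by area fraction", {
  rec <- data.frame(plot_id = 1:6,
                    habitat = rep(c("ecotone", "garigue"), each = 3),
                    radius_m = 5, interval_days = 36,
                    roe_pg = c(2L, 4L, 6L, 0L, 1L, 2L))
  unit <- pi * 25e-6 * 36 * 20
  m_eco <- mean(c(2, 4, 6)) / unit
  m_gar <- mean(c(0, 1, 2)) / unit
  est <- estimate_density(rec, 20, stratified = TRUE,
                          area_fraction = c(ecotone = 0.3, garigue = 0.7),
                          seed = 5)
  expect_equal(est$density, 0.3 * m_eco + 0.7 * m_gar, tolerance = 1e-12)
})

test_that("precision weights invert CI widths and rescale to mean one", {
  ests <- data.frame(ci_low = c(0, 0, 0), ci_high = c(1, 2, 4), se = 1)
  w <- precision_weight(ests)
  expect_equal(w, c(1, 0.5, 0.25))
  expect_equal(precision_weight(data.frame(ci_low = 1, ci_high = 3, se = 1)), 0.5)
  expect_equal(precision_weight(data.frame(ci_low = 0, ci_high = 0.1, se = 1)),
               10, tolerance = 1e-12)
  rw <- rescale_weights(w)
  expect_equal(rw, c(12 / 7, 6 / 7, 3 / 7))
  expect_equal(mean(rw), 1)
})

test_that("relative SE behaves as se over density", {
  expect_equal(relative_se(data.frame(se = 5, density = 50)), 0.10)
  expect_equal(relative_se(data.frame(se = 10, density = 50)), 0.20)
  expect_error(relative_se(data.frame(se = 1, density = 0)), "undefined")
})

test_that("the default synthetic design yields field-typical relative SEs", {
  tr <- simulation_truth()
  land <- landscape_config()
  rels <- vapply(1:10, function(i) {
    set.seed(100 + i)
    pre <- rnorm(land$n_plots, 0, tr$plot_re_sd)
    sv <- simulate_survey(c(roe = 6, fallow = 15), land, tr, seed = 30 + i,
                          plot_re = pre)
    relative_se(estimate_density(sv, 20, count_col = "roe_pg", B = 400,
                                 seed = i))
  }, numeric(1))
  expect_true(all(rels > 0.05 & rels < 0.25))
})

test_that("the series estimator is reproducible and covers both species", {
  ds <- simulate_dataset(years = 3, seed = 8)
  d1 <- estimate_density_series(ds$survey, B = 200, seed = 3)
  d2 <- estimate_density_series(ds$survey, B = 200, seed = 3)
  expect_identical(d1, d2)
  expect_setequal(unique(d1$species), c("roe", "fallow"))
  expect_equal(nrow(d1), 6L)
  expect_true(all(d1$ci_low <= d1$density & d1$density <= d1$ci_high))
})
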