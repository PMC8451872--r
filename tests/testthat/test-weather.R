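# Growing-season summaries and aridity classification.

test_that("growing-season sums cover exactly March through July", {
  w <- constant_weather(2015, rain = 1, temp = 20)
  gs <- growing_season_summary(w, 2015)
  expect_equal(gs$growing_rain_mm, 153)  # 31+30+31+30+31 days
  expect_equal(gs$growing_temp_c, 20)
  # leap year: February 29 never enters the window
  gs16 <- growing_season_summary(constant_weather(2016, rain = 1), 2016)
  expect_equal(gs16$growing_rain_mm, 153)

  w0 <- constant_weather(2015, rain = 0)
  expect_equal(growing_season_summary(w0, 2015)$growing_rain_mm, 0)
})

test_that("small gaps are tolerated, large gaps are an error", {
  w <- constant_weather(2015, rain = 1, temp = 20)
  w_small <- w[!(w$date >= as.Date("2015-04-10") & w$date <= as.Date("2015-04-12")), ]
  expect_warning(gs <- growing_season_summary(w_small, 2015), "missing")
  expect_equal(gs$growing_rain_mm, 150)   # gap days count as dry
  expect_equal(gs$growing_temp_c, 20)     # interpolation is exact here

  w_big <- w[!(w$date >= as.Date("2015-05-01") & w$date <= as.Date("2015-05-10")), ]
  expect_error(growing_season_summary(w_big, 2015), "gap > 5 days")
})

test_that("aridity splits at the median drought index with ties non-arid", {
  wy <- data.frame(year = 1:2, growing_rain_mm = c(100, 400),
                   growing_temp_c = 18)
  wy$drought_index <- wy$growing_rain_mm * (12 / 5) / (wy$growing_temp_c + 10)
  cls <- classify_aridity(wy)
  expect_equal(as.character(cls$aridity_class), c("arid", "non_arid"))

  same <- data.frame(year = 1:3, growing_rain_mm = 250, growing_temp_c = 18,
                     drought_index = 25)
  expect_true(all(classify_aridity(same)$aridity_class == "non_arid"))

  four <- data.frame(year = 1:4, growing_rain_mm = c(150, 250, 350, 450),
                     growing_temp_c = 18)
  four$drought_index <- four$growing_rain_mm * (12 / 5) / 28
  expect_equal(sum(classify_aridity(four)$aridity_class == "arid"), 2L)
  expect_error(classify_aridity(four, method = "bogus"))
  expect_error(classify_aridity(four, method = "index_threshold"), "threshold")
  thr <- classify_aridity(four, method = "index_threshold", threshold = 20)
  expect_equal(sum(thr$aridity_class == "arid"), 1L)
})

test_that("raising rainfall never turns a year arid", {
  set.seed(12)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    wy <- data.frame(year = seq_len(n),
                     growing_rain_mm = runif(n, 50, 500),
                     growing_temp_c = 18)
    wy$drought_index <- wy$growing_rain_mm * (12 / 5) / 28
    before <- classify_aridity(wy)$aridity_class
    j <- sample(n, 1)
    wy$growing_rain_mm[j] <- wy$growing_rain_mm[j] + runif(1, 1, 300)
    wy$drought_index <- wy$growing_rain_mm * (12 / 5) / 28
    after <- classify_aridity(wy)$aridity_class
    if (before[j] == "non_arid") expect_equal(as.character(after[j]), "non_arid")
  }
})

test_that("classification is invariant to row order", {
  wy <- data.frame(year = 1:5, growing_rain_mm = c(90, 210, 330, 150, 480),
                   growing_temp_c = c(17, 18, 19, 18, 17))
  wy$drought_index <- wy$growing_rain_mm * (12 / 5) / (wy$growing_temp_c + 10)
  a <- classify_aridity(wy)
  b <- classify_aridity(wy[c(3, 1, 5, 2, 4), ])
  merged <- merge(a[, c("year", "aridity_class")],
                  b[, c("year", "aridity_class")], by = "year")
  expect_equal(as.character(merged$aridity_class.x),
               as.character(merged$aridity_class.y))
})

test_that("weather-year tables feed the aridity classifier end to end", {
  w <- simulate_weather(6, seed = 77, mean_growing_rain_mm = 250,
                        sd_growing_rain_mm = 100)
  wy <- classify_aridity(weather_year_table(w))
  expect_equal(nrow(wy), 6L)
  expect_true(all(c("arid", "non_arid") %in% levels(wy$aridity_class)))
  expect_true(all(wy$growing_rain_mm >= 0))
})
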