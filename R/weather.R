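# Growing-season weather covariates and aridity classification.
#
# The growing season is March 1 - July 31 (153 days; February never enters
# the window, so leap years change nothing).

growing_window <- function(year) {
  seq(as.Date(sprintf("%d-03-01", year)), as.Date(sprintf("%d-07-31", year)),
      by = "day")
}

#' Summarise one growing season
#'
#' Sums rainfall and averages temperature over March 1 - July 31 of `year`.
#' Missing days are tolerated up to gaps of 5 consecutive days: temperature
#' is linearly interpolated across a gap, rainfall in a gap is treated as 0
#' with a warning. Larger gaps are an error naming the gap.
#'
#' @param daily_table Daily weather table (see [read_weather()]).
#' @param year Calendar year.
#' @return One-row data frame: `year`, `growing_rain_mm`, `growing_temp_c`,
#'   `drought_index` (De Martonne-type, see [classify_aridity()]).
#' @export
growing_season_summary <- function(daily_table, year) {
  window <- growing_window(year)
  idx <- match(window, daily_table$date)
  missing <- is.na(idx)
  if (any(missing)) {
    r <- rle(missing)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bad <- which(r$values & r$lengths > 5L)
    if (length(bad)) {
      stop_input("weather coverage gap > 5 days in ", year, ": ",
                 format(window[starts[bad[1L]]]), " to ",
                 format(window[ends[bad[1L]]]))
    }
    warning(sprintf("%d missing weather day(s) in %d: rainfall taken as 0, temperature interpolated",
                    sum(missing), year))
  }
  rain <- daily_table$rain_mm[idx]
  rain[is.na(rain)] <- 0
  temp <- daily_table$temp_c[idx]
  if (anyNA(temp)) {
    day <- as.numeric(window)
    temp <- stats::approx(day[!is.na(temp)], temp[!is.na(temp)], xout = day,
                          rule = 2)$y
  }
  rain_sum <- sum(rain)
  temp_mean <- mean(temp)
  data.frame(year = year, growing_rain_mm = rain_sum,
             growing_temp_c = temp_mean,
             drought_index = rain_sum * (12 / 5) / (temp_mean + 10))
}

#' Growing-season summaries for every year in a weather table
#'
#' @param daily_table Daily weather table.
#' @param years Years to summarise; defaults to every calendar year with a
#'   complete growing window in the table.
#' @return Data frame of [growing_season_summary()] rows.
#' @export
weather_year_table <- function(daily_table, years = NULL) {
  if (is.null(years)) {
    years <- sort(unique(as.integer(format(daily_table$date, "%Y"))))
  }
  out <- do.call(rbind, lapply(years, growing_season_summary,
                               daily_table = daily_table))
  rownames(out) <- NULL
  out
}

#' Classify growing seasons as arid or non-arid
#'
#' The default method computes a De Martonne-type index,
#' `growing_rain_mm * (12/5) / (growing_temp_c + 10)` (the 12/5 factor
#' annualises the 5-month window), and labels years below the
#' within-dataset median as arid; ties go to non-arid. Alternatives: a
#' fixed index threshold, or a rainfall-only median split. Any monotone,
#' rainfall-dominated index gives the same ordering, which is all the
#' downstream two-level aridity factor uses.
#'
#' @param weather_years Data frame from [weather_year_table()] (needs
#'   `growing_rain_mm`, `growing_temp_c` or `drought_index`).
#' @param method `"demartonne_median"`, `"index_threshold"`, or
#'   `"rain_median"`.
#' @param threshold Index cut for `"index_threshold"`.
#' @return `weather_years` with `aridity_class` (factor, levels
#'   `c("arid", "non_arid")`, reference arid) and `method` columns.
#' @export
classify_aridity <- function(weather_years,
                             method = c("demartonne_median", "index_threshold",
                                        "rain_median"),
                             threshold = NULL) {
  method <- match.arg(method)
  if (nrow(weather_years) < 2L) stop_input("need at least 2 years to classify")
  index <- weather_years$drought_index %||%
    (weather_years$growing_rain_mm * (12 / 5) / (weather_years$growing_temp_c + 10))
  cut <- switch(method,
    demartonne_median = stats::median(index),
    index_threshold = {
      if (is.null(threshold)) stop_input("index_threshold method needs a threshold")
      threshold
    },
    rain_median = {
      index <- weather_years$growing_rain_mm
      stats::median(index)
    })
  arid <- index < cut  # ties -> non_arid
  out <- weather_years
  out$aridity_class <- factor(ifelse(arid, "arid", "non_arid"),
                              levels = c("arid", "non_arid"))
  out$method <- method
  out
}
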