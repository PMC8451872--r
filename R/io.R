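# Readers and writers for the package's plain-text interchange formats.

SURVEY_COLUMNS <- c("plot_id", "year", "habitat", "radius_m", "interval_days",
                    "roe_pg", "fallow_pg")

#' Read a plot-survey table
#'
#' Expects one row per plot x year with columns `plot_id`, `year`,
#' `habitat`, `radius_m`, `interval_days`, `roe_pg`, `fallow_pg`, and
#' validates the plot-record invariants (positive radius and interval,
#' non-negative integer counts).
#'
#' @param path CSV file path.
#' @return Data frame of plot records.
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop_input("survey file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_survey(x)
}

validate_survey <- function(x) {
  missing_cols <- setdiff(SURVEY_COLUMNS, names(x))
  if (length(missing_cols)) {
    stop_input("survey table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(x$radius_m <= 0)) stop_input("plot radius must be positive")
  if (any(x$interval_days <= 0)) stop_input("accumulation interval must be positive")
  counts <- c(x$roe_pg, x$fallow_pg)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_input("pellet-group counts must be non-negative integers")
  }
  x
}

#' Read a daily weather table
#'
#' Expects columns `date` (ISO-8601), `rain_mm`, `temp_c`.
#'
#' @param path CSV file path.
#' @return Data frame with a `Date`-classed `date` column.
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) stop_input("weather file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "rain_mm", "temp_c")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop_input("weather table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) stop_input("weather dates must be ISO-8601")
  if (any(x$rain_mm < 0, na.rm = TRUE)) stop_input("rainfall must be non-negative")
  x
}

#' Read a run configuration from JSON or YAML
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return The parsed configuration list (validated by [run_config()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_input("yaml package required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, cfg)
}

# deterministic JSON serialisation used by the report and fit writers
write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  invisible(path)
}
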