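# Fecal-accumulation-rate density estimation.
#
# Pellet-group counts accumulated between a clearing and a counting survey
# are converted to animal densities by dividing through plot area, interval
# length and the species' defecation rate; uncertainty comes from a seeded
# percentile bootstrap over plots.

#' Estimate study-area density from pellet-group counts
#'
#' Per-plot density is `count / (plot_area_km2 * interval_days *
#' defecation_rate)`; the study-area density is the unweighted mean over
#' plots, or, with `stratified = TRUE`, the habitat-area-fraction-weighted
#' mean of habitat means (resampling within habitat). The SE and 95\%
#' interval come from a percentile bootstrap over plots with `B` resamples
#' under a fixed, recorded seed. Each plot uses its own accumulation
#' interval, so designs with between-plot interval variation are handled
#' exactly.
#'
#' @param records Plot records for one species-year: a data frame with
#'   `radius_m`, `interval_days` and the count column named by `count_col`.
#' @param defecation_rate Pellet groups per individual per day (> 0).
#' @param count_col Name of the count column (e.g. `"roe_pg"`).
#' @param stratified Use the habitat-stratified estimator (requires a
#'   `habitat` column).
#' @param area_fraction Named habitat area fractions for the stratified
#'   estimator; defaults to the plot share per habitat.
#' @param B Bootstrap resamples.
#' @param seed Bootstrap seed (recorded in the result).
#' @param level Confidence level.
#' @param species,year Optional labels carried into the result.
#' @return One-row data frame of class `deer_density_estimate` with columns
#'   `species`, `year`, `density`, `se`, `ci_low`, `ci_high`, `weight`,
#'   `n_plots`, `bootstrap_seed` (`weight` is `NA` for a zero-width
#'   interval; see [precision_weight()]).
#' @export
estimate_density <- function(records, defecation_rate, count_col = "roe_pg",
                             stratified = FALSE, area_fraction = NULL,
                             B = 1000L, seed = 1L, level = 0.95,
                             species = NA_character_, year = NA_integer_) {
  if (nrow(records) < 2L) {
    stop_input("at least 2 plots are required for a confidence interval")
  }
  if (defecation_rate <= 0) stop_input("defecation_rate must be positive")
  if (!count_col %in% names(records)) stop_input("no column ", count_col)
  counts <- records[[count_col]]
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_input("counts must be non-negative integers")
  }
  area_km2 <- pi * records$radius_m^2 * 1e-6
  if (any(area_km2 <= 0) || any(records$interval_days <= 0)) {
    stop_input("plot area and interval must be positive")
  }
  d <- counts / (area_km2 * records$interval_days * defecation_rate)

  point <- function(dd, strata) {
    if (!stratified) return(mean(dd))
    means <- tapply(dd, strata, mean)
    fr <- if (is.null(area_fraction)) {
      tab <- table(strata)
      tab / sum(tab)
    } else {
      area_fraction[names(means)] / sum(area_fraction[names(means)])
    }
    sum(unlist(means) * as.numeric(fr[names(means)]))
  }

  strata <- if (stratified) {
    if (is.null(records$habitat)) stop_input("stratified estimate needs a habitat column")
    factor(records$habitat)
  } else {
    factor(rep(1L, length(d)))
  }
  est <- point(d, strata)

  boot <- with_seed(seed, {
    idx_by <- split(seq_along(d), strata)
    reps <- matrix(0, nrow = B, ncol = length(idx_by))
    for (j in seq_along(idx_by)) {
      ids <- idx_by[[j]]
      m <- matrix(d[sample(ids, length(ids) * B, replace = TRUE)], nrow = length(ids))
      reps[, j] <- colMeans(m)
    }
    if (!stratified) {
      reps[, 1L]
    } else {
      fr <- if (is.null(area_fraction)) {
        tab <- table(strata)
        as.numeric(tab / sum(tab))
      } else {
        f <- area_fraction[names(idx_by)]
        as.numeric(f / sum(f))
      }
      as.numeric(reps %*% fr)
    }
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)
  width <- ci[2L] - ci[1L]
  out <- data.frame(species = species, year = year,
                    density = est, se = stats::sd(boot),
                    ci_low = ci[1L], ci_high = ci[2L],
                    weight = if (width > 0) 1 / width else NA_real_,
                    n_plots = nrow(records),
                    bootstrap_seed = as.integer(seed))
  class(out) <- c("deer_density_estimate", class(out))
  out
}

#' Density estimates for every species-year in a survey table
#'
#' @param survey Survey table (see [read_survey()]).
#' @param defecation_rate Named rates, pellet groups/day, for `roe` and
#'   `fallow`.
#' @param seed Base seed; each species-year uses a derived sub-seed so the
#'   whole table is reproducible.
#' @inheritParams estimate_density
#' @return Data frame with one row per species and year.
#' @export
estimate_density_series <- function(survey,
                                    defecation_rate = c(roe = 20, fallow = 25),
                                    stratified = FALSE, area_fraction = NULL,
                                    B = 1000L, seed = 1L) {
  validate_survey(survey)
  years <- sort(unique(survey$year))
  rows <- list()
  for (sp in c("roe", "fallow")) {
    col <- paste0(sp, "_pg")
    for (i in seq_along(years)) {
      recs <- survey[survey$year == years[i], , drop = FALSE]
      rows[[length(rows) + 1L]] <- estimate_density(
        recs, defecation_rate[[sp]], count_col = col,
        stratified = stratified, area_fraction = area_fraction,
        B = B, seed = derive_seed(seed, i * 2L + (sp == "fallow")),
        species = sp, year = years[i])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Precision weight of a density estimate
#'
#' The inverse of the 95\% confidence-interval width (or, optionally, the
#' inverse bootstrap variance). Weights for a set of years should be
#' rescaled to mean 1 with [rescale_weights()] before entering a weighted
#' regression.
#'
#' @param est A `deer_density_estimate` row (or any data frame with
#'   `ci_low`, `ci_high`, `se`).
#' @param method `"inv_width"` (default) or `"inv_variance"`.
#' @return Positive numeric weight(s).
#' @export
precision_weight <- function(est, method = c("inv_width", "inv_variance")) {
  method <- match.arg(method)
  if (any(est$ci_high < est$ci_low)) stop_input("ci_high must be >= ci_low")
  if (method == "inv_width") {
    width <- est$ci_high - est$ci_low
    if (any(width <= 0)) {
      stop_input("zero-width confidence interval: use an unweighted fit for this year")
    }
    1 / width
  } else {
    if (any(est$se <= 0)) stop_input("zero bootstrap variance: use an unweighted fit")
    1 / est$se^2
  }
}

#' Rescale weights to mean one
#'
#' Keeps the Gaussian likelihood (and hence AICc) on a comparable scale
#' across candidate models.
#'
#' @param w Positive weights.
#' @return Weights scaled to mean exactly 1.
#' @export
rescale_weights <- function(w) {
  if (any(w <= 0) || anyNA(w)) stop_input("weights must be positive")
  w / mean(w)
}

#' Relative standard error of a density estimate
#'
#' @param est A `deer_density_estimate` row.
#' @return `se / density` as a proportion.
#' @export
relative_se <- function(est) {
  if (any(est$density <= 0)) {
    stop_input("relative SE undefined for zero density")
  }
  est$se / est$density
}

#' @exportS3Method base::print
print.deer_density_estimate <- function(x, ...) {
  cat(sprintf("Density estimate%s%s: %.3f ind/km^2 (95%% CI %.3f-%.3f, %d plots)\n",
              if (!is.null(x$species) && !is.na(x$species[1L])) {
                paste0(" [", x$species[1L], "]")
              } else "",
              if (!is.null(x$year) && !is.na(x$year[1L])) {
                paste0(" year ", x$year[1L])
              } else "",
              x$density[1L], x$ci_low[1L], x$ci_high[1L], x$n_plots[1L]))
  invisible(x)
}
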