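# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# single-habitat landscape with unit preference, for exact deposition checks
flat_landscape <- function(n_plots = 10L, radius = 5) {
  landscape_config(habitat_classes = "ecotone",
                   area_fraction = c(ecotone = 1),
                   n_plots = n_plots, plot_radius_m = radius,
                   preference = list(roe = c(ecotone = 1),
                                     fallow = c(ecotone = 1)))
}

# truth with all random structure and suppression switched off
quiet_truth <- function(occupancy_suppression = 0, ...) {
  simulation_truth(process_sd = 0,
                   occupancy_suppression = occupancy_suppression,
                   plot_re_sd = 0, year_re_sd = 0, ...)
}

# minimal hand-built survey covering two habitats and two years
toy_survey <- function() {
  data.frame(
    plot_id = rep(sprintf("P%02d", 1:6), 2),
    year = rep(c(2007L, 2008L), each = 6),
    habitat = rep(c("ecotone", "ecotone", "ecotone", "garigue", "garigue",
                    "pinewood"), 2),
    radius_m = 5,
    interval_days = 36,
    roe_pg = c(3, 1, 6, 2, 0, 0, 1, 3, 0, 4, 2, 0),
    fallow_pg = c(3, 1, 6, 0, 5, 2, 2, 2, 1, 1, 0, 3),
    stringsAsFactors = FALSE)
}

# daily weather with constant values over the full calendar years
constant_weather <- function(years, rain = 1, temp = 20) {
  dates <- do.call(c, lapply(years, function(y) {
    seq(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-12-31", y)),
        by = "day")
  }))
  data.frame(date = dates, rain_mm = rain, temp_c = temp)
}

# a deer_fit shell carrying just what wald_ci() and select_best() consume
fit_shell <- function(fixed, aicc_value, k = length(fixed) + 1L,
                      loglik = 0, estimate = NULL, se = NULL) {
  coefs <- estimate %||% stats::setNames(numeric(0), character(0))
  vc <- if (length(coefs)) diag(se^2, length(coefs)) else matrix(0, 0, 0)
  if (length(coefs)) dimnames(vc) <- list(names(coefs), names(coefs))
  structure(list(spec = list(fixed = fixed, response = "y", family = "test",
                             link = "identity", random = character()),
                 coefficients = coefs, vcov = vc, random_variances = numeric(),
                 dispersion = numeric(), loglik = loglik, n_obs = 10L,
                 k_params = k, aicc = aicc_value, converged = TRUE,
                 df_resid = NULL),
            class = "deer_fit")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
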