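# End-to-end orchestration of the three analyses: study-area density,
# plot-scale occupancy, and habitat-year spatial overlap.

#' Assemble and validate a run configuration
#'
#' Exactly one of `survey`/`weather` file paths or a `simulation` block must
#' be supplied. The simulation block is a list with optional `truth`
#' ([simulation_truth()]), `landscape` ([landscape_config()]) and `years`
#' entries.
#'
#' @param survey,weather CSV paths for real inputs (both or neither).
#' @param simulation Simulation block (see above), or `NULL`.
#' @param analyses Which analyses to run in [run_pipeline()].
#' @param defecation_rate Named pellet-groups/day rates for `roe`, `fallow`.
#' @param aridity_method Method for [classify_aridity()].
#' @param bootstrap_reps Bootstrap resamples for density CIs.
#' @param weight_method Precision-weight method, see [precision_weight()].
#' @param missing_years Survey years treated as unsurveyed (dropped from
#'   the annual density table, with the lagged pairs straddling the gap).
#' @param min_habitat_rows Minimum usable plot-years for a per-habitat
#'   occupancy model.
#' @param occupancy_per_habitat Also fit the per-habitat aridity models.
#' @param collinearity_override Continue past a flagged collinearity screen.
#' @param overlap_source `"survey"` derives the overlap table from plot
#'   counts; `"simulate"` draws it from the generative Beta model (needs a
#'   simulation block).
#' @param seed Integer seed governing every stochastic step.
#' @param out_dir Optional output directory for [run_report()].
#' @return A validated list of class `deer_run_config`.
#' @export
run_config <- function(survey = NULL, weather = NULL, simulation = NULL,
                       analyses = c("density", "occupancy", "overlap"),
                       defecation_rate = c(roe = 20, fallow = 25),
                       aridity_method = "demartonne_median",
                       bootstrap_reps = 1000L,
                       weight_method = "inv_width",
                       missing_years = NULL,
                       min_habitat_rows = 10L,
                       occupancy_per_habitat = TRUE,
                       collinearity_override = FALSE,
                       overlap_source = c("survey", "simulate"),
                       seed = 1L, out_dir = NULL) {
  has_paths <- !is.null(survey) || !is.null(weather)
  has_sim <- !is.null(simulation)
  if (has_paths == has_sim) {
    stop_input("supply either survey+weather paths or a simulation block, not both")
  }
  if (has_paths && (is.null(survey) || is.null(weather))) {
    stop_input("both survey and weather paths are required")
  }
  if (any(defecation_rate <= 0)) stop_input("defecation rates must be > 0")
  overlap_source <- match.arg(overlap_source)
  if (overlap_source == "simulate" && !has_sim) {
    stop_input("overlap_source = 'simulate' requires a simulation block")
  }
  if (has_sim) {
    simulation$truth <- simulation$truth %||% simulation_truth()
    simulation$landscape <- simulation$landscape %||% landscape_config()
    simulation$years <- simulation$years %||% 11L
  }
  structure(
    list(survey = survey, weather = weather, simulation = simulation,
         analyses = analyses, defecation_rate = defecation_rate,
         aridity_method = aridity_method,
         bootstrap_reps = as.integer(bootstrap_reps),
         weight_method = weight_method, missing_years = missing_years,
         min_habitat_rows = as.integer(min_habitat_rows),
         occupancy_per_habitat = isTRUE(occupancy_per_habitat),
         collinearity_override = isTRUE(collinearity_override),
         overlap_source = overlap_source,
         seed = as.integer(seed), out_dir = out_dir),
    class = "deer_run_config")
}

load_inputs <- function(config) {
  if (!is.null(config$simulation)) {
    ds <- simulate_dataset(truth = config$simulation$truth,
                           landscape = config$simulation$landscape,
                           years = config$simulation$years,
                           seed = config$seed)
    list(survey = ds$survey, weather = ds$weather, synth = ds)
  } else {
    list(survey = read_survey(config$survey),
         weather = read_weather(config$weather), synth = NULL)
  }
}

check_screen <- function(screen, config, where) {
  if (any(screen$flagged)) {
    msg <- paste0("collinearity flagged in ", where, " covariates: ",
                  paste(sprintf("%s~%s (r=%.2f)",
                                screen$var1[screen$flagged],
                                screen$var2[screen$flagged],
                                screen$r[screen$flagged]), collapse = ", "))
    if (!config$collinearity_override) {
      stop(errorCondition(paste0(msg, "; set collinearity_override = TRUE to continue"),
                          class = c("deercomp_collinearity_block", "error")))
    }
    warning(msg, " (override active)")
  }
  invisible(screen)
}

#' Study-area density analysis
#'
#' Estimates annual densities for both species, builds the lagged annual
#' table (roe density in year t against fallow density in years t and t-1,
#' roe density in t-1, and growing-season rainfall of t-1), rescales the
#' precision weights to mean 1, screens the predictors for collinearity,
#' fits every admissible weighted Gaussian candidate, applies the AICc
#' nesting rule, and checks best-model residual normality (Shapiro-Wilk).
#' Years listed in `missing_years` are treated as unsurveyed: both lagged
#' pairs into and out of each gap are dropped.
#'
#' @param config A [run_config()].
#' @param inputs Optional preloaded inputs (internal reuse).
#' @return List of class `deer_density_analysis`: `density_table`,
#'   `annual_table`, `screen`, `selection`, `best_fit`, `global_fit`,
#'   `shapiro`.
#' @export
run_density_analysis <- function(config, inputs = NULL) {
  inputs <- inputs %||% load_inputs(config)
  dens <- estimate_density_series(inputs$survey, config$defecation_rate,
                                  B = config$bootstrap_reps,
                                  seed = derive_seed(config$seed, 101L))
  if (!is.null(config$missing_years)) {
    dens <- dens[!dens$year %in% config$missing_years, , drop = FALSE]
  }
  wy <- weather_year_table(inputs$weather)
  years <- sort(unique(dens$year))
  pick <- function(sp, yr, col) {
    v <- dens[dens$species == sp & dens$year == yr, col]
    if (length(v) == 1L) v else NA_real_
  }
  rows <- list()
  for (yr in years) {
    if (!(yr - 1L) %in% years) next  # lagged pair straddles a gap
    rain_tm1 <- wy$growing_rain_mm[wy$year == yr - 1L]
    rows[[length(rows) + 1L]] <- data.frame(
      year = yr,
      roe_t = pick("roe", yr, "density"),
      fallow_t = pick("fallow", yr, "density"),
      fallow_tm1 = pick("fallow", yr - 1L, "density"),
      roe_tm1 = pick("roe", yr - 1L, "density"),
      rain_tm1 = if (length(rain_tm1)) rain_tm1 else NA_real_,
      ci_width = pick("roe", yr, "ci_high") - pick("roe", yr, "ci_low"),
      se = pick("roe", yr, "se"))
  }
  if (length(rows) < 5L) {
    stop_input("fewer than 5 usable year-rows after lagging (got ",
               length(rows), ")")
  }
  annual <- do.call(rbind, rows)
  annual$weight <- rescale_weights(
    precision_weight(data.frame(ci_low = 0, ci_high = annual$ci_width,
                                se = annual$se),
                     method = config$weight_method))
  predictors <- c("fallow_t", "fallow_tm1", "roe_tm1", "rain_tm1")
  screen <- collinearity_screen(annual, predictors)
  check_screen(screen, config, "density-model")
  global_spec <- model_spec("roe_t", "gaussian", fixed = predictors,
                            weights = "weight")
  selection <- fit_candidates(global_spec, annual)
  global_fit <- fit_wls(global_spec, annual)
  best <- selection$best
  resid <- annual$roe_t - best$fitted
  shapiro <- if (length(unique(round(resid, 10))) > 2L) {
    stats::shapiro.test(resid)
  } else {
    NULL
  }
  structure(list(density_table = dens, annual_table = annual, screen = screen,
                 selection = selection, best_fit = best,
                 global_fit = global_fit, shapiro = shapiro),
            class = "deer_density_analysis")
}

#' Plot-scale occupancy analysis
#'
#' Filters to plot-years where at least one species was detected and drops
#' pinewood (roe deer never occur there), then fits (i) a binomial-logit
#' model of roe presence and (ii) a negative-binomial-log model of roe
#' pellet-group abundance, each with habitat, local fallow abundance and
#' their interaction as fixed effects (reference habitat: ecotone) and
#' year and plot as crossed random intercepts, through AICc selection.
#' Second-level models are then fitted separately per habitat with aridity
#' class (reference: arid), fallow abundance and their interaction, and a
#' plot random intercept; habitats with fewer usable rows than
#' `min_habitat_rows` are skipped with a warning.
#'
#' @param config A [run_config()].
#' @param inputs Optional preloaded inputs.
#' @param per_habitat Fit the per-habitat aridity models as well.
#' @return List of class `deer_occupancy_analysis` with `data`,
#'   `presence`, `abundance` (each a `deer_candidates`), `screen`, and
#'   `habitat_models`.
#' @export
run_occupancy_analysis <- function(config, inputs = NULL,
                                   per_habitat = config$occupancy_per_habitat %||% TRUE) {
  inputs <- inputs %||% load_inputs(config)
  survey <- validate_survey(inputs$survey)
  if (length(unique(survey$year)) < 2L || length(unique(survey$habitat)) < 2L) {
    stop_input("occupancy analysis needs >= 2 years and >= 2 habitats")
  }
  dat <- survey[survey$roe_pg > 0 | survey$fallow_pg > 0, , drop = FALSE]
  dat <- dat[dat$habitat != "pinewood", , drop = FALSE]
  dat$presence <- as.integer(dat$roe_pg > 0)
  dat$year_f <- factor(dat$year)
  wy <- classify_aridity(weather_year_table(inputs$weather),
                         method = config$aridity_method)
  dat$aridity <- wy$aridity_class[match(dat$year, wy$year)]
  screen <- collinearity_screen(dat, c("habitat", "fallow_pg"))
  check_screen(screen, config, "occupancy-model")
  ref <- list(habitat = "ecotone")
  pres_spec <- model_spec("presence", "binomial",
                          fixed = c("habitat", "fallow_pg", "habitat:fallow_pg"),
                          random = c("year_f", "plot_id"),
                          reference_levels = ref)
  abund_spec <- model_spec("roe_pg", "negbin",
                           fixed = c("habitat", "fallow_pg", "habitat:fallow_pg"),
                           random = c("year_f", "plot_id"),
                           reference_levels = ref)
  presence <- fit_candidates(pres_spec, dat)
  abundance <- fit_candidates(abund_spec, dat)

  habitat_models <- list()
  if (per_habitat) {
    for (h in sort(unique(dat$habitat))) {
      sub <- dat[dat$habitat == h, , drop = FALSE]
      if (nrow(sub) < config$min_habitat_rows) {
        warning("habitat ", h, " skipped: only ", nrow(sub), " usable plot-years")
        next
      }
      refs <- list(aridity = "arid")
      hm <- lapply(c(presence = "binomial", abundance = "negbin"), function(famly) {
        resp <- if (famly == "binomial") "presence" else "roe_pg"
        sp <- model_spec(resp, famly,
                         fixed = c("aridity", "fallow_pg", "aridity:fallow_pg"),
                         random = "plot_id", reference_levels = refs)
        tryCatch(fit_candidates(sp, sub),
                 error = function(e) {
                   warning("per-habitat model failed for ", h, ": ",
                           conditionMessage(e))
                   NULL
                 })
      })
      habitat_models[[h]] <- hm
    }
  }
  structure(list(data = dat, screen = screen, presence = presence,
                 abundance = abundance, habitat_models = habitat_models,
                 aridity = wy),
            class = "deer_occupancy_analysis")
}

#' Habitat-year overlap analysis
#'
#' Builds (or, with `overlap_source = "simulate"`, draws from the
#' generative Beta model) the habitat-year overlap table, drops records
#' where an index is undefined, and fits Beta-logit candidate models for
#' the Pianka index and the shared-space proportion with habitat,
#' same-year growing-season rainfall, their interaction, and the two
#' pellet sums as covariates, through AICc selection.
#'
#' @param config A [run_config()].
#' @param inputs Optional preloaded inputs.
#' @return List of class `deer_overlap_analysis` with `table`, `screen`,
#'   and per-index `selection`/`global_fit` entries.
#' @export
run_overlap_analysis <- function(config, inputs = NULL) {
  inputs <- inputs %||% load_inputs(config)
  wy <- weather_year_table(inputs$weather)
  tab <- if (config$overlap_source == "simulate") {
    simulate_overlap_table(config$simulation$truth, wy,
                           seed = derive_seed(config$seed, 201L))
  } else {
    build_overlap_table(inputs$survey, wy)
  }
  if (nrow(tab) < 10L) {
    stop_input("overlap table has fewer than 10 records")
  }
  fit_index <- function(response) {
    use <- tab[!is.na(tab[[response]]), , drop = FALSE]
    if (nrow(use) < 10L) {
      stop_input("overlap table has fewer than 10 defined ", response, " records")
    }
    spec <- model_spec(response, "beta",
                       fixed = c("habitat", "rainfall_mm", "habitat:rainfall_mm",
                                 "roe_pg_sum", "fallow_pg_sum"),
                       reference_levels = list(habitat = "ecotone"))
    list(selection = fit_candidates(spec, use),
         global_fit = fit_glm(spec, use),
         n = nrow(use))
  }
  screen <- collinearity_screen(
    tab, c("habitat", "rainfall_mm", "roe_pg_sum", "fallow_pg_sum"))
  check_screen(screen, config, "overlap-model")
  structure(list(table = tab, screen = screen,
                 pianka = fit_index("pianka"),
                 prop_shared = fit_index("prop_shared")),
            class = "deer_overlap_analysis")
}

#' Run every enabled analysis and write the consolidated report
#'
#' @param config A [run_config()].
#' @return List of class `deer_run` with the per-analysis results and, if
#'   `config$out_dir` is set, the report paths.
#' @export
run_pipeline <- function(config) {
  inputs <- load_inputs(config)
  results <- list(config = config)
  if ("density" %in% config$analyses) {
    results$density <- run_density_analysis(config, inputs)
  }
  if ("occupancy" %in% config$analyses) {
    results$occupancy <- run_occupancy_analysis(config, inputs)
  }
  if ("overlap" %in% config$analyses) {
    results$overlap <- run_overlap_analysis(config, inputs)
  }
  results <- structure(results, class = "deer_run")
  if (!is.null(config$out_dir)) {
    results$report <- run_report(results, config, config$out_dir)
  }
  results
}
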