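# Consolidated human- and machine-readable reporting.

#' Write the consolidated analysis report
#'
#' Produces `report.md` (density series, selection tables, coefficient
#' tables with 95\% CIs, random-intercept variances and zero-exclusion
#' flags, diagnostic notes) and `report.json` (the same content,
#' machine-readable and byte-stable under a fixed config and seed). CSV
#' side tables are written for the density series, each selection table,
#' and the overlap records. Analyses that were disabled are listed as
#' omitted, with the reason.
#'
#' @param results A `deer_run` (or a list with any of `density`,
#'   `occupancy`, `overlap`).
#' @param config The [run_config()] used.
#' @param out_dir Output directory.
#' @return Invisibly, named vector of the files written.
#' @export
run_report <- function(results, config, out_dir) {
  if (is.null(results$density) && is.null(results$occupancy) &&
      is.null(results$overlap)) {
    stop_input("no completed analysis to report; run at least one of ",
               "density/occupancy/overlap")
  }
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop_input("cannot create report directory: ", out_dir)
  files <- character()
  md <- c("# Deer competition analysis report", "")

  fmt_sel <- function(sel) {
    tab <- sel$table
    c("| model | k | logLik | AICc | dAICc | retained | weight |",
      "|---|---|---|---|---|---|---|",
      sprintf("| %s | %d | %.3f | %.3f | %.3f | %s | %s |",
              tab$model, tab$k, tab$loglik, tab$aicc, tab$delta_aicc,
              ifelse(tab$retained, "yes", ""),
              ifelse(is.na(tab$weight), "", sprintf("%.4f", tab$weight))))
  }
  fmt_fit <- function(fit) {
    ci <- fit$ci
    out <- c("| predictor | B | 95% CI | |",
             "|---|---|---|---|",
             sprintf("| %s | %.3f | %.3f; %.3f | %s |", ci$term, ci$estimate,
                     ci$ci_low, ci$ci_high,
                     ifelse(ci$excludes_zero, "*", "")))
    if (length(fit$random_variances)) {
      out <- c(out, "", paste0("Random-intercept variances: ",
                               paste(sprintf("[%s] var = %.3f",
                                             names(fit$random_variances),
                                             fit$random_variances),
                                     collapse = "; ")))
    }
    out
  }

  json <- list(seed = config$seed)

  if (!is.null(results$density)) {
    da <- results$density
    md <- c(md, "## Study-area density (weighted Gaussian, identity link)", "",
            "Annual density estimates (ind/km^2):", "",
            "| species | year | density | SE | 95% CI | n plots |",
            "|---|---|---|---|---|---|",
            sprintf("| %s | %s | %.3f | %.3f | %.3f-%.3f | %d |",
                    da$density_table$species, da$density_table$year,
                    da$density_table$density, da$density_table$se,
                    da$density_table$ci_low, da$density_table$ci_high,
                    da$density_table$n_plots),
            "", "Model selection:", "", fmt_sel(da$selection),
            "", "Best model coefficients:", "", fmt_fit(da$best_fit))
    if (!is.null(da$shapiro)) {
      md <- c(md, "", sprintf(
        "Residual normality (Shapiro-Wilk): W = %.3f, P = %.2f.",
        da$shapiro$statistic, da$shapiro$p.value))
    }
    f <- file.path(out_dir, "density_estimates.csv")
    utils::write.csv(da$density_table, f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(out_dir, "density_selection.csv")
    utils::write.csv(da$selection$table, f, row.names = FALSE)
    files <- c(files, f)
    json$density <- list(estimates = da$density_table,
                         selection = da$selection$table,
                         best = fit_to_list(da$best_fit),
                         shapiro = if (!is.null(da$shapiro)) {
                           list(W = unname(da$shapiro$statistic),
                                p = da$shapiro$p.value)
                         })
  } else {
    md <- c(md, "## Study-area density", "",
            "Omitted: the density analysis was not enabled in this run.")
  }

  if (!is.null(results$occupancy)) {
    oa <- results$occupancy
    md <- c(md, "", "## Roe presence at plots (binomial, logit link)", "",
            fmt_sel(oa$presence), "", fmt_fit(oa$presence$best),
            "", "## Roe abundance at plots (negative binomial, log link)", "",
            fmt_sel(oa$abundance), "", fmt_fit(oa$abundance$best))
    for (part in c("presence", "abundance")) {
      f <- file.path(out_dir, paste0("occupancy_", part, "_selection.csv"))
      utils::write.csv(oa[[part]]$table, f, row.names = FALSE)
      files <- c(files, f)
    }
    json$occupancy <- list(
      presence = list(selection = oa$presence$table,
                      best = fit_to_list(oa$presence$best)),
      abundance = list(selection = oa$abundance$table,
                       best = fit_to_list(oa$abundance$best)),
      habitat_models = lapply(oa$habitat_models, function(hm) {
        lapply(hm, function(m) if (!is.null(m)) fit_to_list(m$best))
      }))
  } else {
    md <- c(md, "", "## Plot-scale occupancy", "",
            "Omitted: the occupancy analysis was not enabled in this run.")
  }

  if (!is.null(results$overlap)) {
    ov <- results$overlap
    md <- c(md, "", "## Pianka spatial overlap (Beta, logit link)", "",
            fmt_sel(ov$pianka$selection), "", fmt_fit(ov$pianka$selection$best),
            "", "## Shared-space proportion (Beta, logit link)", "",
            fmt_sel(ov$prop_shared$selection), "",
            fmt_fit(ov$prop_shared$selection$best))
    f <- file.path(out_dir, "overlap_table.csv")
    utils::write.csv(ov$table, f, row.names = FALSE)
    files <- c(files, f)
    json$overlap <- list(
      pianka = list(selection = ov$pianka$selection$table,
                    best = fit_to_list(ov$pianka$selection$best)),
      prop_shared = list(selection = ov$prop_shared$selection$table,
                         best = fit_to_list(ov$prop_shared$selection$best)))
  } else {
    md <- c(md, "", "## Spatial overlap", "",
            "Omitted: the overlap analysis was not enabled in this run.")
  }

  md_path <- file.path(out_dir, "report.md")
  writeLines(md, md_path)
  json_path <- file.path(out_dir, "report.json")
  write_json_stable(json, json_path)
  files <- c(files, md_path, json_path)
  invisible(files)
}
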