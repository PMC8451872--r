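# Habitat-year spatial overlap between the two deer species at plot scale.

#' Pianka niche-overlap index
#'
#' The normalised inner product of the two species' per-plot use
#' proportions:
#' \deqn{P = \frac{\sum_i O_{iF} O_{iR}}{\sqrt{\sum_i O_{iF}^2 \sum_i O_{iR}^2}}}
#' where `O_i` for each species is that plot's share of the species' total
#' pellet groups. Bounded in \[0, 1\]; symmetric; invariant to rescaling
#' either species' counts.
#'
#' @param roe_counts,fallow_counts Aligned per-plot pellet-group counts.
#' @return The index, or `NA` when either species is absent from every plot
#'   (the index is undefined and the record is excluded from overlap
#'   models).
#' @export
pianka_index <- function(roe_counts, fallow_counts) {
  if (length(roe_counts) != length(fallow_counts) || length(roe_counts) < 1L) {
    stop_input("count vectors must be the same positive length")
  }
  if (any(roe_counts < 0) || any(fallow_counts < 0)) {
    stop_input("counts must be non-negative")
  }
  sr <- sum(roe_counts)
  sf <- sum(fallow_counts)
  if (sr == 0 || sf == 0) return(NA_real_)
  p <- roe_counts / sr
  q <- fallow_counts / sf
  sum(p * q) / sqrt(sum(p^2) * sum(q^2))
}

#' Proportion of roe-deer space also used by fallow deer
#'
#' `n_FR / n_R`, where `n_R` is the number of plots containing roe pellet
#' groups and `n_FR` the number containing both species. Depends only on
#' presence patterns, not on count magnitudes.
#'
#' @inheritParams pianka_index
#' @return Proportion in \[0, 1\], or `NA` when no plot contains roe sign.
#' @export
shared_space_proportion <- function(roe_counts, fallow_counts) {
  if (length(roe_counts) != length(fallow_counts) || length(roe_counts) < 1L) {
    stop_input("count vectors must be the same positive length")
  }
  n_R <- sum(roe_counts > 0)
  if (n_R == 0) return(NA_real_)
  sum(roe_counts > 0 & fallow_counts > 0) / n_R
}

#' Build the habitat-year overlap table
#'
#' One record per habitat x year (pinewood excluded by default, since roe
#' deer never occur there), with both overlap indices computed on that
#' habitat-year's plots, the plot tallies behind them, and the
#' growing-season rainfall of the same year joined from the weather
#' summaries.
#'
#' @param survey Survey table (see [read_survey()]).
#' @param weather_years Data frame with `year` and `growing_rain_mm`, e.g.
#'   from [weather_year_table()].
#' @param exclude_habitats Habitats dropped before computing records.
#' @return Data frame of overlap records: `habitat`, `year`, `pianka`,
#'   `prop_shared`, `n_plots`, `n_R`, `n_FR`, `roe_pg_sum`,
#'   `fallow_pg_sum`, `rainfall_mm`.
#' @export
build_overlap_table <- function(survey, weather_years,
                                exclude_habitats = "pinewood") {
  validate_survey(survey)
  missing_years <- setdiff(unique(survey$year), weather_years$year)
  if (length(missing_years)) {
    stop_input("weather table lacks survey year(s): ",
               paste(sort(missing_years), collapse = ", "))
  }
  survey <- survey[!survey$habitat %in% exclude_habitats, , drop = FALSE]
  groups <- split(survey, list(survey$habitat, survey$year), drop = TRUE)
  rows <- lapply(groups, function(g) {
    data.frame(habitat = g$habitat[1L], year = g$year[1L],
               pianka = pianka_index(g$roe_pg, g$fallow_pg),
               prop_shared = shared_space_proportion(g$roe_pg, g$fallow_pg),
               n_plots = nrow(g),
               n_R = sum(g$roe_pg > 0),
               n_FR = sum(g$roe_pg > 0 & g$fallow_pg > 0),
               roe_pg_sum = sum(g$roe_pg),
               fallow_pg_sum = sum(g$fallow_pg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$year, out$habitat), , drop = FALSE]
  out$rainfall_mm <- weather_years$growing_rain_mm[match(out$year, weather_years$year)]
  rownames(out) <- NULL
  out
}
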