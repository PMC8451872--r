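# AICc multimodel inference: exhaustive candidate enumeration, the nesting
# rule, standardized Akaike weights, and the collinearity screen.

#' Enumerate all admissible sub-models of a global model
#'
#' Every subset of the global model's fixed terms that respects marginality
#' (an interaction is only present together with both of its main
#' effects), always including the null (intercept-only) model. Random
#' terms, family, weights and reference levels are held constant across
#' candidates.
#'
#' @param global_spec The global [model_spec()].
#' @param max_candidates Safety cap; exceeding it is an error suggesting
#'   term reduction.
#' @return List of [model_spec()] objects, ordered from simplest to most
#'   complex (term count, then term labels).
#' @export
enumerate_candidates <- function(global_spec, max_candidates = 4096L) {
  stopifnot(inherits(global_spec, "deer_model_spec"))
  terms_all <- global_spec$fixed
  ints <- terms_all[grepl(":", terms_all, fixed = TRUE)]
  mains <- setdiff(terms_all, ints)
  main_sets <- list(character())
  for (m in mains) {
    main_sets <- c(main_sets, lapply(main_sets, function(s) c(s, m)))
  }
  sets <- list()
  for (s in main_sets) {
    admissible <- ints[vapply(ints, function(tm) {
      all(strsplit(tm, ":", fixed = TRUE)[[1L]] %in% s)
    }, logical(1L))]
    int_sets <- list(character())
    for (tm in admissible) {
      int_sets <- c(int_sets, lapply(int_sets, function(x) c(x, tm)))
    }
    sets <- c(sets, lapply(int_sets, function(x) c(s, x)))
    if (length(sets) > max_candidates) {
      stop_input("more than ", max_candidates,
                 " candidate models; reduce the number of terms")
    }
  }
  ord <- order(lengths(sets),
               vapply(sets, function(s) paste(sort(s), collapse = "|"), ""))
  lapply(sets[ord], function(s) {
    sp <- global_spec
    sp$fixed <- terms_all[terms_all %in% s]  # preserve global ordering
    sp
  })
}

#' Fit every candidate model
#'
#' Rows with missing values in any column used by the global model are
#' dropped once, before fitting, so all candidates share an identical
#' response vector and their AICc values are comparable. Candidates that
#' fail to converge are dropped with a warning.
#'
#' @param global_spec The global [model_spec()].
#' @param data Data frame.
#' @param ... Passed to [fit_model()].
#' @return An object of class `deer_candidates`: list with `fits`,
#'   `global_spec`, and the selection `table` from [select_best()].
#' @export
fit_candidates <- function(global_spec, data, ...) {
  vars <- unique(c(global_spec$response,
                   unlist(strsplit(global_spec$fixed, ":", fixed = TRUE)),
                   global_spec$random,
                   if (is.character(global_spec$weights)) global_spec$weights))
  vars <- intersect(vars, names(data))
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  if (!all(keep)) {
    message(sum(!keep), " row(s) with missing values dropped before fitting")
    data <- data[keep, , drop = FALSE]
  }
  specs <- enumerate_candidates(global_spec)
  fits <- lapply(specs, function(sp) {
    tryCatch(fit_model(sp, data, ...), error = function(e) {
      warning("candidate {", paste(sp$fixed, collapse = ", "),
              "} failed: ", conditionMessage(e))
      NULL
    })
  })
  ok <- !vapply(fits, is.null, logical(1L))
  conv <- vapply(fits[ok], function(f) isTRUE(f$converged), logical(1L))
  if (!all(conv)) {
    warning(sum(!conv), " non-converged candidate(s) excluded from selection")
  }
  fits <- fits[ok][conv]
  if (!length(fits)) stop_input("no candidate model converged")
  select_best(fits, global_spec = global_spec)
}

#' Apply the AICc nesting rule to fitted candidates
#'
#' A candidate is retained when its AICc lies within 2 units of the
#' minimum AND is strictly lower than the AICc of every strictly simpler
#' candidate nested within it (nesting judged on fixed-term sets, compared
#' against all candidates, retained or not). Ties between nested pairs go
#' to the simpler model. Standardized Akaike weights are computed within
#' the retained subset.
#'
#' @param fits List of `deer_fit` objects over a common dataset.
#' @param delta_max Retention window (AICc units above the minimum).
#' @param global_spec Optional global spec stored for reporting.
#' @return `deer_candidates` object whose `table` has one row per
#'   candidate: `model`, `k`, `loglik`, `aicc`, `delta_aicc`, `retained`,
#'   `weight`.
#' @export
select_best <- function(fits, delta_max = 2, global_spec = NULL) {
  stopifnot(length(fits) >= 1L)
  aiccs <- vapply(fits, function(f) f$aicc, numeric(1L))
  term_sets <- lapply(fits, function(f) f$spec$fixed)
  labels <- vapply(term_sets, function(s) {
    if (length(s)) paste(s, collapse = " + ") else "(null)"
  }, character(1L))
  delta <- aiccs - min(aiccs)
  n_mod <- length(fits)
  retained <- logical(n_mod)
  for (i in seq_len(n_mod)) {
    if (delta[i] > delta_max) next
    simpler <- vapply(seq_len(n_mod), function(j) {
      length(term_sets[[j]]) < length(term_sets[[i]]) &&
        all(term_sets[[j]] %in% term_sets[[i]])
    }, logical(1L))
    retained[i] <- !any(simpler & aiccs <= aiccs[i])
  }
  w <- rep(NA_real_, n_mod)
  w[retained] <- akaike_weights(aiccs[retained])
  tab <- data.frame(model = labels, k = vapply(fits, function(f) f$k_params, 1L),
                    loglik = vapply(fits, function(f) f$loglik, 1),
                    aicc = aiccs, delta_aicc = delta,
                    retained = retained, weight = w,
                    stringsAsFactors = FALSE)
  ord <- order(tab$aicc)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 fits = fits[ord],
                 best = fits[[which.min(aiccs)]],
                 global_spec = global_spec),
            class = "deer_candidates")
}

#' Standardized Akaike weights
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`, with deltas
#' recomputed within the supplied (retained) subset.
#'
#' @param aiccs AICc values of the retained models.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aiccs) {
  if (!length(aiccs)) stop_input("no models supplied")
  d <- aiccs - min(aiccs)
  e <- exp(-d / 2)
  e / sum(e)
}

#' Pairwise Pearson collinearity screen
#'
#' Expands factors to indicator columns, computes all pairwise Pearson
#' correlations on complete observations, and flags pairs with
#' `|r| >= threshold`. Indicator pairs from the same factor are skipped;
#' zero-variance covariates are reported as degenerate, not correlated. A
#' flagged pair blocks pipeline continuation unless overridden.
#'
#' @param data Data frame.
#' @param covariates Covariate column names.
#' @param threshold Absolute correlation flag threshold.
#' @return Object of class `deer_collinearity`: data frame of pairs with
#'   `r` and `flagged`, plus a `degenerate` attribute naming zero-variance
#'   columns.
#' @export
collinearity_screen <- function(data, covariates, threshold = 0.5) {
  cols <- list()
  origin <- character()
  for (v in covariates) {
    x <- data[[v]]
    if (is.null(x)) stop_input("covariate not found: ", v)
    if (is.character(x) || is.factor(x)) {
      f <- factor(x)
      if (nlevels(f) < 2L) {  # single-level factor: degenerate constant
        cols[[paste0(v, "=", levels(f))]] <- rep(1, length(f))
        origin <- c(origin, v)
        next
      }
      mm <- stats::model.matrix(~ f - 1)
      colnames(mm) <- paste0(v, "=", levels(f))
      for (j in seq_len(ncol(mm))) {
        cols[[colnames(mm)[j]]] <- mm[, j]
        origin <- c(origin, v)
      }
    } else {
      cols[[v]] <- as.numeric(x)
      origin <- c(origin, v)
    }
  }
  nm <- names(cols)
  if (length(cols) < 2L) stop_input("need at least two covariate columns to screen")
  degenerate <- nm[vapply(cols, function(x) stats::var(x, na.rm = TRUE) == 0,
                          logical(1L))]
  pairs <- utils::combn(seq_along(cols), 2L)
  rows <- list()
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    if (origin[i] == origin[j]) next  # indicators of the same factor
    xi <- cols[[i]]; xj <- cols[[j]]
    ok <- stats::complete.cases(xi, xj)
    if (sum(ok) < 3L) stop_input("fewer than 3 complete observations for ",
                                 nm[i], " vs ", nm[j])
    r <- if (nm[i] %in% degenerate || nm[j] %in% degenerate) {
      NA_real_
    } else {
      stats::cor(xi[ok], xj[ok])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      var1 = nm[i], var2 = nm[j], r = r,
      flagged = !is.na(r) && abs(r) >= threshold,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "degenerate") <- degenerate
  class(out) <- c("deer_collinearity", class(out))
  out
}

#' @exportS3Method base::print
print.deer_candidates <- function(x, ...) {
  cat("AICc model selection (", nrow(x$table), " candidates, ",
      sum(x$table$retained), " retained)\n", sep = "")
  tab <- x$table
  tab$loglik <- round(tab$loglik, 3)
  tab$aicc <- round(tab$aicc, 3)
  tab$delta_aicc <- round(tab$delta_aicc, 3)
  tab$weight <- round(tab$weight, 4)
  print.data.frame(utils::head(tab, 10), row.names = FALSE)
  if (nrow(tab) > 10) cat("  ... ", nrow(tab) - 10, " more\n")
  invisible(x)
}
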