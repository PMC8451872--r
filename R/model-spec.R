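# Model specification and design-matrix construction for the fitting engine.

FAMILY_LINKS <- c(gaussian = "identity", binomial = "logit",
                  negbin = "log", beta = "logit")

#' Specify a regression model
#'
#' A declarative description of one candidate model: response, family-link
#' pair, ordered fixed terms (main effects and `"a:b"` interactions obeying
#' marginality), optional random-intercept grouping factors, optional
#' per-observation weights, and factor reference levels.
#'
#' Only the four family-link pairs used by the analyses are admitted:
#' gaussian-identity, binomial-logit, negative-binomial-log, Beta-logit.
#'
#' @param response Response column name.
#' @param family One of `"gaussian"`, `"binomial"`, `"negbin"`, `"beta"`.
#' @param fixed Character vector of fixed terms; interactions are written
#'   `"a:b"` and require both main effects to be present.
#' @param random Character vector of grouping-factor column names (random
#'   intercepts only).
#' @param link Link name; defaults to the family's canonical choice and
#'   must match it.
#' @param weights Column name or numeric vector of positive observation
#'   weights (gaussian family only).
#' @param reference_levels Named list mapping factor columns to their
#'   reference level.
#' @return An object of class `deer_model_spec`.
#' @export
model_spec <- function(response,
                       family = c("gaussian", "binomial", "negbin", "beta"),
                       fixed = character(), random = character(),
                       link = NULL, weights = NULL,
                       reference_levels = list()) {
  family <- match.arg(family)
  link <- link %||% FAMILY_LINKS[[family]]
  if (!identical(link, FAMILY_LINKS[[family]])) {
    stop_input("family ", family, " is fitted with the ", FAMILY_LINKS[[family]],
               " link only")
  }
  fixed <- unique(as.character(fixed))
  check_marginality(fixed)
  structure(
    list(response = response, family = family, link = link,
         fixed = fixed, random = as.character(random),
         weights = weights, reference_levels = reference_levels),
    class = "deer_model_spec")
}

check_marginality <- function(fixed) {
  ints <- fixed[grepl(":", fixed, fixed = TRUE)]
  mains <- setdiff(fixed, ints)
  for (tm in ints) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    if (!all(parts %in% mains)) {
      stop_input("interaction ", tm, " requires main effects ",
                 paste(parts, collapse = " and "))
    }
  }
  invisible(fixed)
}

#' @exportS3Method base::print
print.deer_model_spec <- function(x, ...) {
  rhs <- if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1"
  cat(sprintf("Model spec: %s ~ %s [%s(%s)]\n", x$response, rhs, x$family, x$link))
  if (length(x$random)) cat("  random intercepts:", paste(x$random, collapse = ", "), "\n")
  invisible(x)
}

# Build response vector, design matrix, weights and term bookkeeping.
build_design <- function(spec, data) {
  if (!spec$response %in% names(data)) {
    stop_input("response column not found: ", spec$response)
  }
  vars <- unique(unlist(strsplit(spec$fixed, ":", fixed = TRUE)))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    stop_input("covariate column(s) not found: ", paste(missing_vars, collapse = ", "))
  }
  for (v in vars) {
    if (is.character(data[[v]]) || is.logical(data[[v]])) data[[v]] <- factor(data[[v]])
    ref <- spec$reference_levels[[v]]
    if (!is.null(ref)) data[[v]] <- stats::relevel(factor(data[[v]]), ref = ref)
  }
  fml <- if (length(spec$fixed)) stats::reformulate(spec$fixed) else ~1
  mf <- stats::model.frame(fml, data, na.action = stats::na.fail)
  X <- stats::model.matrix(fml, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_input("design matrix is rank deficient; aliased terms: ",
               paste(aliased, collapse = ", "))
  }
  y <- data[[spec$response]]
  w <- spec$weights
  if (is.character(w)) w <- data[[w]]
  if (is.null(w)) w <- rep(1, nrow(X))
  if (any(w <= 0) || anyNA(w)) stop_input("weights must be positive")
  term_of_col <- c("(Intercept)",
                   attr(stats::terms(fml), "term.labels"))[attr(X, "assign") + 1L]
  list(X = X, y = y, w = w, data = data, term_of_col = term_of_col)
}

check_response <- function(y, family) {
  switch(family,
    gaussian = {
      if (!is.numeric(y)) stop_input("gaussian response must be numeric")
    },
    binomial = {
      if (is.logical(y)) y <- as.numeric(y)
      if (!all(y %in% c(0, 1))) stop_input("binomial responses must be 0/1")
      if (length(unique(y)) < 2L) stop_input("binomial response is constant")
    },
    negbin = {
      if (any(y < 0) || any(y != round(y))) {
        stop_input("negative-binomial responses must be non-negative integers")
      }
      if (all(y == 0)) stop_input("all counts are zero; the mean is not estimable")
    },
    beta = {
      if (any(y < 0) || any(y > 1)) stop_input("beta responses must lie in [0, 1]")
      if (length(unique(y)) < 2L) stop_input("beta response is constant")
    })
  as.numeric(y)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`. Returns `Inf` (with a
#' warning) when `n <= k + 1`, where the correction is undefined.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters (fixed coefficients +
#'   random-effect variances + dispersion, where estimated).
#' @param n Number of observations.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) {
    warning("AICc undefined for n <= k + 1; returning Inf")
    return(Inf)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}
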