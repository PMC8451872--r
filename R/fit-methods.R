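# Accessors, confidence intervals and printing for fitted models.

#' Wald confidence intervals for the fixed coefficients
#'
#' `estimate +/- q(level) * SE` on the link scale; gaussian fits use t
#' quantiles with residual degrees of freedom, the other families use
#' normal quantiles. Each interval carries a flag recording whether it
#' excludes zero, the criterion used to assess predictor effects.
#'
#' @param fit A `deer_fit`.
#' @param level Confidence level.
#' @return Data frame with `term`, `estimate`, `se`, `ci_low`, `ci_high`,
#'   `excludes_zero`.
#' @export
wald_ci <- function(fit, level = 0.95) {
  se <- sqrt(diag(fit$vcov))
  if (any(!is.finite(se))) {
    stop_input("covariance matrix is not positive definite; no Wald intervals ",
               "(condition: non-finite standard errors)")
  }
  q <- if (!is.null(fit$df_resid)) {
    stats::qt(1 - (1 - level) / 2, df = fit$df_resid)
  } else {
    stats::qnorm(1 - (1 - level) / 2)
  }
  est <- fit$coefficients
  lo <- est - q * se
  hi <- est + q * se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             ci_low = unname(lo), ci_high = unname(hi),
             excludes_zero = unname(lo > 0 | hi < 0),
             stringsAsFactors = FALSE)
}

#' @exportS3Method base::print
print.deer_fit <- function(x, digits = 3, ...) {
  rhs <- if (length(x$spec$fixed)) paste(x$spec$fixed, collapse = " + ") else "1"
  cat(sprintf("%s(%s) fit: %s ~ %s\n", x$spec$family, x$spec$link,
              x$spec$response, rhs))
  if (length(x$random_variances)) {
    cat("  random-intercept variances:",
        paste(sprintf("%s = %.3f", names(x$random_variances),
                      x$random_variances), collapse = ", "), "\n")
  }
  ci <- x$ci
  cat(sprintf("  n = %d, logLik = %.3f, k = %d, AICc = %.3f%s\n",
              x$n_obs, x$loglik, x$k_params, x$aicc,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  for (i in seq_len(nrow(ci))) {
    cat(sprintf("  %-42s %8.*f  (%.*f; %.*f)%s\n", ci$term[i],
                digits, ci$estimate[i], digits, ci$ci_low[i],
                digits, ci$ci_high[i],
                if (ci$excludes_zero[i]) " *" else ""))
  }
  invisible(x)
}

#' @export
coef.deer_fit <- function(object, ...) object$coefficients

#' @export
vcov.deer_fit <- function(object, ...) object$vcov

#' @export
logLik.deer_fit <- function(object, ...) {
  structure(object$loglik, df = object$k_params, nobs = object$n_obs,
            class = "logLik")
}

# serialisable summary of a fit
fit_to_list <- function(fit) {
  list(response = fit$spec$response, family = fit$spec$family,
       link = fit$spec$link, fixed = as.list(fit$spec$fixed),
       random = as.list(fit$spec$random),
       coefficients = as.list(fit$coefficients),
       ci = fit$ci,
       random_variances = as.list(fit$random_variances),
       dispersion = as.list(fit$dispersion),
       loglik = fit$loglik, n_obs = fit$n_obs, k_params = fit$k_params,
       aicc = fit$aicc, converged = fit$converged)
}
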