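# Fixed-effect model fitting: weighted least squares and IRLS GLMs with
# profiled dispersion.

new_deer_fit <- function(spec, coefficients, vcov, random_variances, dispersion,
                         loglik, n_obs, k_params, converged,
                         df_resid = NULL, boundary = FALSE, fitted = NULL) {
  fit <- structure(
    list(spec = spec, coefficients = coefficients, vcov = vcov,
         random_variances = random_variances, dispersion = dispersion,
         loglik = loglik, n_obs = n_obs, k_params = k_params,
         aicc = aicc(loglik, k_params, n_obs), converged = converged,
         df_resid = df_resid, boundary = boundary, fitted = fitted),
    class = "deer_fit")
  fit$ci <- wald_ci(fit)
  fit
}

#' Fit a weighted Gaussian linear model
#'
#' Solves the weighted least-squares normal equations through a QR
#' decomposition of the square-root-weighted design; the log-likelihood is
#' the weighted Gaussian likelihood at the ML variance, and confidence
#' intervals use t quantiles with `n - p` degrees of freedom.
#'
#' @param spec A gaussian-family [model_spec()] (its `weights` entry names
#'   the weight column or supplies a numeric vector; omit for OLS).
#' @param data Data frame.
#' @return A `deer_fit`.
#' @export
fit_wls <- function(spec, data) {
  stopifnot(inherits(spec, "deer_model_spec"))
  if (spec$family != "gaussian") stop_input("fit_wls requires the gaussian family")
  d <- build_design(spec, data)
  y <- check_response(d$y, "gaussian")
  X <- d$X; w <- d$w
  n <- length(y); p <- ncol(X)
  sw <- sqrt(w)
  qr_fit <- qr(X * sw)
  beta <- qr.coef(qr_fit, y * sw)
  r <- y - drop(X %*% beta)
  rss_w <- sum(w * r^2)
  sigma2_ml <- rss_w / n
  loglik <- -0.5 * n * (log(2 * pi * sigma2_ml) + 1) + 0.5 * sum(log(w))
  s2 <- rss_w / (n - p)
  XtWX_inv <- chol2inv(qr.R(qr_fit))
  vcov <- s2 * XtWX_inv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  new_deer_fit(spec, coefficients = stats::setNames(beta, colnames(X)),
               vcov = vcov, random_variances = numeric(),
               dispersion = c(sigma2 = sigma2_ml),
               loglik = loglik, n_obs = n, k_params = p + 1L,
               converged = TRUE, df_resid = n - p,
               fitted = drop(X %*% beta))
}

#' Fit a fixed-effects GLM by iteratively reweighted least squares
#'
#' Binomial (logit), negative-binomial (log; NB2 variance `mu + mu^2/theta`)
#' or Beta (logit; precision phi) maximum likelihood. Coefficients are
#' updated by Fisher-scoring IRLS with step halving so the log-likelihood
#' never decreases across accepted iterations; the dispersion (theta or
#' phi) is profiled by univariate likelihood maximisation, alternating with
#' the coefficient updates until the relative log-likelihood change falls
#' below `tol`. Complete separation in a binomial fit is flagged by marking
#' the fit non-converged.
#'
#' @param spec A binomial, negbin or beta [model_spec()] without random
#'   terms (gaussian specs are delegated to [fit_wls()]).
#' @param data Data frame.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param maxit Maximum alternation iterations.
#' @param shrink Boundary handling for beta responses, see
#'   [shrink_proportions()].
#' @return A `deer_fit`.
#' @export
fit_glm <- function(spec, data, tol = 1e-10, maxit = 200L,
                    shrink = "boundary") {
  stopifnot(inherits(spec, "deer_model_spec"))
  if (spec$family == "gaussian") return(fit_wls(spec, data))
  if (length(spec$random)) stop_input("fit_glm does not take random terms; use fit_glmm")
  d <- build_design(spec, data)
  y <- check_response(d$y, spec$family)
  if (spec$family == "beta") y <- shrink_proportions(y, shrink)
  X <- d$X
  fam <- family_funs(spec$family)
  n <- length(y); p <- ncol(X)

  disp <- init_dispersion(spec$family, y)
  beta <- init_coefficients(spec$family, X, y, disp)
  eta <- drop(X %*% beta)
  ll <- fam$loglik(y, eta, disp)

  converged <- FALSE
  for (iter in seq_len(maxit)) {
    ll_prev <- ll
    up <- irls_step(X, y, beta, fam, disp)
    beta <- up$beta; eta <- up$eta; ll <- up$ll
    if (fam$has_disp) {
      prof <- stats::optimize(function(ld) fam$loglik(y, eta, exp(ld)),
                              interval = c(-7, 12), maximum = TRUE,
                              tol = 1e-10)
      disp <- exp(prof$maximum)
      ll <- prof$objective
    }
    if (abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-8)) {
      converged <- TRUE
      break
    }
  }
  if (spec$family == "binomial" && max(abs(drop(X %*% beta))) > 25) {
    warning("possible complete separation: coefficients diverging; fit marked non-converged")
    converged <- FALSE
  }

  W <- fam$hess(y, eta, disp)
  H <- crossprod(X, X * W)
  vcov <- tryCatch(solve(H), error = function(e) {
    warning("singular information matrix at the optimum")
    matrix(NA_real_, p, p)
  })
  dimnames(vcov) <- list(colnames(X), colnames(X))
  disp_out <- if (fam$has_disp) {
    stats::setNames(disp, if (spec$family == "negbin") "theta" else "phi")
  } else {
    numeric()
  }
  new_deer_fit(spec, coefficients = stats::setNames(beta, colnames(X)),
               vcov = vcov, random_variances = numeric(),
               dispersion = disp_out, loglik = ll, n_obs = n,
               k_params = p + as.integer(fam$has_disp),
               converged = converged, fitted = eta)
}

# One Fisher-scoring Newton update with step halving.
irls_step <- function(X, y, beta, fam, disp) {
  eta <- drop(X %*% beta)
  ll0 <- fam$loglik(y, eta, disp)
  g <- fam$grad(y, eta, disp)
  W <- fam$hess(y, eta, disp)
  H <- crossprod(X, X * W)
  delta <- tryCatch(solve(H, crossprod(X, g)), error = function(e) NULL)
  if (is.null(delta)) return(list(beta = beta, eta = eta, ll = ll0))
  step <- 1
  for (h in 1:30) {
    beta_new <- beta + step * drop(delta)
    eta_new <- drop(X %*% beta_new)
    ll_new <- fam$loglik(y, eta_new, disp)
    if (is.finite(ll_new) && ll_new >= ll0 - 1e-12) {
      return(list(beta = beta_new, eta = eta_new, ll = ll_new))
    }
    step <- step / 2
  }
  list(beta = beta, eta = eta, ll = ll0)
}

init_dispersion <- function(family, y) {
  switch(family,
    binomial = NULL,
    negbin = {
      m <- mean(y); v <- stats::var(y)
      if (is.na(v) || v <= m) 100 else min(max(m^2 / (v - m), 0.1), 1e4)
    },
    beta = {
      m <- mean(y); v <- stats::var(y)
      if (is.na(v) || v <= 0) 10 else max(m * (1 - m) / v - 1, 0.5)
    })
}

init_coefficients <- function(family, X, y, disp) {
  z <- switch(family,
    binomial = stats::qlogis((y * (length(y) - 1) + 0.5) / length(y)),
    negbin = log(y + 0.5),
    beta = stats::qlogis(squeeze_unit(y, 1e-4)))
  qr.coef(qr(X), z)
}
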