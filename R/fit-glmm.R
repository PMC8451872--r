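# Random-intercept GLMMs via the Laplace approximation.
#
# The marginal likelihood is approximated by maximising the joint
# log-density over the random effects (a penalised Newton step on the
# sparse indicator design) and applying the curvature correction
#   l(beta, sigma, disp) ~ l_joint(u_hat) - sum(log sigma_j) - 0.5 log|H|,
# with H = Z'WZ + D^-1 the negative joint Hessian in u. Fixed effects,
# random-intercept SDs and the dispersion are then maximised over this
# approximated likelihood from a deterministic starting point (the GLM fit,
# variances 0.1), so fits are bit-reproducible.

#' Fit a random-intercept GLMM by the Laplace approximation
#'
#' Supports binomial (logit), negative-binomial (log) and Beta (logit)
#' responses with one or more crossed random intercepts. Optimisation is
#' two-staged: the variance (and dispersion) parameters are first optimised
#' with the fixed effects profiled at the joint mode, then all parameters
#' are refined jointly on the full Laplace objective by BFGS. A
#' random-effect SD collapsing to zero is a boundary fit: the variance is
#' recorded as 0 and removed from the parameter count.
#'
#' @param spec A [model_spec()] with at least one random grouping factor.
#' @param data Data frame; random-factor columns must have >= 2 levels.
#' @param fix_sd Optional named numeric of random-effect SDs to hold fixed
#'   (e.g. `c(plot_id = 0)` reduces the model to the fixed-effect GLM).
#' @param start_sd Starting SD for free random effects.
#' @param shrink Boundary handling for beta responses.
#' @param outer_maxit Iteration cap for each outer optimiser stage.
#' @return A `deer_fit` with `random_variances` filled in.
#' @export
fit_glmm <- function(spec, data, fix_sd = NULL, start_sd = sqrt(0.1),
                     shrink = "boundary", outer_maxit = 500L) {
  stopifnot(inherits(spec, "deer_model_spec"))
  if (!length(spec$random)) stop_input("fit_glmm needs at least one random term")
  if (spec$family == "gaussian") {
    stop_input("gaussian mixed models are not part of this engine")
  }
  d <- build_design(spec, data)
  y <- check_response(d$y, spec$family)
  if (spec$family == "beta") y <- shrink_proportions(y, shrink)
  X <- d$X
  fam <- family_funs(spec$family)
  n <- length(y); p <- ncol(X)

  factors <- lapply(spec$random, function(rf) {
    if (!rf %in% names(data)) stop_input("random factor not found: ", rf)
    f <- factor(data[[rf]])
    if (nlevels(f) < 2L) stop_input("random factor ", rf, " needs >= 2 levels")
    f
  })
  names(factors) <- spec$random

  # fixed-effect GLM supplies deterministic starts
  glm_spec <- spec; glm_spec$random <- character()
  glm_fit <- fit_glm(glm_spec, data, shrink = shrink)
  beta0 <- glm_fit$coefficients
  disp0 <- if (fam$has_disp) unname(glm_fit$dispersion) else NULL

  sd_fixed <- rep(NA_real_, length(factors))
  names(sd_fixed) <- names(factors)
  if (!is.null(fix_sd)) sd_fixed[names(fix_sd)] <- fix_sd
  free <- is.na(sd_fixed)

  build_blocks <- function(active) {
    # active: logical over factors; returns Z, per-element block id
    qs <- vapply(factors[active], nlevels, 1L)
    if (!length(qs) || sum(qs) == 0L) {
      return(list(Z = NULL, block = integer(), q = 0L, active = active))
    }
    offs <- c(0L, cumsum(qs))[seq_along(qs)]
    ii <- rep(seq_len(n), sum(active))
    jj <- unlist(mapply(function(f, o) as.integer(f) + o,
                        factors[active], offs, SIMPLIFY = FALSE))
    Z <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                              dims = c(n, sum(qs)))
    list(Z = Z, block = rep(seq_along(qs), qs), q = sum(qs), active = active)
  }

  # Laplace log-likelihood with random effects profiled at their mode.
  # If `profile_beta`, beta is profiled at the joint mode as well (stage A).
  laplace_ll <- function(beta, sds_active, disp, bl, cache, profile_beta = FALSE) {
    if (bl$q == 0L) {
      eta <- drop(X %*% beta)
      return(list(ll = fam$loglik(y, eta, disp), beta = beta,
                  u = numeric(), eta = eta))
    }
    pen <- 1 / pmax(sds_active, 1e-6)[bl$block]^2
    Z <- bl$Z
    u <- cache$u
    if (is.null(u) || length(u) != bl$q) u <- numeric(bl$q)
    b <- beta
    for (it in 1:60) {
      eta <- drop(X %*% b) + as.numeric(Z %*% u)
      g <- fam$grad(y, eta, disp)
      W <- fam$hess(y, eta, disp)
      jll0 <- fam$loglik(y, eta, disp) - 0.5 * sum(pen * u^2)
      if (profile_beta) {
        ZW <- Z * W
        Huu <- as.matrix(Matrix::crossprod(Z, ZW)); diag(Huu) <- diag(Huu) + pen
        Hbb <- crossprod(X, X * W)
        Hbu <- as.matrix(Matrix::crossprod(Matrix::Matrix(X * W, sparse = TRUE), Z))
        H <- rbind(cbind(Hbb, Hbu), cbind(t(Hbu), Huu))
        grad <- c(drop(crossprod(X, g)), as.numeric(Matrix::crossprod(Z, g)) - pen * u)
      } else {
        ZW <- Z * W
        H <- as.matrix(Matrix::crossprod(Z, ZW)); diag(H) <- diag(H) + pen
        grad <- as.numeric(Matrix::crossprod(Z, g)) - pen * u
      }
      R <- tryCatch(chol(H), error = function(e) chol(H + diag(1e-8, nrow(H))))
      delta <- backsolve(R, backsolve(R, grad, transpose = TRUE))
      step <- 1; jll_new <- -Inf
      for (h in 1:30) {
        if (profile_beta) {
          b_try <- b + step * delta[seq_len(p)]
          u_try <- u + step * delta[-seq_len(p)]
        } else {
          b_try <- b
          u_try <- u + step * delta
        }
        eta_try <- drop(X %*% b_try) + as.numeric(Z %*% u_try)
        jll_new <- fam$loglik(y, eta_try, disp) - 0.5 * sum(pen * u_try^2)
        if (is.finite(jll_new) && jll_new >= jll0 - 1e-12) break
        step <- step / 2
      }
      if (!is.finite(jll_new) || jll_new < jll0 - 1e-12) break
      moved <- max(abs(c(if (profile_beta) b_try - b else 0, u_try - u)))
      b <- b_try; u <- u_try
      if (moved < 1e-10 || abs(jll_new - jll0) < 1e-12 * (abs(jll0) + 1)) break
    }
    cache$u <- u
    eta <- drop(X %*% b) + as.numeric(Z %*% u)
    W <- fam$hess(y, eta, disp)
    Huu <- as.matrix(Matrix::crossprod(Z, Z * W)); diag(Huu) <- diag(Huu) + pen
    R <- tryCatch(chol(Huu), error = function(e) chol(Huu + diag(1e-8, nrow(Huu))))
    logdet <- 2 * sum(log(diag(R)))
    jll <- fam$loglik(y, eta, disp) - 0.5 * sum(pen * u^2)
    ll <- jll - sum(log(pmax(sds_active, 1e-6)[bl$block])) - 0.5 * logdet
    list(ll = ll, beta = b, u = u, eta = eta)
  }

  # ---- stage A: variances (and dispersion) with beta profiled ----
  sds <- ifelse(free, start_sd, sd_fixed)
  active <- sds > 0 | free
  bl <- build_blocks(active)
  cacheA <- new.env(parent = emptyenv())
  n_free <- sum(free)
  objA <- function(th) {
    sds_all <- sds
    sds_all[free] <- abs(th[seq_len(n_free)])
    disp <- if (fam$has_disp) exp(th[n_free + 1L]) else NULL
    res <- laplace_ll(beta0, sds_all[bl$active], disp, bl, cacheA,
                      profile_beta = TRUE)
    if (!is.finite(res$ll)) return(1e10)
    -res$ll
  }
  thA <- c(sds[free], if (fam$has_disp) log(disp0))
  if (length(thA)) {
    if (length(thA) == 1L) {
      bounds <- if (n_free == 1L) c(0, 10) else c(-7, 12)
      opt <- stats::optim(thA, objA, method = "Brent",
                          lower = bounds[1L], upper = bounds[2L],
                          control = list(maxit = outer_maxit))
      thA <- opt$par
    } else {
      opt <- stats::optim(thA, objA, method = "Nelder-Mead",
                          control = list(maxit = outer_maxit, reltol = 1e-9))
      thA <- opt$par
    }
  }
  sds[free] <- abs(thA[seq_len(n_free)])
  if (fam$has_disp && length(thA) > n_free) disp0 <- exp(thA[n_free + 1L])

  # boundary detection: free SDs that collapsed are fixed at zero
  boundary <- free & sds < 1e-3
  if (any(boundary)) {
    sds[boundary] <- 0
    free[boundary] <- FALSE
  }
  active <- sds > 0
  bl <- build_blocks(active)
  n_free <- sum(free)

  # ---- stage B: full Laplace objective over (beta, free SDs, dispersion) ----
  cacheB <- new.env(parent = emptyenv())
  betaA <- laplace_ll(beta0, sds[bl$active], disp0, bl, cacheA,
                      profile_beta = TRUE)$beta
  unpack <- function(par) {
    list(beta = par[seq_len(p)],
         sds = {
           s <- sds
           if (n_free) s[free] <- abs(par[p + seq_len(n_free)])
           s
         },
         disp = if (fam$has_disp) exp(par[p + n_free + 1L]) else NULL)
  }
  objB <- function(par) {
    pp <- unpack(par)
    res <- laplace_ll(pp$beta, pp$sds[bl$active], pp$disp, bl, cacheB)
    if (!is.finite(res$ll)) return(1e10)
    -res$ll
  }
  parB <- c(betaA, if (n_free) sds[free], if (fam$has_disp) log(disp0))
  optB <- stats::optim(parB, objB, method = "BFGS",
                       control = list(maxit = outer_maxit, reltol = 1e-12))
  # polish: a short Nelder-Mead pass guards against poor BFGS line searches
  optB2 <- stats::optim(optB$par, objB, method = "Nelder-Mead",
                        control = list(maxit = 400L, reltol = 1e-12))
  # converged if BFGS reported success or the polish found nothing material
  outer_converged <- optB$convergence == 0 || optB$value - optB2$value < 1e-4
  if (optB2$value < optB$value) optB <- optB2
  hess <- stats::optimHess(optB$par, objB)

  pp <- unpack(optB$par)
  sds <- pp$sds
  final <- laplace_ll(pp$beta, sds[bl$active], pp$disp, bl, cacheB)
  loglik <- final$ll
  beta_hat <- stats::setNames(pp$beta, colnames(X))

  vcov <- tryCatch({
    V <- solve(hess)
    Vb <- V[seq_len(p), seq_len(p), drop = FALSE]
    if (any(!is.finite(diag(Vb))) || any(diag(Vb) <= 0)) stop("bad")
    Vb
  }, error = function(e) {
    # conditional fallback: information of beta at the random-effect mode
    W <- fam$hess(y, final$eta, pp$disp)
    solve(crossprod(X, X * W))
  })
  dimnames(vcov) <- list(colnames(X), colnames(X))

  disp_out <- if (fam$has_disp) {
    stats::setNames(pp$disp, if (spec$family == "negbin") "theta" else "phi")
  } else {
    numeric()
  }
  k <- p + n_free + as.integer(fam$has_disp)
  fit <- new_deer_fit(spec, coefficients = beta_hat, vcov = vcov,
                      random_variances = stats::setNames(sds^2, names(factors)),
                      dispersion = disp_out, loglik = loglik, n_obs = n,
                      k_params = k, converged = outer_converged,
                      boundary = any(boundary), fitted = final$eta)
  fit$ranef <- final$u
  fit
}

#' Fit any model specification
#'
#' Dispatches to [fit_wls()] (gaussian), [fit_glmm()] (random terms
#' present) or [fit_glm()].
#'
#' @param spec A [model_spec()].
#' @param data Data frame.
#' @param ... Passed to the underlying fitter.
#' @return A `deer_fit`.
#' @export
fit_model <- function(spec, data, ...) {
  if (spec$family == "gaussian") {
    fit_wls(spec, data)
  } else if (length(spec$random)) {
    fit_glmm(spec, data, ...)
  } else {
    fit_glm(spec, data, ...)
  }
}
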