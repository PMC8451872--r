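# The model-fitting engine: WLS, IRLS GLMs, Laplace GLMMs, Wald intervals.

test_that("weighted least squares solves the normal equations", {
  d <- data.frame(x = c(0, 1, 2), y = c(1, 2, 2), w = c(1, 1, 4))
  fit <- fit_wls(model_spec("y", "gaussian", fixed = "x", weights = "w"), d)
  # independent closed-form normal-equation solution
  X <- cbind(1, d$x); W <- diag(d$w)
  beta_hand <- drop(solve(t(X) %*% W %*% X, t(X) %*% W %*% d$y))
  expect_equal(unname(coef(fit)), beta_hand, tolerance = 1e-12)

  # exact fit: y = 2x with arbitrary positive weights
  d2 <- data.frame(x = 1:6, y = 2 * (1:6), w = c(1, 3, 2, 5, 1, 2))
  fit2 <- fit_wls(model_spec("y", "gaussian", fixed = "x", weights = "w"), d2)
  expect_equal(unname(coef(fit2)), c(0, 2), tolerance = 1e-10)
})

test_that("unit-weight WLS equals ordinary least squares", {
  set.seed(5)
  d <- data.frame(x = rnorm(30), z = rnorm(30))
  d$y <- 1 + 0.5 * d$x - 0.2 * d$z + rnorm(30)
  fit <- fit_wls(model_spec("y", "gaussian", fixed = c("x", "z")), d)
  ref <- stats::lm(y ~ x + z, d)
  expect_equal(coef(fit), coef(ref), tolerance = 1e-10)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$ci$ci_low), unname(stats::confint(ref)[, 1]),
               tolerance = 1e-8)
})

test_that("intercept-only GLMs match their closed forms", {
  db <- data.frame(y = c(rep(1L, 7), rep(0L, 3)))
  fb <- fit_glm(model_spec("y", "binomial"), db)
  expect_equal(unname(coef(fb)), log(7 / 3), tolerance = 1e-8)

  dn <- data.frame(y = 0:4)
  fn <- fit_glm(model_spec("y", "negbin"), dn)
  expect_equal(unname(coef(fn)), log(2), tolerance = 1e-7)
})

test_that("binomial and negbin fits agree with stats::glm and MASS::glm.nb", {
  set.seed(8)
  n <- 150
  d <- data.frame(x = rnorm(n), f = factor(sample(c("a", "b"), n, TRUE)))
  d$y <- rbinom(n, 1, plogis(-0.3 + 0.8 * d$x + 0.5 * (d$f == "b")))
  fit <- fit_glm(model_spec("y", "binomial", fixed = c("x", "f")), d)
  ref <- stats::glm(y ~ x + f, d, family = stats::binomial())
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-8)

  d$cnt <- rnbinom(n, size = 2, mu = exp(0.5 + 0.4 * d$x))
  fitnb <- fit_glm(model_spec("cnt", "negbin", fixed = "x"), d)
  refnb <- MASS::glm.nb(cnt ~ x, d)
  expect_equal(unname(coef(fitnb)), unname(coef(refnb)), tolerance = 1e-5)
  expect_equal(unname(fitnb$dispersion), refnb$theta, tolerance = 1e-3)
})

test_that("beta regression maximises the Beta likelihood", {
  set.seed(9)
  n <- 120
  d <- data.frame(x = runif(n))
  mu <- plogis(-1 + 2 * d$x)
  d$y <- rbeta(n, mu * 15, (1 - mu) * 15)
  fit <- fit_glm(model_spec("y", "beta", fixed = "x"), d)
  # independent generic-optimizer oracle on the same likelihood
  nll <- function(par) {
    m <- plogis(par[1] + par[2] * d$x); phi <- exp(par[3])
    -sum(stats::dbeta(d$y, m * phi, (1 - m) * phi, log = TRUE))
  }
  opt <- stats::optim(c(0, 0, 1), nll, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  expect_lt(abs(fit$loglik - (-opt$value)), 1e-6)
  expect_equal(unname(coef(fit)), opt$par[1:2], tolerance = 1e-4)
})

test_that("boundary proportions are shrunk before beta fitting", {
  y <- c(0, 0.2, 0.7, 1)
  s <- shrink_proportions(y)
  expect_true(all(s > 0 & s < 1))
  expect_equal(s[2:3], y[2:3])   # interior values untouched
  expect_equal(s[1], 0.5 / 4)
  expect_identical(shrink_proportions(y, "none"), y)
})

test_that("each family's fitted log-likelihood beats the null model", {
  set.seed(10)
  n <- 100
  d <- data.frame(x = rnorm(n), w = runif(n, 0.5, 2))
  d$yg <- 1 + 0.7 * d$x + rnorm(n)
  d$yb <- rbinom(n, 1, plogis(0.9 * d$x))
  d$yc <- rnbinom(n, size = 1.5, mu = exp(0.5 + 0.5 * d$x))
  d$yp <- rbeta(n, plogis(0.8 * d$x) * 10, (1 - plogis(0.8 * d$x)) * 10)
  cases <- list(
    list(resp = "yg", fam = "gaussian", w = "w"),
    list(resp = "yb", fam = "binomial", w = NULL),
    list(resp = "yc", fam = "negbin", w = NULL),
    list(resp = "yp", fam = "beta", w = NULL))
  for (cs in cases) {
    full <- fit_model(model_spec(cs$resp, cs$fam, fixed = "x", weights = cs$w), d)
    null <- fit_model(model_spec(cs$resp, cs$fam, weights = cs$w), d)
    expect_gte(full$loglik, null$loglik)
  }
})

test_that("negbin with huge theta reproduces Poisson coefficients", {
  set.seed(11)
  # underdispersed counts push the ML shape to its upper limit, where the
  # NB2 likelihood collapses onto the Poisson one
  d <- data.frame(x = rnorm(200))
  d$y <- rbinom(200, 8, plogis(d$x - 1))
  fit <- fit_glm(model_spec("y", "negbin", fixed = "x"), d)
  ref <- stats::glm(y ~ x, d, family = stats::poisson())
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-3)
  expect_gt(unname(fit$dispersion), 1e4)
})

test_that("complete separation is flagged as non-converged", {
  d <- data.frame(x = c(-2, -1, -0.5, 0.5, 1, 2),
                  y = c(0, 0, 0, 1, 1, 1))
  expect_warning(fit <- fit_glm(model_spec("y", "binomial", fixed = "x"), d),
                 "separation")
  expect_false(fit$converged)
  expect_error(fit_glm(model_spec("y", "binomial"),
                       data.frame(y = rep(1L, 10))), "constant")
})

test_that("design-matrix contracts are enforced", {
  d <- data.frame(a = 1:6, b = 2 * (1:6), y = rnorm(6))
  expect_error(fit_wls(model_spec("y", "gaussian", fixed = c("a", "b")), d),
               "rank deficient")
  expect_error(model_spec("y", "binomial", fixed = "a:b"), "requires main")
  expect_error(model_spec("y", "binomial", link = "log"), "logit")
})

test_that("the AICc correction vanishes for large n", {
  expect_lt(abs(aicc(0, 5, 1e6) - (2 * 5)), 1e-4)
  expect_equal(aicc(-10, 3, 20), 20 + 6 + 2 * 3 * 4 / 16)
  expect_warning(expect_equal(aicc(0, 5, 6), Inf), "undefined")
})

test_that("Wald intervals reconstruct printed coefficient tables", {
  fit <- fit_shell(fixed = "x", aicc_value = 0,
                   estimate = c(x = -0.326), se = 0.1474)
  ci <- wald_ci(fit)
  expect_equal(c(ci$ci_low, ci$ci_high), c(-0.615, -0.037), tolerance = 1e-3)
  expect_true(ci$excludes_zero)

  fit2 <- fit_shell(fixed = "x", aicc_value = 0,
                    estimate = c(x = 0.181), se = (1.297 - 0.181) / qnorm(0.975))
  ci2 <- wald_ci(fit2)
  expect_equal(c(ci2$ci_low, ci2$ci_high), c(-0.935, 1.297), tolerance = 1e-3)
  expect_false(ci2$excludes_zero)

  # zero-SE limit collapses to the estimate
  fit3 <- fit_shell(fixed = "x", aicc_value = 0, estimate = c(x = 1.5), se = 0)
  ci3 <- wald_ci(fit3)
  expect_equal(c(ci3$ci_low, ci3$ci_high), c(1.5, 1.5))
})

test_that("the Laplace GLMM degenerates to the GLM at zero variance", {
  set.seed(13)
  n <- 120
  d <- data.frame(x = rnorm(n), g = factor(rep(1:12, each = 10)))
  d$y <- rbinom(n, 1, plogis(0.3 - 0.5 * d$x))
  glmm <- fit_glmm(model_spec("y", "binomial", fixed = "x", random = "g"), d,
                   fix_sd = c(g = 0))
  glm_fit <- fit_glm(model_spec("y", "binomial", fixed = "x"), d)
  expect_equal(coef(glmm), coef(glm_fit), tolerance = 1e-6)
  expect_lt(abs(glmm$loglik - glm_fit$loglik), 1e-6)
  expect_equal(unname(glmm$random_variances), 0)
})

test_that("binomial GLMM matches lme4 on a common dataset", {
  skip_if_not_installed("lme4")
  set.seed(14)
  ng <- 30; m <- 15
  g <- factor(rep(seq_len(ng), each = m))
  u <- rnorm(ng, 0, 0.8)
  x <- rnorm(ng * m)
  d <- data.frame(x = x, g = g,
                  y = rbinom(ng * m, 1, plogis(0.4 - 0.4 * x + u[g])))
  fit <- fit_glmm(model_spec("y", "binomial", fixed = "x", random = "g"), d)
  ref <- lme4::glmer(y ~ x + (1 | g), d, family = stats::binomial())
  expect_equal(unname(coef(fit)), unname(lme4::fixef(ref)), tolerance = 1e-3)
  expect_equal(unname(fit$random_variances),
               as.numeric(lme4::VarCorr(ref)$g), tolerance = 1e-2)
  expect_lt(abs(fit$loglik - as.numeric(stats::logLik(ref))), 1e-3)
})

test_that("crossed-intercept negbin GLMM matches glmmTMB", {
  skip_if_not_installed("glmmTMB")
  set.seed(15)
  np <- 40; ny <- 5
  d <- expand.grid(plot = factor(sprintf("p%02d", seq_len(np))),
                   yr = factor(seq_len(ny)))
  up <- rnorm(np, 0, 0.6); uy <- rnorm(ny, 0, 0.3)
  d$x <- rpois(nrow(d), 2)
  d$y <- rnbinom(nrow(d), size = 1.5,
                 mu = exp(-0.2 - 0.25 * d$x + up[d$plot] + uy[d$yr]))
  fit <- fit_glmm(model_spec("y", "negbin", fixed = "x",
                             random = c("plot", "yr")), d)
  ref <- glmmTMB::glmmTMB(y ~ x + (1 | plot) + (1 | yr), d,
                          family = glmmTMB::nbinom2)
  expect_equal(unname(coef(fit)), unname(glmmTMB::fixef(ref)$cond),
               tolerance = 1e-3)
  expect_lt(abs(fit$loglik - as.numeric(stats::logLik(ref))), 1e-3)
  expect_equal(unname(fit$dispersion), glmmTMB::sigma(ref), tolerance = 1e-2)
})
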