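# Link-scale log-likelihoods and derivatives for the fitting engine.
#
# Each family exposes: loglik(y, eta, disp), grad(y, eta, disp) = d l/d eta,
# and hess(y, eta, disp) = -d2 l/d eta2 (observed for negbin, which equals
# the expected information for the canonical binomial-logit pair; expected
# information for beta). disp is theta (negbin shape) or phi (beta
# precision); unused for binomial.

ETA_CLAMP <- 30

clamp_eta <- function(eta) pmin(pmax(eta, -ETA_CLAMP), ETA_CLAMP)

family_funs <- function(family) {
  switch(family,
    binomial = list(
      loglik = function(y, eta, disp = NULL) {
        sum(stats::dbinom(y, 1, stats::plogis(clamp_eta(eta)), log = TRUE))
      },
      grad = function(y, eta, disp = NULL) y - stats::plogis(clamp_eta(eta)),
      hess = function(y, eta, disp = NULL) {
        mu <- stats::plogis(clamp_eta(eta))
        pmax(mu * (1 - mu), 1e-10)
      },
      has_disp = FALSE),
    negbin = list(
      loglik = function(y, eta, disp) {
        sum(stats::dnbinom(y, size = disp, mu = exp(clamp_eta(eta)), log = TRUE))
      },
      grad = function(y, eta, disp) {
        mu <- exp(clamp_eta(eta))
        y - mu * (y + disp) / (mu + disp)
      },
      hess = function(y, eta, disp) {
        mu <- exp(clamp_eta(eta))
        pmax((y + disp) * disp * mu / (mu + disp)^2, 1e-10)
      },
      has_disp = TRUE),
    beta = list(
      loglik = function(y, eta, disp) {
        mu <- squeeze_unit(stats::plogis(clamp_eta(eta)))
        sum(stats::dbeta(y, mu * disp, (1 - mu) * disp, log = TRUE))
      },
      grad = function(y, eta, disp) {
        mu <- squeeze_unit(stats::plogis(clamp_eta(eta)))
        ystar <- stats::qlogis(y)
        mustar <- digamma(mu * disp) - digamma((1 - mu) * disp)
        disp * (ystar - mustar) * mu * (1 - mu)
      },
      hess = function(y, eta, disp) {
        mu <- squeeze_unit(stats::plogis(clamp_eta(eta)))
        v <- trigamma(mu * disp) + trigamma((1 - mu) * disp)
        pmax(disp^2 * v * (mu * (1 - mu))^2, 1e-10)
      },
      has_disp = TRUE),
    stop_input("unsupported family: ", family))
}

squeeze_unit <- function(mu, eps = 1e-10) pmin(pmax(mu, eps), 1 - eps)

#' Shrink boundary proportions into the open unit interval
#'
#' Proportions exactly 0 or 1 make the Beta likelihood undefined; affected
#' values are replaced by `(y * (n - 1) + 0.5) / n` while interior values
#' are left untouched (set `which = "all"` to transform every value).
#'
#' @param y Proportions in \[0, 1\].
#' @param which `"boundary"` (default), `"all"`, or `"none"`.
#' @return Shrunk proportions strictly inside (0, 1).
#' @export
shrink_proportions <- function(y, which = c("boundary", "all", "none")) {
  which <- match.arg(which)
  if (which == "none") return(y)
  n <- length(y)
  shrunk <- (y * (n - 1) + 0.5) / n
  if (which == "all") shrunk else ifelse(y <= 0 | y >= 1, shrunk, y)
}
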