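# Bernoulli likelihood calculus on a Fourier design matrix.
# All three derivatives use the linear predictor eta = D %*% theta and the
# stable identities log(1+e^eta) = max(eta,0) + log1p(e^{-|eta|}) and
# pi = plogis(eta); probabilities are clamped into the open unit interval so
# downstream logs and weights stay finite even under quasi-separation.

log1pexp <- function(eta) pmax(eta, 0) + log1p(exp(-abs(eta)))

.check_theta_dim <- function(design, theta) {
  if (length(theta) != ncol(design)) {
    stop(sprintf("theta has length %d but the design has %d columns",
                 length(theta), ncol(design)))
  }
}

.check_response <- function(y, design) {
  if (length(y) != nrow(design)) {
    stop(sprintf("response has length %d but the design has %d rows",
                 length(y), nrow(design)))
  }
  if (!all(y %in% c(0, 1))) stop("response must contain only 0 and 1")
}

#' Success probabilities under the Fourier-series logistic model
#'
#' Evaluates `pi_i = exp(eta_i) / (1 + exp(eta_i))` with
#' `eta = design %*% theta`.  The computation is overflow-safe for linear
#' predictors of any magnitude, and the result is clamped into the open
#' interval (0, 1) so that weights `pi (1 - pi)` and log terms never hit an
#' exact 0 or 1.
#'
#' @param design design matrix from [fourier_design()].
#' @param theta flat coefficient vector, length `ncol(design)`.
#' @return numeric vector of probabilities, strictly inside (0, 1).
#' @export
predict_prob <- function(design, theta) {
  .check_theta_dim(design, theta)
  eta <- drop(design %*% theta)
  p <- stats::plogis(eta)
  pmin(pmax(p, 1e-300), 1 - .Machine$double.eps / 2)
}

#' Bernoulli log-likelihood, score and observed Hessian
#'
#' The log-likelihood of a binary response under the logistic model is
#' `sum(y * eta - log(1 + exp(eta)))`; its gradient (score) is
#' `t(design) %*% (y - pi)` and its Hessian is
#' `-t(design) %*% diag(pi (1 - pi)) %*% design`, the negative observed
#' information.  These are the exact analytic derivatives used by the
#' Newton-Raphson fitter and by the Wald variance estimates.
#'
#' @param y binary 0/1 response vector.
#' @param design design matrix from [fourier_design()].
#' @param theta flat coefficient vector, length `ncol(design)`.
#' @return `loglik_bernoulli()`: a scalar (always <= 0);
#'   `score_bernoulli()`: a named vector of length `ncol(design)`;
#'   `hessian_bernoulli()`: a symmetric negative-semidefinite matrix.
#' @export
loglik_bernoulli <- function(y, design, theta) {
  .check_theta_dim(design, theta)
  .check_response(y, design)
  eta <- drop(design %*% theta)
  sum(y * eta - log1pexp(eta))
}

#' @rdname loglik_bernoulli
#' @export
score_bernoulli <- function(y, design, theta) {
  .check_theta_dim(design, theta)
  .check_response(y, design)
  p <- predict_prob(design, theta)
  drop(crossprod(design, y - p))
}

#' @rdname loglik_bernoulli
#' @export
hessian_bernoulli <- function(y, design, theta) {
  .check_theta_dim(design, theta)
  .check_response(y, design)
  p <- predict_prob(design, theta)
  w <- p * (1 - p)
  H <- -crossprod(design, design * w)
  (H + t(H)) / 2  # enforce exact symmetry against rounding
}
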