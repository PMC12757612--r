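#' Simultaneous likelihood-ratio test of all regression parameters
#'
#' Tests the null hypothesis that every linear slope `b_j` and every cosine
#' coefficient `a_kj` is zero (the intercept-only model) against the fitted
#' full model.  The statistic is `G2 = 2 [L(theta_full) - L(theta_null)]`,
#' which under the null is asymptotically chi-square with degrees of freedom
#' equal to the number of constrained (non-intercept) parameters,
#' `p + sum(K)`; when all predictors share a common order `K` this is the
#' familiar `p (K + 1)`.  The null is rejected when `G2` exceeds the upper
#' `alpha` chi-square quantile.
#'
#' @param fit_full a converged fitted `"fsnblr"` model.
#' @param fit_null the nested null fit on the same data; defaults to the
#'   intercept-only model, re-estimated on `fit_full$y`.
#' @param alpha significance level (default 0.05).
#' @return an object of class `"fsnblr_lrt"`: list with `G2`, `df`,
#'   `p_value`, `critical_value`, `alpha`, `reject`, and the two
#'   log-likelihoods.
#' @examples
#' sc <- fsnblr_scenario("strong_cosine", n = 300, seed = 2)
#' fit <- fsnblr(y ~ x1 + x2, data = sc$data, K = c(2, 1))
#' lrt(fit)
#' @export
lrt <- function(fit_full, fit_null = NULL, alpha = 0.05) {
  stopifnot(inherits(fit_full, "fsnblr"))
  if (is.null(fit_null)) {
    fit_null <- fsnblr_fit(fit_full$y, NULL, control = fit_full$control)
  }
  stopifnot(inherits(fit_null, "fsnblr"))
  if (fit_full$nobs != fit_null$nobs || !isTRUE(all.equal(fit_full$y, fit_null$y))) {
    stop("the two fits are not on the same data")
  }
  if (fit_null$df > fit_full$df) stop("fit_null must be nested in fit_full")
  if (fit_null$loglik > fit_full$loglik + 1e-8) {
    stop("null log-likelihood exceeds full log-likelihood: optimizer failure")
  }
  G2 <- 2 * (fit_full$loglik - fit_null$loglik)
  df <- fit_full$df - fit_null$df
  if (df == 0L) {
    # degenerate comparison of a model with itself: never rejects
    return(structure(list(G2 = G2, df = 0L, p_value = 1, critical_value = 0,
                          alpha = alpha, reject = FALSE,
                          loglik_full = fit_full$loglik,
                          loglik_null = fit_null$loglik),
                     class = "fsnblr_lrt"))
  }
  crit <- stats::qchisq(1 - alpha, df)
  p <- stats::pchisq(G2, df, lower.tail = FALSE)
  structure(list(G2 = G2, df = df, p_value = p, critical_value = crit,
                 alpha = alpha, reject = G2 > crit,
                 loglik_full = fit_full$loglik, loglik_null = fit_null$loglik),
            class = "fsnblr_lrt")
}

#' @export
print.fsnblr_lrt <- function(x, ...) {
  cat("Simultaneous likelihood-ratio test\n")
  cat(sprintf("  G2 = %.4f, df = %d, p = %.4g\n", x$G2, x$df, x$p_value))
  cat(sprintf("  critical value (alpha = %g): %.4f -> %s\n", x$alpha,
              x$critical_value, ifelse(x$reject, "reject H0", "fail to reject H0")))
  invisible(x)
}

#' Per-parameter Wald tests
#'
#' For every coefficient (including the intercept) computes the Wald
#' statistic `z = estimate / se`, where the standard error is the square
#' root of the corresponding diagonal element of the inverse observed
#' information `-solve(H(theta_hat))`.  Two-sided p-values come from the
#' standard normal reference; H0 (coefficient = 0) is rejected when
#' `|z| > z_{alpha/2}`.
#'
#' @param fit a converged fitted `"fsnblr"` model with a valid covariance.
#' @param alpha significance level (default 0.05).
#' @return a data frame of class `"fsnblr_wald"` with columns `label`,
#'   `estimate`, `se`, `z`, `p_value`, `reject`.
#' @export
wald_test <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "fsnblr"))
  V <- vcov(fit)
  v <- diag(V)
  if (any(v <= 0)) {
    stop("non-positive Wald variance for: ",
         paste(names(fit$coefficients)[v <= 0], collapse = ", "))
  }
  out <- wald_stat(fit$coefficients, sqrt(v), alpha = alpha)
  out$label <- names(fit$coefficients)
  out <- out[, c("label", "estimate", "se", "z", "p_value", "reject")]
  structure(out, class = c("fsnblr_wald", "data.frame"), alpha = alpha)
}

#' Wald z statistic and two-sided p-value from estimate and standard error
#'
#' Vectorized helper: `z = estimate / se`, `p = 2 (1 - Phi(|z|))`, rejection
#' at level `alpha` when `|z|` exceeds the upper `alpha/2` normal quantile.
#'
#' @param estimate coefficient estimate(s).
#' @param se standard error(s), strictly positive.
#' @param alpha significance level (default 0.05).
#' @return data frame with columns `estimate`, `se`, `z`, `p_value`,
#'   `reject`.
#' @examples
#' wald_stat(-0.0414, 0.0109)
#' @export
wald_stat <- function(estimate, se, alpha = 0.05) {
  if (any(se <= 0)) stop("standard errors must be positive")
  z <- estimate / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(estimate = as.numeric(estimate), se = as.numeric(se),
             z = as.numeric(z), p_value = p, reject = p < alpha)
}

#' @export
print.fsnblr_wald <- function(x, digits = 4L, ...) {
  tab <- data.frame(
    Parameters = x$label,
    Estimations = round(x$estimate, digits),
    `Std. Error` = round(x$se, digits),
    `z value` = round(x$z, 3L),
    `Pr(>|z|)` = signif(x$p_value, 3L),
    Decision = ifelse(x$reject, "reject H0", "fail to reject H0"),
    check.names = FALSE
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Predictors retained by the partial Wald tests
#'
#' A predictor is declared significant when the Wald test of its linear
#' slope `b_j` rejects at level `alpha`; the cosine harmonics of a retained
#' predictor are kept wholesale (hierarchical retention), matching the usual
#' refit workflow in which non-significant harmonics of significant
#' predictors stay in the reduced model.
#'
#' @param wald a `"fsnblr_wald"` table from [wald_test()].
#' @param alpha significance level; defaults to the level the table was
#'   built with.
#' @return character vector of retained predictor names (possibly empty).
#' @export
significant_predictors <- function(wald, alpha = NULL) {
  if (NROW(wald) == 0L) stop("empty Wald table")
  if (is.null(alpha)) alpha <- attr(wald, "alpha")
  if (is.null(alpha)) alpha <- 0.05
  slopes <- wald[startsWith(wald$label, "b:"), , drop = FALSE]
  sub("^b:", "", slopes$label[slopes$p_value < alpha])
}
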