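#' @export
print.fsnblr <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("\nFourier-series nonparametric binary logistic regression\n")
  if (!is.null(x$call)) {
    cat("Call: ", paste(deparse(x$call), collapse = "\n"), "\n", sep = "")
  }
  kind <- switch(x$model_kind,
                 intercept_only = "intercept-only (null) model",
                 blr = "plain binary logistic regression (all K = 0)",
                 fsnblr = "Fourier-series model")
  cat("Model kind: ", kind, "\n", sep = "")
  if (length(x$K)) {
    cat("Harmonic counts K: ",
        paste(sprintf("%s=%d", names(x$K), x$K), collapse = ", "), "\n", sep = "")
  }
  cat("\nCoefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nlog-likelihood: %.4f   deviance: %.4f   AIC: %.4f\n",
              x$loglik, -2 * x$loglik, -2 * x$loglik + 2 * x$df))
  cat(sprintf("Converged: %s (%d iterations)\n",
              ifelse(x$converged, "yes", "NO"), x$n_iter))
  if (isTRUE(x$separation)) cat("Warning: separation detected\n")
  invisible(x)
}

#' Summarize a fitted model: Wald table and overall likelihood-ratio test
#'
#' @param object a fitted `"fsnblr"` model.
#' @param alpha significance level for the per-parameter decisions
#'   (default 0.05).
#' @param ... unused.
#' @return an object of class `"summary.fsnblr"` containing the Wald
#'   coefficient table (see [wald_test()]) and, when the model has
#'   predictors, the simultaneous likelihood-ratio test against the
#'   intercept-only null.
#' @export
summary.fsnblr <- function(object, alpha = 0.05, ...) {
  wt <- wald_test(object, alpha = alpha)
  lr <- NULL
  if (object$model_kind != "intercept_only") {
    lr <- lrt(object, alpha = alpha)
  }
  structure(list(call = object$call, wald = wt, lrt = lr,
                 loglik = object$loglik, df = object$df,
                 deviance = -2 * object$loglik,
                 aic = -2 * object$loglik + 2 * object$df,
                 n = object$nobs, K = object$K, alpha = alpha,
                 converged = object$converged, n_iter = object$n_iter),
            class = "summary.fsnblr")
}

#' @export
print.summary.fsnblr <- function(x, ...) {
  if (!is.null(x$call)) {
    cat("Call: ", paste(deparse(x$call), collapse = "\n"), "\n\n", sep = "")
  }
  print(x$wald)
  cat(sprintf("\nn = %d, parameters = %d, log-likelihood = %.4f\n",
              x$n, x$df, x$loglik))
  cat(sprintf("Deviance: %.4f   AIC: %.4f\n", x$deviance, x$aic))
  if (!is.null(x$lrt)) {
    cat(sprintf("Simultaneous LRT: G2 = %.4f on %d df, p = %.3g (%s at alpha = %g)\n",
                x$lrt$G2, x$lrt$df, x$lrt$p_value,
                ifelse(x$lrt$reject, "reject H0", "fail to reject H0"), x$lrt$alpha))
  }
  if (!x$converged) cat("Warning: fit did not converge\n")
  invisible(x)
}

#' @export
coef.fsnblr <- function(object, ...) object$coefficients

#' Covariance of the fitted coefficients
#'
#' The estimated covariance matrix is the inverse observed information,
#' `-solve(H(theta_hat))`, whose diagonal supplies the Wald variances.
#'
#' @param object a converged `"fsnblr"` fit.
#' @param ... unused.
#' @return symmetric positive-semidefinite matrix.
#' @export
vcov.fsnblr <- function(object, ...) {
  if (!object$converged) stop("covariance requires a converged fit")
  if (is.null(object$vcov)) stop("observed information is singular at the optimum")
  object$vcov
}

#' @export
logLik.fsnblr <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$nobs,
            class = "logLik")
}

#' Residual deviance of a fitted model
#'
#' For ungrouped binary data the saturated log-likelihood is zero, so the
#' residual deviance is `-2 * logLik`.
#'
#' @param object a converged `"fsnblr"` fit.
#' @param ... unused.
#' @export
deviance.fsnblr <- function(object, ...) {
  if (!object$converged) stop("deviance requires a converged fit")
  -2 * object$loglik
}

#' @export
nobs.fsnblr <- function(object, ...) object$nobs

#' Predictions from a fitted model
#'
#' @param object a fitted `"fsnblr"` model.
#' @param newdata optional data frame (or matrix with the training predictor
#'   columns); defaults to the training data.
#' @param type `"response"` for probabilities, `"link"` for the linear
#'   predictor, `"class"` for 0/1 labels at `cutoff`.
#' @param cutoff classification threshold for `type = "class"`; a
#'   probability exactly equal to the cutoff is classified as 1.
#' @param ... unused.
#' @export
predict.fsnblr <- function(object, newdata = NULL,
                           type = c("response", "link", "class"),
                           cutoff = 0.5, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (is.null(object$X)) {
      design <- matrix(1, nrow = object$nobs, ncol = 1L)
    } else {
      design <- fourier_design(object$X, object$K,
                               rescale_cosine = object$rescale_cosine,
                               ranges = object$ranges)
    }
  } else {
    if (is.null(object$X)) {
      design <- matrix(1, nrow = NROW(newdata), ncol = 1L)
    } else {
      nd <- as.data.frame(newdata)
      miss <- setdiff(colnames(object$X), names(nd))
      if (length(miss)) stop("newdata is missing columns: ", paste(miss, collapse = ", "))
      design <- fourier_design(as.matrix(nd[, colnames(object$X), drop = FALSE]),
                               object$K, rescale_cosine = object$rescale_cosine,
                               ranges = object$ranges)
    }
  }
  eta <- drop(design %*% object$coefficients)
  switch(type,
         link = eta,
         response = predict_prob(design, object$coefficients),
         class = as.integer(predict_prob(design, object$coefficients) >= cutoff))
}

#' @export
fitted.fsnblr <- function(object, ...) object$fitted.values

#' @export
residuals.fsnblr <- function(object, type = c("deviance", "pearson", "response"), ...) {
  type <- match.arg(type)
  y <- object$y
  p <- object$fitted.values
  switch(type,
         response = y - p,
         pearson = (y - p) / sqrt(p * (1 - p)),
         deviance = sign(y - p) * sqrt(-2 * (y * log(p) + (1 - y) * log(1 - p))))
}

#' @export
simulate.fsnblr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$fitted.values
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot fitted per-predictor component functions
#'
#' Draws, for each requested predictor, the fitted contribution
#' `g_j(x) = b_j x + sum_k a_kj cos(k x)` over the observed range of that
#' predictor (cosines on the rescaled axis when the model used
#' `rescale_cosine = TRUE`), with a rug of the observed values.
#'
#' @param x a fitted `"fsnblr"` model with at least one predictor.
#' @param which predictors to plot (names or indices; default all).
#' @param n_grid grid resolution (default 200).
#' @param ... passed to [graphics::plot()].
#' @export
plot.fsnblr <- function(x, which = NULL, n_grid = 200L, ...) {
  if (is.null(x$X)) stop("intercept-only model has no component functions")
  nms <- colnames(x$X)
  if (is.null(which)) which <- nms
  if (is.numeric(which)) which <- nms[which]
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  th <- theta_unpack(x$coefficients, x$K)
  for (nm in which) {
    j <- match(nm, nms)
    xs <- seq(min(x$X[, j]), max(x$X[, j]), length.out = n_grid)
    z <- xs
    if (x$rescale_cosine) {
      lo <- x$ranges[j, 1L]; hi <- x$ranges[j, 2L]
      z <- if (hi > lo) (xs - lo) / (hi - lo) * pi else rep(0, n_grid)
    }
    g <- th$b[j] * xs
    if (x$K[j] > 0L) {
      for (k in seq_len(x$K[j])) g <- g + th$a[[j]][k] * cos(k * z)
    }
    graphics::plot(xs, g, type = "l", xlab = nm,
                   ylab = sprintf("component g(%s)", nm), ...)
    graphics::rug(x$X[, j])
  }
  invisible(x)
}

#' Likelihood-ratio comparison of nested fitted models
#'
#' `anova(null, full)` computes the likelihood-ratio statistic
#' `G2 = 2 (logLik(full) - logLik(null))` with degrees of freedom equal to
#' the difference in parameter counts.  With a single model the comparison
#' is against the intercept-only null (the simultaneous test).
#'
#' @param object,... fitted `"fsnblr"` models on the same data, smallest
#'   first.
#' @param alpha significance level (default 0.05).
#' @export
anova.fsnblr <- function(object, ..., alpha = 0.05) {
  fits <- c(list(object), Filter(function(z) inherits(z, "fsnblr"), list(...)))
  if (length(fits) == 1L) return(lrt(object, alpha = alpha))
  out <- NULL
  for (i in seq_len(length(fits) - 1L)) {
    lr <- lrt(fits[[i + 1L]], fits[[i]], alpha = alpha)
    out <- rbind(out, data.frame(model = i + 1L, G2 = lr$G2, df = lr$df,
                                 p_value = lr$p_value, reject = lr$reject))
  }
  out
}
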