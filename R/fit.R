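#' Convergence control for the Newton-Raphson fitter
#'
#' @param epsilon convergence tolerance: iteration stops once the max-abs
#'   change in the coefficient vector falls below `epsilon` (default 1e-6)
#'   and the score is numerically zero.
#' @param max_iter iteration cap (default 100).
#' @param ridge transient Hessian regularization used only when a Newton
#'   system is numerically singular mid-iteration, scaled by the mean
#'   diagonal of the information matrix (default 1e-8).  The final
#'   covariance always comes from the unregularized Hessian.
#' @param step_halving logical; halve a Newton step (up to 30 times) when
#'   the full step would decrease the log-likelihood (default `TRUE`).
#' @param grad_tol score tolerance used to certify convergence (default 1e-6).
#' @return a list of class `fsnblr_control`.
#' @export
fsnblr_control <- function(epsilon = 1e-6, max_iter = 100L, ridge = 1e-8,
                           step_halving = TRUE, grad_tol = 1e-6) {
  stopifnot(epsilon > 0, max_iter >= 1)
  structure(list(epsilon = epsilon, max_iter = as.integer(max_iter),
                 ridge = ridge, step_halving = step_halving,
                 grad_tol = grad_tol),
            class = "fsnblr_control")
}

# Newton-Raphson maximizer of the Bernoulli log-likelihood on a fixed design.
# Deterministic: theta(0) = 0 (or `start`), full analytic Newton steps with
# optional step-halving so accepted steps never decrease the log-likelihood.
newton_logistic <- function(y, design, control = fsnblr_control(), start = NULL) {
  m <- ncol(design)
  theta <- if (is.null(start)) numeric(m) else {
    if (length(start) != m) stop("`start` has the wrong length")
    as.numeric(start)
  }
  names(theta) <- colnames(design)
  ll <- loglik_bernoulli(y, design, theta)
  trace <- data.frame(iter = 0L, step = NA_real_, loglik = ll, halvings = 0L)
  converged <- FALSE
  separation <- FALSE
  iter <- 0L

  while (iter < control$max_iter) {
    iter <- iter + 1L
    g <- score_bernoulli(y, design, theta)
    A <- -hessian_bernoulli(y, design, theta)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) {
      # transient ridge; never used for the reported covariance
      A <- A + control$ridge * mean(diag(A)) * diag(m)
      ch <- tryCatch(chol(A), error = function(e) NULL)
      if (is.null(ch)) {
        warning("Hessian numerically singular; stopping without convergence")
        break
      }
    }
    step <- backsolve(ch, forwardsolve(t(ch), g))
    theta_new <- theta + step
    ll_new <- loglik_bernoulli(y, design, theta_new)
    halvings <- 0L
    if (control$step_halving) {
      while ((!is.finite(ll_new) || ll_new < ll) && halvings < 30L) {
        step <- step / 2
        theta_new <- theta + step
        ll_new <- loglik_bernoulli(y, design, theta_new)
        halvings <- halvings + 1L
      }
    }
    if (!is.finite(ll_new) || ll_new < ll) {
      delta <- max(abs(step))
      if (delta < control$epsilon) {
        # already at the optimum: no improving direction, step negligible
        converged <- TRUE
      } else {
        warning("no improving Newton step found; stopping without convergence")
      }
      break
    }
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    ll <- ll_new
    trace <- rbind(trace, data.frame(iter = iter, step = delta,
                                     loglik = ll, halvings = halvings))
    if (delta < control$epsilon) {
      if (max(abs(score_bernoulli(y, design, theta))) < control$grad_tol) {
        converged <- TRUE
        break
      }
    }
  }

  if (!converged && iter >= control$max_iter) {
    warning(sprintf("Newton-Raphson did not converge in %d iterations",
                    control$max_iter))
  }
  # complete separation: likelihood flat at its supremum 0 with runaway theta
  if (ll > -1e-4 && max(abs(theta)) > 50) {
    separation <- TRUE
    converged <- FALSE
    warning("complete or quasi-complete separation detected (log-likelihood ~ 0, diverging coefficients)")
  }

  vcov <- NULL
  if (converged) {
    A <- -hessian_bernoulli(y, design, theta)   # unregularized
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (!is.null(ch)) {
      vcov <- chol2inv(ch)
      vcov <- (vcov + t(vcov)) / 2
      dimnames(vcov) <- list(colnames(design), colnames(design))
    } else {
      warning("observed information singular at the optimum; covariance unavailable")
    }
  }
  list(theta = theta, loglik = ll, n_iter = iter, converged = converged,
       separation = separation, trace = trace, vcov = vcov)
}

.validate_response <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("factor response must have exactly two levels")
    y <- as.integer(y) - 1L
  }
  if (is.logical(y)) y <- as.integer(y)
  y <- as.numeric(y)
  bad <- which(!(y %in% c(0, 1)))
  if (length(bad)) {
    stop(sprintf("response must be binary 0/1; offending rows: %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  y
}

#' Fit a Fourier-series nonparametric binary logistic regression
#'
#' `fsnblr()` fits, by Newton-Raphson maximum likelihood, a logistic model
#' for a binary response in which each continuous predictor contributes a
#' linear term plus a truncated cosine series:
#' \deqn{logit P(Y_i = 1) = a_0 + \sum_j \left( b_j x_{ji} +
#'       \sum_{k=1}^{K_j} a_{kj} \cos(k x_{ji}) \right).}
#' `K[j] = 0` drops the cosine terms for predictor j, so `K = 0` is ordinary
#' binary logistic regression (BLR) and `y ~ 1` the intercept-only null
#' model.  Starting values are zero for every coefficient (fitted
#' probabilities 1/2), accepted steps never decrease the log-likelihood, and
#' the iteration stops when the max-abs coefficient change drops below
#' `control$epsilon`.
#'
#' @param formula model formula, e.g. `y ~ x1 + x2`; predictors must be
#'   continuous and enter additively (use `y ~ 1` for the null model).
#' @param data data frame containing the variables.
#' @param K integer vector of cosine-harmonic counts, one per predictor in
#'   the order they appear in the formula (scalar recycled; default 0 =
#'   plain logistic regression).
#' @param rescale_cosine logical; rescale each predictor to `[0, pi]` before
#'   the cosine transform (default `FALSE`, i.e. raw-scale cosines).
#' @param control a [fsnblr_control()] list.
#' @param start optional starting coefficient vector (flat, length
#'   `1 + p + sum(K)`).
#' @return An object of class `"fsnblr"` with components `coefficients`,
#'   `loglik`, `vcov`, `fitted.values`, `K`, `n_iter`, `converged`,
#'   `separation`, `trace`, `model_kind`, and the training `y`/`X`.
#'   Standard methods are available: `print`, `summary` (Wald table),
#'   `coef`, `vcov`, `logLik`, `deviance`, `AIC`, `predict`, `residuals`,
#'   `simulate`, `plot`, `anova` (likelihood-ratio test).
#' @examples
#' sc <- fsnblr_scenario("strong_cosine", n = 400, seed = 7)
#' fit <- fsnblr(y ~ x1 + x2, data = sc$data, K = c(2, 1))
#' summary(fit)
#' @seealso [select_orders()] for choosing `K` by AIC, [lrt()] for the
#'   simultaneous test, [classification_report()] for diagnostics.
#' @export
fsnblr <- function(formula, data, K = 0L, rescale_cosine = FALSE,
                   control = fsnblr_control(), start = NULL) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  vars <- attr(stats::terms(formula, data = data), "term.labels")
  X <- if (length(vars)) {
    Xd <- mf[, vars, drop = FALSE]
    if (!all(vapply(Xd, is.numeric, logical(1L)))) {
      stop("all predictors must be numeric (continuous)")
    }
    as.matrix(Xd)
  } else NULL
  fit <- fsnblr_fit(y, X, K = K, rescale_cosine = rescale_cosine,
                    control = control, start = start)
  fit$call <- match.call()
  fit$formula <- formula
  fit
}

#' @param y binary 0/1 response vector (also accepts logical or a two-level
#'   factor).
#' @param X numeric predictor matrix (or `NULL` for the intercept-only
#'   model).
#' @rdname fsnblr
#' @export
fsnblr_fit <- function(y, X = NULL, K = 0L, rescale_cosine = FALSE,
                       control = fsnblr_control(), start = NULL) {
  y <- .validate_response(y)
  if (length(unique(y)) < 2L) stop("fitting requires both response classes to be present")
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (nrow(X) != length(y)) stop("X and y have different lengths")
  }
  p <- if (is.null(X)) 0L else ncol(X)
  if (p == 0L) {
    design <- matrix(1, nrow = length(y), ncol = 1L,
                     dimnames = list(NULL, "(Intercept)"))
    attr(design, "orders") <- integer(0)
    attr(design, "rescale_cosine") <- rescale_cosine
    attr(design, "ranges") <- matrix(numeric(0), ncol = 2L)
    K <- integer(0)
  } else {
    if (length(K) == 1L) K <- rep(as.integer(K), p)
    design <- fourier_design(X, K, rescale_cosine = rescale_cosine)
    K <- attr(design, "orders")
  }

  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop(sprintf("design matrix is rank deficient; offending columns: %s",
                 paste(bad, collapse = ", ")))
  }

  nf <- newton_logistic(y, design, control = control, start = start)
  model_kind <- if (p == 0L) "intercept_only" else if (all(K == 0L)) "blr" else "fsnblr"
  structure(list(
    coefficients = nf$theta,
    loglik = nf$loglik,
    vcov = nf$vcov,
    fitted.values = predict_prob(design, nf$theta),
    y = y, X = X, K = K,
    rescale_cosine = rescale_cosine,
    ranges = attr(design, "ranges"),
    n_iter = nf$n_iter, converged = nf$converged,
    separation = nf$separation, trace = nf$trace,
    model_kind = model_kind,
    df = ncol(design), nobs = length(y),
    control = control,
    call = match.call()
  ), class = "fsnblr")
}
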