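#' AIC-driven search over cosine-harmonic counts
#'
#' Chooses the per-predictor harmonic counts `K = (K_1, ..., K_p)` by
#' minimizing `AIC = -2 logLik + 2 m`, where `m = 1 + p + sum(K)` counts
#' every coefficient including the intercept.  The default `"exhaustive"`
#' mode fits every combination in `{1, ..., Kmax}^p` (refusing spaces larger
#' than 20000 combinations); `"greedy"` starts from all-ones and raises one
#' `K_j` at a time while the AIC improves, which evaluates only a subset of
#' the space and so can never beat the exhaustive optimum.  Combinations
#' whose fit fails or does not converge are recorded but excluded from the
#' argmin.  Ties are broken toward the smaller total `sum(K)`, then
#' lexicographically.
#'
#' @param formula,data model formula and data frame, as in [fsnblr()].
#' @param Kmax largest harmonic count tried per predictor (default 3).
#' @param mode `"exhaustive"` (default) or `"greedy"`.
#' @param rescale_cosine passed to [fsnblr()].
#' @param control a [fsnblr_control()] list.
#' @return object of class `"fsnblr_selection"`: list with `grid` (data
#'   frame of combinations, AIC and convergence flag), `best_K`, `best_fit`
#'   (a refitted `"fsnblr"` object at `best_K`), `mode`, `Kmax`.
#' @examples
#' sc <- fsnblr_scenario("strong_cosine", n = 400, seed = 11)
#' sel <- select_orders(y ~ x1 + x2, data = sc$data, Kmax = 2)
#' sel$best_K
#' @export
select_orders <- function(formula, data, Kmax = 3L,
                          mode = c("exhaustive", "greedy"),
                          rescale_cosine = FALSE,
                          control = fsnblr_control()) {
  mode <- match.arg(mode)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  vars <- attr(stats::terms(formula, data = data), "term.labels")
  if (!length(vars)) stop("order selection needs at least one predictor")
  X <- as.matrix(mf[, vars, drop = FALSE])
  out <- select_orders_xy(y, X, Kmax = Kmax, mode = mode,
                          rescale_cosine = rescale_cosine, control = control)
  out$call <- match.call()
  out
}

#' @param y,X response vector and predictor matrix (matrix interface).
#' @rdname select_orders
#' @export
select_orders_xy <- function(y, X, Kmax = 3L, mode = c("exhaustive", "greedy"),
                             rescale_cosine = FALSE, control = fsnblr_control()) {
  mode <- match.arg(mode)
  Kmax <- as.integer(Kmax)
  if (Kmax < 1L) stop("Kmax must be >= 1")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)

  eval_combo <- function(K) {
    fit <- tryCatch(
      suppressWarnings(fsnblr_fit(y, X, K = K, rescale_cosine = rescale_cosine,
                                  control = control)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      list(aic = NA_real_, converged = FALSE)
    } else {
      list(aic = -2 * fit$loglik + 2 * fit$df, converged = TRUE)
    }
  }

  if (mode == "exhaustive") {
    if (Kmax^p > 20000) {
      stop(sprintf("exhaustive search space (%d^%d combinations) exceeds the 20000 guard; use mode = \"greedy\"",
                   Kmax, p))
    }
    combos <- as.matrix(expand.grid(rep(list(seq_len(Kmax)), p)))
    colnames(combos) <- colnames(X)
    res <- apply(combos, 1L, function(K) eval_combo(as.integer(K)))
    aics <- vapply(res, `[[`, numeric(1L), "aic")
    conv <- vapply(res, `[[`, logical(1L), "converged")
  } else {
    K <- rep(1L, p)
    seen <- new.env()
    combos <- NULL; aics <- numeric(0); conv <- logical(0)
    record <- function(K) {
      key <- paste(K, collapse = ",")
      if (!is.null(seen[[key]])) return(seen[[key]])
      r <- eval_combo(K)
      combos <<- rbind(combos, K)
      aics <<- c(aics, r$aic)
      conv <<- c(conv, r$converged)
      seen[[key]] <- r$aic
      r$aic
    }
    cur <- record(K)
    repeat {
      cand <- lapply(seq_len(p), function(j) {
        Kj <- K; Kj[j] <- Kj[j] + 1L
        if (Kj[j] > Kmax) NULL else Kj
      })
      cand <- Filter(Negate(is.null), cand)
      if (!length(cand)) break
      cand_aic <- vapply(cand, record, numeric(1L))
      if (all(is.na(cand_aic)) || min(cand_aic, na.rm = TRUE) >= cur - 1e-12) break
      best <- which.min(cand_aic)
      K <- cand[[best]]
      cur <- cand_aic[best]
    }
    colnames(combos) <- colnames(X)
    rownames(combos) <- NULL
  }

  if (!any(conv)) stop("all candidate fits failed or did not converge")
  # argmin with ties toward smaller sum(K), then lexicographic
  ord <- do.call(order, c(list(ifelse(conv, aics, Inf), rowSums(combos)),
                          as.data.frame(combos)))
  best_idx <- ord[1L]
  best_K <- stats::setNames(as.integer(combos[best_idx, ]), colnames(X))
  best_fit <- fsnblr_fit(y, X, K = best_K, rescale_cosine = rescale_cosine,
                         control = control)
  grid <- data.frame(combos, AIC = aics, converged = conv, check.names = FALSE)
  structure(list(grid = grid, best_K = best_K, best_aic = aics[best_idx],
                 best_fit = best_fit, mode = mode, Kmax = Kmax),
            class = "fsnblr_selection")
}

#' @export
print.fsnblr_selection <- function(x, n = 10L, ...) {
  cat(sprintf("AIC order selection (%s mode, Kmax = %d, %d combinations)\n",
              x$mode, x$Kmax, nrow(x$grid)))
  g <- x$grid[order(ifelse(x$grid$converged, x$grid$AIC, Inf)), , drop = FALSE]
  print(utils::head(g, n), row.names = FALSE)
  cat(sprintf("Best: K = (%s), AIC = %.4f\n",
              paste(x$best_K, collapse = ","), x$best_aic))
  invisible(x)
}

#' Refit on the predictors retained by the partial Wald tests
#'
#' Reproduces the two-stage workflow: run the per-parameter Wald tests on a
#' full fitted model, keep the predictors whose linear slope is significant
#' at level `alpha` (harmonics of retained predictors are kept wholesale),
#' re-run the AIC order search on the reduced predictor set, and fit the
#' resulting best model.  If no predictor is significant the intercept-only
#' model is returned with a warning.
#'
#' @param fit a converged full `"fsnblr"` fit (with stored predictors).
#' @param alpha significance level for the Wald screen (default 0.05).
#' @param Kmax,mode,control passed to the order search on the reduced set.
#' @return a fitted `"fsnblr"` model on the retained predictors, with the
#'   selection object attached as attribute `"selection"` and the retained
#'   names as attribute `"retained"`.
#' @export
refit_significant <- function(fit, alpha = 0.05, Kmax = 3L,
                              mode = c("exhaustive", "greedy"),
                              control = fsnblr_control()) {
  stopifnot(inherits(fit, "fsnblr"))
  if (!fit$converged) stop("refit requires a converged fit")
  mode <- match.arg(mode)
  keep <- significant_predictors(wald_test(fit, alpha = alpha), alpha = alpha)
  if (!length(keep)) {
    warning("no significant predictors at level ", alpha,
            "; returning the intercept-only model")
    out <- fsnblr_fit(fit$y, NULL, control = control)
    attr(out, "retained") <- character(0)
    return(out)
  }
  Xred <- fit$X[, keep, drop = FALSE]
  if (fit$model_kind == "blr") {
    out <- fsnblr_fit(fit$y, Xred, K = 0L, control = control)
    attr(out, "retained") <- keep
    return(out)
  }
  sel <- select_orders_xy(fit$y, Xred, Kmax = Kmax, mode = mode,
                          rescale_cosine = fit$rescale_cosine, control = control)
  out <- sel$best_fit
  attr(out, "selection") <- sel
  attr(out, "retained") <- keep
  out
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)`, where `R^2_j` comes from the least-squares
#' regression of predictor j on the remaining predictors plus an intercept.
#' Values of 10 or more conventionally flag harmful multicollinearity;
#' exactly collinear predictors get an infinite VIF.
#'
#' @param X numeric matrix or data frame with at least two columns and more
#'   rows than columns.
#' @return data frame with columns `variable`, `vif` and logical `high`
#'   (`vif >= 10`).
#' @examples
#' vif(matrix(rnorm(400), 100, 4))
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("VIF needs at least two predictors")
  if (nrow(X) <= ncol(X)) stop("VIF needs more observations than predictors")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  out <- vapply(seq_len(ncol(X)), function(j) {
    xj <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Z, xj)
    rss <- sum(fit$residuals^2)
    tss <- sum((xj - mean(xj))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L))
  data.frame(variable = colnames(X), vif = out, high = out >= 10)
}
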