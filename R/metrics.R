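#' Classify predicted probabilities at a cutoff
#'
#' Labels an observation 1 when its predicted probability is greater than
#' or equal to `cutoff` (the boundary is classified as 1 so that the rule is
#' deterministic) and tallies the 2x2 confusion matrix against the supplied
#' truth, rows indexed by the true class and columns by the predicted class.
#'
#' @param probs predicted probabilities in `[0, 1]`.
#' @param truth binary 0/1 true labels, same length.
#' @param cutoff classification threshold (default 0.5).
#' @return list with `pred` (integer labels) and `confusion` (2x2 matrix
#'   with dimnames `truth` 0/1 by `predicted` 0/1).
#' @export
classify <- function(probs, truth, cutoff = 0.5) {
  if (length(probs) != length(truth)) stop("probs and truth have different lengths")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(truth %in% c(0, 1))) stop("truth must be binary 0/1")
  pred <- as.integer(probs >= cutoff)
  confusion <- table(factor(truth, levels = c(0, 1)),
                     factor(pred, levels = c(0, 1)))
  confusion <- unclass(confusion)
  dimnames(confusion) <- list(truth = c("0", "1"), predicted = c("0", "1"))
  list(pred = pred, confusion = confusion)
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' Accuracy is the overall proportion correct.  Sensitivity is the
#' within-class correct rate of the *positive* class and specificity that of
#' the other class.  The default orientation, `positive = "majority"`, takes
#' the larger true class as positive — the convention under which the
#' sensitivity of an imbalanced two-class problem refers to the majority
#' class.  Empty classes yield `NA` (not 0) for the affected rate.
#'
#' @param confusion 2x2 matrix of counts, rows = true class (0, 1), columns
#'   = predicted class (0, 1).
#' @param positive `"majority"` (default), `"0"` or `"1"`.
#' @return list with `accuracy`, `sensitivity`, `specificity` (proportions
#'   in `[0, 1]`) and `positive` (the class used as positive).
#' @export
confusion_metrics <- function(confusion, positive = c("majority", "0", "1")) {
  positive <- match.arg(positive)
  confusion <- as.matrix(confusion)
  if (any(confusion < 0)) stop("confusion counts must be non-negative")
  n <- sum(confusion)
  if (n < 1) stop("confusion matrix is empty")
  if (positive == "majority") {
    positive <- if (sum(confusion[2L, ]) > sum(confusion[1L, ])) "1" else "0"
  }
  ip <- if (positive == "1") 2L else 1L
  io <- 3L - ip
  rate <- function(i) {
    tot <- sum(confusion[i, ])
    if (tot == 0) NA_real_ else confusion[i, i] / tot
  }
  list(accuracy = (confusion[1L, 1L] + confusion[2L, 2L]) / n,
       sensitivity = rate(ip), specificity = rate(io), positive = positive)
}

#' Rank-based (Mann-Whitney) area under the ROC curve
#'
#' The AUC equals the probability that a randomly chosen positive case has
#' a higher score than a randomly chosen negative case, ties counted one
#' half — computed from midranks, so it is invariant under any strictly
#' monotone transform of the scores.
#'
#' @param truth binary 0/1 labels; both classes must be present.
#' @param probs scores (e.g. predicted probabilities), same length.
#' @return scalar in `[0, 1]`.
#' @export
auc_mw <- function(truth, probs) {
  if (length(truth) != length(probs)) stop("truth and probs have different lengths")
  if (!all(truth %in% c(0, 1))) stop("truth must be binary 0/1")
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(probs)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Press's Q statistic for classification better than chance
#'
#' `Q = (N - n K)^2 / (N (K - 1))` for `n` correct classifications out of
#' `N` cases in `K` groups; under chance assignment Q is asymptotically
#' chi-square with 1 degree of freedom, so large values indicate that the
#' classifier beats chance.
#'
#' @param n_correct number of correctly classified cases.
#' @param n_total total number of cases.
#' @param n_groups number of groups (default 2).
#' @return scalar Q >= 0.
#' @examples
#' press_q(195, 232)  # 107.6034
#' @export
press_q <- function(n_correct, n_total, n_groups = 2L) {
  if (n_total < 1 || n_correct < 0 || n_correct > n_total) stop("invalid counts")
  if (n_groups < 2) stop("n_groups must be >= 2")
  (n_total - n_correct * n_groups)^2 / (n_total * (n_groups - 1))
}

#' Full classification report at a probability cutoff
#'
#' Bundles the 0.5-cutoff (by default) confusion matrix with accuracy,
#' sensitivity, specificity (see [confusion_metrics()] for the orientation
#' convention), the rank-based AUC and Press's Q, the latter compared
#' against the chi-square(1) critical value at `alpha`.
#'
#' @param truth binary 0/1 labels.
#' @param probs predicted probabilities.
#' @param cutoff classification threshold (default 0.5).
#' @param positive orientation for sensitivity/specificity (default
#'   `"majority"`).
#' @param alpha level for the Press's Q decision (default 0.05).
#' @return object of class `"fsnblr_classification"`.
#' @export
classification_report <- function(truth, probs, cutoff = 0.5,
                                  positive = "majority", alpha = 0.05) {
  cl <- classify(probs, truth, cutoff = cutoff)
  cm <- confusion_metrics(cl$confusion, positive = positive)
  n <- length(truth)
  n_correct <- cl$confusion[1L, 1L] + cl$confusion[2L, 2L]
  q <- press_q(n_correct, n, 2L)
  structure(list(confusion = cl$confusion, accuracy = cm$accuracy,
                 sensitivity = cm$sensitivity, specificity = cm$specificity,
                 positive = cm$positive,
                 auc = auc_mw(truth, probs), press_q = q,
                 press_q_reject = q > stats::qchisq(1 - alpha, 1L),
                 cutoff = cutoff, n = n, n_correct = n_correct,
                 alpha = alpha),
            class = "fsnblr_classification")
}

#' @export
print.fsnblr_classification <- function(x, ...) {
  cat(sprintf("Classification at cutoff %.2f (n = %d, %d correct)\n",
              x$cutoff, x$n, x$n_correct))
  print(x$confusion)
  cat(sprintf("Accuracy %.2f%%  Sensitivity %.2f%%  Specificity %.2f%%  (positive class: %s)\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
              x$positive))
  cat(sprintf("AUC %.4f   Press's Q %.4f (%s chance-level H0 at alpha = %g)\n",
              x$auc, x$press_q,
              ifelse(x$press_q_reject, "reject", "fail to reject"), x$alpha))
  invisible(x)
}

#' Side-by-side comparison of fitted models
#'
#' Tabulates deviance, AIC and the classification diagnostics for two or
#' more models fitted to the same data, flagging the minimum-deviance and
#' maximum-AUC models.
#'
#' @param ... named, converged `"fsnblr"` fits on the same response.
#' @param cutoff,positive,alpha passed to [classification_report()].
#' @return data frame of class `"fsnblr_comparison"` with one row per
#'   model and logical columns `best_deviance`, `best_auc`.
#' @export
compare_models <- function(..., cutoff = 0.5, positive = "majority",
                           alpha = 0.05) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) && !inherits(fits[[1L]], "fsnblr")) {
    fits <- fits[[1L]]
  }
  if (length(fits) < 2L) stop("compare_models needs at least two fits")
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  y0 <- fits[[1L]]$y
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    stopifnot(inherits(f, "fsnblr"))
    if (!isTRUE(all.equal(f$y, y0))) stop("fits are not on the same data")
    rep <- classification_report(f$y, f$fitted.values, cutoff = cutoff,
                                 positive = positive, alpha = alpha)
    data.frame(model = nm, deviance = deviance(f),
               AIC = -2 * f$loglik + 2 * f$df,
               accuracy = rep$accuracy, sensitivity = rep$sensitivity,
               specificity = rep$specificity, auc = rep$auc,
               press_q = rep$press_q)
  })
  out <- do.call(rbind, rows)
  out$best_deviance <- out$deviance <= min(out$deviance) + 1e-12
  out$best_auc <- out$auc >= max(out$auc) - 1e-12
  structure(out, class = c("fsnblr_comparison", "data.frame"))
}

#' @export
print.fsnblr_comparison <- function(x, ...) {
  y <- as.data.frame(x)
  for (cn in c("accuracy", "sensitivity", "specificity", "auc")) {
    y[[cn]] <- sprintf("%.2f%%", 100 * y[[cn]])
  }
  y$deviance <- round(y$deviance, 4L)
  y$AIC <- round(y$AIC, 4L)
  y$press_q <- round(y$press_q, 4L)
  print(y, row.names = FALSE)
  invisible(x)
}
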