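#' Read and validate a modelling dataset from delimited text
#'
#' Reads a CSV file with header, checks that the response column is binary
#' 0/1 and that the predictor columns are numeric with no missing values,
#' and returns the validated pieces.  Validation failures name the
#' offending rows.
#'
#' @param path path to a CSV file with a header row.
#' @param response name of the binary response column (default `"y"`).
#' @param predictors character vector of predictor column names; defaults
#'   to every other column.
#' @return list with `y` (numeric 0/1 vector), `X` (numeric matrix),
#'   `response`, `predictors` and the raw `data` frame.
#' @export
read_fsnblr_data <- function(path, response = "y", predictors = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  data <- utils::read.csv(path)
  if (nrow(data) == 0L) stop("empty dataset: ", path)
  if (!response %in% names(data)) stop("response column not found: ", response)
  if (is.null(predictors)) predictors <- setdiff(names(data), response)
  miss <- setdiff(predictors, names(data))
  if (length(miss)) stop("predictor columns not found: ", paste(miss, collapse = ", "))
  y <- data[[response]]
  bad <- which(is.na(y) | !(y %in% c(0, 1)))
  if (length(bad)) {
    stop(sprintf("response '%s' must be binary 0/1; offending rows: %s",
                 response, paste(utils::head(bad, 5L), collapse = ", ")))
  }
  X <- data[, predictors, drop = FALSE]
  for (nm in predictors) {
    if (!is.numeric(X[[nm]])) stop("predictor is not numeric: ", nm)
    bad <- which(!is.finite(X[[nm]]))
    if (length(bad)) {
      stop(sprintf("predictor '%s' has missing/non-finite values at rows: %s",
                   nm, paste(utils::head(bad, 5L), collapse = ", ")))
    }
  }
  list(y = as.numeric(y), X = as.matrix(X), response = response,
       predictors = predictors, data = data)
}

.fit_summary <- function(fit, alpha) {
  wt <- tryCatch(wald_test(fit, alpha = alpha), error = function(e) NULL)
  list(model_kind = fit$model_kind,
       K = as.list(fit$K),
       coefficients = as.list(fit$coefficients),
       loglik = fit$loglik, deviance = -2 * fit$loglik,
       aic = -2 * fit$loglik + 2 * fit$df,
       n_iter = fit$n_iter, converged = fit$converged,
       wald = if (!is.null(wt)) as.data.frame(wt) else NULL)
}

#' Run the full modelling workflow on one dataset
#'
#' Executes, in order: the VIF multicollinearity screen; the plain logistic
#' (BLR) fit with its Wald table and its reduced refit on the significant
#' predictors; the AIC search over cosine-harmonic counts and the resulting
#' full Fourier-series fit with simultaneous LRT and Wald tables; the
#' significant-predictor Fourier refit (orders re-selected on the reduced
#' set); and a side-by-side model comparison by deviance, AIC and
#' classification diagnostics.  When `out_dir` is given the bundle is also
#' written to disk: `report.json` (canonical), one TSV per table, and a
#' plain-text log with options and iteration counts.
#'
#' @param data a data frame, or a path to a CSV file read via
#'   [read_fsnblr_data()].
#' @param response,predictors response / predictor column names (defaults:
#'   `"y"` and all other columns).
#' @param alpha significance level (default 0.05).
#' @param Kmax harmonic-count cap for the AIC search (default 3).
#' @param cutoff classification threshold (default 0.5).
#' @param rescale_cosine map predictors to `[0, pi]` before cosines
#'   (default `FALSE`).
#' @param search_mode `"exhaustive"` (default) or `"greedy"`.
#' @param control a [fsnblr_control()] list.
#' @param out_dir optional output directory for reports.
#' @return (invisibly) the report bundle: a named list with elements
#'   `config`, `vif`, `blr`, `blr_reduced`, `selection`, `fsnblr`, `lrt`,
#'   `fsnblr_reduced`, `comparison`.  On a stage failure the error is
#'   re-thrown with the stage name, and the partial bundle is attached to
#'   the condition.
#' @export
run_fsnblr_pipeline <- function(data, response = "y", predictors = NULL,
                                alpha = 0.05, Kmax = 3L, cutoff = 0.5,
                                rescale_cosine = FALSE,
                                search_mode = c("exhaustive", "greedy"),
                                control = fsnblr_control(), out_dir = NULL) {
  search_mode <- match.arg(search_mode)
  stopifnot(alpha > 0, alpha < 1, cutoff > 0, cutoff < 1)
  if (is.character(data)) {
    ds <- read_fsnblr_data(data, response = response, predictors = predictors)
  } else {
    data <- as.data.frame(data)
    if (is.null(predictors)) predictors <- setdiff(names(data), response)
    if (!response %in% names(data)) stop("response column not found: ", response)
    ds <- list(y = .validate_response(data[[response]]),
               X = as.matrix(data[, predictors, drop = FALSE]),
               response = response, predictors = predictors)
  }
  bundle <- list(config = list(response = ds$response,
                               predictors = ds$predictors,
                               n = length(ds$y), alpha = alpha, Kmax = Kmax,
                               cutoff = cutoff, rescale_cosine = rescale_cosine,
                               search_mode = search_mode))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cond <- simpleError(sprintf("pipeline stage '%s' failed: %s", name,
                                  conditionMessage(e)))
      cond$partial <- bundle
      stop(cond)
    })
  }

  if (length(ds$predictors) >= 2L) {
    bundle$vif <- stage("vif", vif(ds$X))
  }

  blr <- stage("blr_fit", fsnblr_fit(ds$y, ds$X, K = 0L, control = control))
  bundle$blr <- .fit_summary(blr, alpha)
  blr_red <- stage("blr_reduced",
                   refit_significant(blr, alpha = alpha, control = control))
  bundle$blr_reduced <- .fit_summary(blr_red, alpha)
  bundle$blr_reduced$retained <- attr(blr_red, "retained")

  sel <- stage("order_selection",
               select_orders_xy(ds$y, ds$X, Kmax = Kmax, mode = search_mode,
                                rescale_cosine = rescale_cosine,
                                control = control))
  bundle$selection <- list(grid = sel$grid, best_K = as.list(sel$best_K),
                           best_aic = sel$best_aic, mode = sel$mode)
  fs <- sel$best_fit
  bundle$fsnblr <- .fit_summary(fs, alpha)
  lr <- stage("lrt", lrt(fs, alpha = alpha))
  bundle$lrt <- list(G2 = lr$G2, df = lr$df, p_value = lr$p_value,
                     critical_value = lr$critical_value, reject = lr$reject)

  fs_red <- stage("fsnblr_reduced",
                  refit_significant(fs, alpha = alpha, Kmax = Kmax,
                                    mode = search_mode, control = control))
  bundle$fsnblr_reduced <- .fit_summary(fs_red, alpha)
  bundle$fsnblr_reduced$retained <- attr(fs_red, "retained")

  cmp <- stage("comparison",
               compare_models(list(BLR = blr_red, FSNBLR = fs_red),
                              cutoff = cutoff, alpha = alpha))
  bundle$comparison <- as.data.frame(cmp)

  if (!is.null(out_dir)) {
    write_pipeline_reports(bundle, out_dir)
  }
  invisible(bundle)
}

# JSON (canonical) + per-table TSV + plain-text log.
write_pipeline_reports <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(bundle, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$vif)) wtsv(bundle$vif, "vif")
  for (nm in c("blr", "blr_reduced", "fsnblr", "fsnblr_reduced")) {
    if (!is.null(bundle[[nm]]$wald)) wtsv(bundle[[nm]]$wald, paste0(nm, "_wald"))
  }
  if (!is.null(bundle$selection)) wtsv(bundle$selection$grid, "selection_grid")
  if (!is.null(bundle$comparison)) wtsv(bundle$comparison, "comparison")
  log <- c(
    sprintf("n = %d, predictors: %s", bundle$config$n,
            paste(bundle$config$predictors, collapse = ", ")),
    sprintf("alpha = %g, Kmax = %d, cutoff = %g, search_mode = %s, rescale_cosine = %s",
            bundle$config$alpha, bundle$config$Kmax, bundle$config$cutoff,
            bundle$config$search_mode, bundle$config$rescale_cosine),
    sprintf("BLR: loglik %.6f, %d iterations, converged %s",
            bundle$blr$loglik, bundle$blr$n_iter, bundle$blr$converged),
    sprintf("FSNBLR best K: (%s), AIC %.6f",
            paste(unlist(bundle$selection$best_K), collapse = ","),
            bundle$selection$best_aic),
    sprintf("FSNBLR: loglik %.6f, %d iterations, converged %s",
            bundle$fsnblr$loglik, bundle$fsnblr$n_iter, bundle$fsnblr$converged),
    sprintf("LRT: G2 %.6f on %d df, p %.6g", bundle$lrt$G2, bundle$lrt$df,
            bundle$lrt$p_value))
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
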