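#' Fourier-series design matrix for binary logistic regression
#'
#' Expands a matrix of continuous predictors into the regression basis used
#' throughout the package: an intercept column, one linear column per
#' predictor, and `K[j]` cosine-harmonic columns `cos(k * x_j)` per predictor
#' (`k = 1, ..., K[j]`).  Setting `K[j] = 0` leaves predictor `j` linear, so
#' the ordinary binary logistic regression basis is the special case
#' `K = 0`.
#'
#' Column labels follow a fixed scheme that the inference and reporting
#' functions rely on: `"(Intercept)"`, `"b:<name>"` for linear terms and
#' `"a<k>:<name>"` for the k-th cosine harmonic of predictor `<name>`.
#'
#' By default the cosine argument is the raw predictor value, which is what
#' the model's fitted coefficients assume.  For predictors spanning hundreds
#' of units the raw-scale cosine oscillates very rapidly;
#' `rescale_cosine = TRUE` first maps each predictor linearly onto
#' `[0, pi]` (using `ranges`, by default the observed min/max) before taking
#' cosines.  The linear column always uses the raw values.
#'
#' @param X numeric matrix or data frame of continuous predictors (n x p),
#'   or `NULL`/zero-column for an intercept-only basis.
#' @param K integer vector of per-predictor harmonic counts (length p,
#'   recycled from a scalar); all entries must be >= 0.
#' @param rescale_cosine logical; map predictors to `[0, pi]` before the
#'   cosine transform (default `FALSE`).
#' @param ranges optional p x 2 matrix of (min, max) used for the rescaling;
#'   defaults to the observed column ranges.  Ignored unless
#'   `rescale_cosine = TRUE`.
#' @return An n x m numeric matrix, `m = 1 + p + sum(K)`, with attributes
#'   `orders` (the `K` used), `rescale_cosine` and `ranges`.
#' @examples
#' X <- cbind(x1 = runif(10, 0, 2 * pi), x2 = runif(10, 0, 2 * pi))
#' D <- fourier_design(X, K = c(2, 1))
#' colnames(D)
#' @export
fourier_design <- function(X, K, rescale_cosine = FALSE, ranges = NULL) {
  if (is.null(X) || (!is.null(dim(X)) && ncol(X) == 0L)) {
    n <- if (is.null(X)) 1L else nrow(X)
    out <- matrix(1, nrow = n, ncol = 1L, dimnames = list(NULL, "(Intercept)"))
    attr(out, "orders") <- integer(0)
    attr(out, "rescale_cosine") <- rescale_cosine
    attr(out, "ranges") <- matrix(numeric(0), ncol = 2L)
    return(out)
  }
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("predictors must be numeric")
  if (anyNA(X) || any(!is.finite(X))) stop("predictors contain missing or non-finite values")
  p <- ncol(X)
  if (length(K) == 1L) K <- rep(K, p)
  if (length(K) != p) {
    stop(sprintf("length of K (%d) does not match number of predictors (%d)",
                 length(K), p))
  }
  K <- as.integer(K)
  if (any(K < 0L)) stop("harmonic counts K must be non-negative")
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("x", seq_len(p))

  if (is.null(ranges)) {
    ranges <- cbind(apply(X, 2L, min), apply(X, 2L, max))
  }
  ranges <- matrix(as.numeric(ranges), ncol = 2L)

  n <- nrow(X)
  m <- 1L + p + sum(K)
  out <- matrix(0, nrow = n, ncol = m)
  labels <- character(m)
  out[, 1L] <- 1
  labels[1L] <- "(Intercept)"
  col <- 2L
  for (j in seq_len(p)) {
    xj <- X[, j]
    out[, col] <- xj
    labels[col] <- paste0("b:", nms[j])
    col <- col + 1L
    if (K[j] > 0L) {
      zj <- xj
      if (rescale_cosine) {
        lo <- ranges[j, 1L]; hi <- ranges[j, 2L]
        zj <- if (hi > lo) (xj - lo) / (hi - lo) * pi else rep(0, n)
      }
      for (k in seq_len(K[j])) {
        out[, col] <- cos(k * zj)
        labels[col] <- paste0("a", k, ":", nms[j])
        col <- col + 1L
      }
    }
  }
  colnames(out) <- labels
  attr(out, "orders") <- stats::setNames(K, nms)
  attr(out, "rescale_cosine") <- rescale_cosine
  attr(out, "ranges") <- ranges
  out
}

#' Flatten and unflatten structured coefficient sets
#'
#' The model's parameters have a natural block structure: an intercept `a0`,
#' one linear slope `b_j` per predictor, and `K[j]` cosine coefficients
#' `a_kj` per predictor.  Internally everything is a single flat named
#' vector aligned with the columns of [fourier_design()]; these helpers
#' convert between the two representations.  The mapping is a bijection:
#' `theta_pack(theta_unpack(v, K))` returns `v` unchanged.
#'
#' @param a0 scalar intercept.
#' @param b numeric vector of p linear slopes (named by predictor, or names
#'   supplied via `names`).
#' @param a list of p numeric vectors, `a[[j]]` holding the `K[j]` cosine
#'   coefficients of predictor j (may be length zero).
#' @param names optional character vector of predictor names.
#' @return `theta_pack()` returns the flat named vector of length
#'   `1 + p + sum(lengths(a))`; `theta_unpack()` returns a list with
#'   elements `a0`, `b`, `a`.
#' @examples
#' th <- theta_pack(0.5, b = c(x1 = 1, x2 = -1), a = list(c(0.3, 0.2), 0.1))
#' theta_unpack(th, K = c(2, 1))
#' @export
theta_pack <- function(a0, b = numeric(0), a = NULL, names = NULL) {
  p <- length(b)
  if (is.null(a)) a <- rep(list(numeric(0)), p)
  if (length(a) != p) stop("`a` must have one element per slope in `b`")
  if (is.null(names)) names <- if (!is.null(base::names(b))) base::names(b) else paste0("x", seq_len(p))
  out <- c(a0, unlist(lapply(seq_len(p), function(j) c(b[j], a[[j]]))))
  lab <- "(Intercept)"
  for (j in seq_len(p)) {
    lab <- c(lab, paste0("b:", names[j]),
             if (length(a[[j]])) paste0("a", seq_along(a[[j]]), ":", names[j]))
  }
  stats::setNames(as.numeric(out), lab)
}

#' @param theta flat named coefficient vector as produced by `theta_pack()`
#'   or a model fit.
#' @param K integer vector of harmonic counts, one per predictor.
#' @rdname theta_pack
#' @export
theta_unpack <- function(theta, K) {
  p <- length(K)
  m <- 1L + p + sum(K)
  if (length(theta) != m) {
    stop(sprintf("theta has length %d but K implies %d components", length(theta), m))
  }
  nms <- sub("^b:", "", grep("^b:", base::names(theta), value = TRUE))
  if (length(nms) != p) nms <- paste0("x", seq_len(p))
  a0 <- unname(theta[1L])
  b <- numeric(p)
  a <- vector("list", p)
  pos <- 2L
  for (j in seq_len(p)) {
    b[j] <- theta[pos]
    pos <- pos + 1L
    a[[j]] <- unname(theta[seq_len(K[j]) + pos - 1L])
    pos <- pos + K[j]
  }
  list(a0 = a0, b = stats::setNames(b, nms), a = stats::setNames(a, nms))
}
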