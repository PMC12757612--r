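# Independent oracles used to cross-check the package's analytic paths.
# These deliberately avoid the implementation under test: IRLS instead of
# Newton-Raphson, finite differences instead of analytic derivatives,
# all-pairs enumeration instead of rank statistics.

# Iteratively reweighted least squares for plain logistic regression.
# X must already contain the intercept column.
irls_logistic <- function(y, X, tol = 1e-12, max_iter = 100L) {
  beta <- numeric(ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    z <- eta + (y - p) / w
    beta_new <- drop(solve(crossprod(X, X * w), crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  V <- solve(crossprod(X, X * (p * (1 - p))))
  ll <- sum(y * log(p) + (1 - y) * log(1 - p))
  list(coef = unname(beta), se = unname(sqrt(diag(V))), vcov = unname(V),
       loglik = ll)
}

# Central finite-difference gradient of a scalar function.
fd_gradient <- function(f, theta, h = 1e-6) {
  vapply(seq_along(theta), function(i) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h
    tm[i] <- tm[i] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1L))
}

# Central finite-difference Hessian of a scalar function.
fd_hessian <- function(f, theta, h = 1e-4) {
  m <- length(theta)
  H <- matrix(0, m, m)
  for (i in seq_len(m)) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h
    tm[i] <- tm[i] - h
    H[i, i] <- (f(tp) - 2 * f(theta) + f(tm)) / h^2
    for (j in seq_len(m)[-seq_len(i)]) {
      tpp <- theta; tpm <- theta; tmp <- theta; tmm <- theta
      tpp[i] <- tpp[i] + h; tpp[j] <- tpp[j] + h
      tpm[i] <- tpm[i] + h; tpm[j] <- tpm[j] - h
      tmp[i] <- tmp[i] - h; tmp[j] <- tmp[j] + h
      tmm[i] <- tmm[i] - h; tmm[j] <- tmm[j] - h
      H[i, j] <- H[j, i] <- (f(tpp) - f(tpm) - f(tmp) + f(tmm)) / (4 * h^2)
    }
  }
  H
}

# All-pairs AUC with ties counted one half.
auc_bruteforce <- function(truth, probs) {
  pos <- probs[truth == 1]
  neg <- probs[truth == 0]
  total <- 0
  for (a in pos) {
    for (b in neg) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(pos) * length(neg))
}

# Small random logistic dataset with a random Fourier truth.
random_instance <- function(n = 40L, p = 2L, Kmax = 2L) {
  K <- sample.int(Kmax + 1L, p, replace = TRUE) - 1L
  X <- matrix(runif(n * p, 0, 2 * pi), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  design <- fourier_design(X, K)
  theta <- rnorm(ncol(design), 0, 0.7)
  y <- rbinom(n, 1L, predict_prob(design, theta))
  if (length(unique(y)) < 2L) y[1:2] <- c(0L, 1L)
  list(y = y, X = X, K = K, design = design, theta = theta)
}
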