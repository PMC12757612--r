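test_that("the simultaneous LRT has the right statistic, df and decisions", {
  sc <- fsnblr_scenario("strong_cosine", n = 400, seed = 20)
  fit <- fsnblr(y ~ x1 + x2, data = sc$data, K = c(2, 1))
  null <- fsnblr(y ~ 1, data = sc$data)
  lr <- lrt(fit, null)
  expect_equal(lr$G2, 2 * (fit$loglik - null$loglik))
  expect_equal(lr$df, 2 + 3)  # p + sum(K)
  expect_equal(lr$p_value, pchisq(lr$G2, lr$df, lower.tail = FALSE))
  expect_equal(lr$reject, lr$G2 > qchisq(0.95, lr$df))
  expect_equal(lr$reject, lr$p_value < 0.05)

  # a model compared with itself: G2 = 0, never rejected
  self <- lrt(fit, fit)
  expect_equal(self$G2, 0)
  expect_false(self$reject)

  # six predictors at a common K = 1: df = p (K + 1) = 12
  sc6 <- fsnblr_scenario("regional", seed = 21)
  fit6 <- fsnblr(y ~ x1 + x2 + x3 + x4 + x5 + x6, data = sc6$data, K = 1)
  expect_equal(lrt(fit6)$df, 12L)

  # mismatched data are rejected
  other <- fsnblr(y ~ 1, data = fsnblr_scenario("strong_cosine", n = 400, seed = 99)$data)
  expect_error(lrt(fit, other), "same data")
})

test_that("G2 of nested fits is non-negative over randomized instances", {
  set.seed(22)
  for (rep in 1:20) {
    inst <- random_instance(n = 150, p = 2, Kmax = 2)
    fit <- tryCatch(suppressWarnings(fsnblr_fit(inst$y, inst$X, K = inst$K)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    expect_gte(lrt(fit)$G2, -1e-8)
  }
})

test_that("Wald z, p-values and decisions follow the normal reference", {
  # z from a printed estimate/SE pair: -0.0414 / 0.0109
  w <- wald_stat(-0.0414, 0.0109)
  expect_equal(w$z, -3.80, tolerance = 0.01)
  expect_equal(w$p_value, 0.000145, tolerance = 5e-6 / 0.000145)
  expect_true(w$reject)

  # a zero estimate never rejects
  w0 <- wald_stat(0, 0.5)
  expect_equal(w0$z, 0)
  expect_equal(w0$p_value, 1)
  expect_false(w0$reject)

  # p-values equal 2 (1 - Phi(|z|)) by high-accuracy numerical integration
  set.seed(23)
  for (z in c(0.3, 1.2, 2.7, 3.9)) {
    w <- wald_stat(z, 1)
    tail <- integrate(dnorm, abs(z), Inf, rel.tol = 1e-13)$value
    expect_equal(w$p_value, 2 * tail, tolerance = 1e-10)
  }
  expect_error(wald_stat(1, 0), "positive")
})

test_that("wald_test covers every parameter of a fit and matches vcov diagonals", {
  sc <- fsnblr_scenario("strong_cosine", n = 500, seed = 24)
  fit <- fsnblr(y ~ x1 + x2, data = sc$data, K = c(2, 1))
  wt <- wald_test(fit)
  expect_equal(wt$label, names(coef(fit)))
  expect_equal(wt$se, unname(sqrt(diag(vcov(fit)))))
  expect_equal(wt$z, unname(coef(fit)) / wt$se)
  expect_equal(wt$reject, abs(wt$z) > qnorm(0.975))
})

test_that("predictor retention keys on the linear slopes and keeps harmonics wholesale", {
  # a Wald table with the published p-value pattern: only b of x2 and x6
  # fall below 0.05 among the slopes
  tab <- data.frame(
    label = c("(Intercept)", "b:x1", "a1:x1", "a2:x1", "a3:x1", "b:x2",
              "a1:x2", "a2:x2", "b:x3", "a1:x3", "b:x4", "a1:x4", "b:x5",
              "a1:x5", "b:x6", "a1:x6"),
    p_value = c(0.0146, 0.9685, 0.7689, 0.2280, 0.0760, 0.000001, 0.1160,
                0.1381, 0.2254, 0.1778, 0.2779, 0.3061, 0.5706, 0.2472,
                0.0183, 0.7959))
  tab$estimate <- 0; tab$se <- 1; tab$z <- 0; tab$reject <- tab$p_value < 0.05
  class(tab) <- c("fsnblr_wald", "data.frame")
  expect_equal(significant_predictors(tab, alpha = 0.05), c("x2", "x6"))

  # all slopes significant: nothing dropped
  tab2 <- tab
  tab2$p_value[startsWith(tab2$label, "b:")] <- 0.001
  expect_equal(significant_predictors(tab2, alpha = 0.05),
               paste0("x", 1:6))
  expect_error(significant_predictors(tab[0, ]), "empty")
})

test_that("test decisions are invariant to predictor ordering", {
  sc <- fsnblr_scenario("one_null_predictor", n = 600, seed = 25)
  f1 <- fsnblr(y ~ x1 + x2 + x3, data = sc$data, K = c(1, 1, 1))
  f2 <- fsnblr(y ~ x3 + x2 + x1, data = sc$data, K = c(1, 1, 1))
  w1 <- wald_test(f1)
  w2 <- wald_test(f2)
  expect_equal(lrt(f1)$G2, lrt(f2)$G2, tolerance = 1e-8)
  for (lab in w1$label) {
    expect_equal(w1$reject[w1$label == lab], w2$reject[w2$label == lab])
    expect_equal(w1$z[w1$label == lab], w2$z[w2$label == lab], tolerance = 1e-6)
  }
  expect_equal(sort(significant_predictors(w1)), sort(significant_predictors(w2)))
})
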