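test_that("AIC counts every coefficient including the intercept", {
  y <- rep(c(0, 1), 30)
  fit0 <- fsnblr_fit(y)
  expect_equal(AIC(fit0), 2 * 60 * log(2) + 2, tolerance = 1e-8)

  sc <- fsnblr_scenario("strong_cosine", n = 300, seed = 30)
  fit <- fsnblr(y ~ x1 + x2, data = sc$data, K = c(2, 1))
  m <- 1 + 2 + 3
  expect_equal(AIC(fit), -2 * fit$loglik + 2 * m, tolerance = 1e-10)
  expect_equal(AIC(fit), deviance(fit) + 2 * m, tolerance = 1e-10)
})

test_that("exhaustive order search equals a brute-force enumeration oracle", {
  sc <- fsnblr_scenario("strong_cosine", n = 400, seed = 31)
  y <- sc$data$y
  X <- as.matrix(sc$data[, c("x1", "x2")])

  sel <- select_orders(y ~ x1 + x2, data = sc$data, Kmax = 2)
  expect_equal(nrow(sel$grid), 4L)

  # independent enumeration: fit each combination directly, pick the min
  combos <- expand.grid(K1 = 1:2, K2 = 1:2)
  aics <- apply(combos, 1, function(K) {
    f <- fsnblr_fit(y, X, K = as.integer(K))
    -2 * f$loglik + 2 * f$df
  })
  expect_equal(sort(sel$grid$AIC), sort(aics), tolerance = 1e-8)
  best <- as.integer(combos[which.min(aics), ])
  expect_equal(unname(sel$best_K), best)
  expect_equal(sel$best_aic, min(aics), tolerance = 1e-8)

  # singleton space: p = 1, Kmax = 1
  sel1 <- select_orders(y ~ x1, data = sc$data, Kmax = 1)
  expect_equal(nrow(sel1$grid), 1L)
  expect_equal(unname(sel1$best_K), 1L)
})

test_that("greedy search never beats the exhaustive optimum", {
  for (seed in 32:34) {
    sc <- fsnblr_scenario("strong_cosine", n = 300, seed = seed)
    ex <- select_orders(y ~ x1 + x2, data = sc$data, Kmax = 3, mode = "exhaustive")
    gr <- select_orders(y ~ x1 + x2, data = sc$data, Kmax = 3, mode = "greedy")
    expect_lte(ex$best_aic, gr$best_aic + 1e-10)
  }
})

test_that("the best entry is the converged argmin under the stated tie-break", {
  sc <- fsnblr_scenario("strong_cosine", n = 300, seed = 35)
  sel <- select_orders(y ~ x1 + x2, data = sc$data, Kmax = 3)
  g <- sel$grid[sel$grid$converged, ]
  expect_equal(sel$best_aic, min(g$AIC), tolerance = 1e-12)
  expect_true(all(sel$best_aic <= g$AIC + 1e-12))
  expect_error(select_orders(y ~ x1 + x2, data = sc$data, Kmax = 200),
               "guard")
})

test_that("the significant-predictor refit reproduces the two-stage workflow", {
  # strong truth in both predictors: the predictor set must survive intact
  sc <- fsnblr_scenario("strong_cosine", n = 800, seed = 36)
  fit <- fsnblr(y ~ x1 + x2, data = sc$data, K = c(2, 1))
  red <- refit_significant(fit, Kmax = 2)
  expect_equal(sort(attr(red, "retained")), c("x1", "x2"))
  expect_true(red$converged)

  # intercept-only world: nothing significant, warn and fall back to the null
  scn <- fsnblr_scenario("null_model", n = 400, seed = 37)
  fit0 <- fsnblr(y ~ x1 + x2, data = scn$data, K = c(1, 1))
  wt <- wald_test(fit0)
  if (length(significant_predictors(wt)) == 0) {
    expect_warning(red0 <- refit_significant(fit0), "no significant")
    expect_equal(red0$model_kind, "intercept_only")
  }

  # a truly null third predictor is usually dropped
  scp <- fsnblr_scenario("one_null_predictor", n = 2000, seed = 38)
  fitp <- fsnblr(y ~ x1 + x2 + x3, data = scp$data, K = c(1, 1, 1))
  redp <- refit_significant(fitp, Kmax = 2)
  expect_true(all(attr(redp, "retained") %in% c("x1", "x2")))
})

test_that("VIF matches the least-squares definition and its invariances", {
  set.seed(39)
  # exactly orthogonal centered predictors: all VIF = 1
  M <- qr.Q(qr(scale(matrix(rnorm(200), 50, 4), center = TRUE, scale = FALSE)))
  v <- vif(M)
  expect_equal(v$vif, rep(1, 4), tolerance = 1e-6)

  # exact collinearity is flagged as infinite
  X <- cbind(x1 = runif(60), x2 = runif(60))
  X2 <- cbind(X, x3 = 2 * X[, "x1"])
  v2 <- vif(X2)
  expect_true(is.infinite(v2$vif[v2$variable == "x1"]))
  expect_true(is.infinite(v2$vif[v2$variable == "x3"]))
  expect_true(all(v2$high[is.infinite(v2$vif)]))

  # random matrix: matches 1 / (1 - R^2) from an independent lm() solve
  Z <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("x", 1:4)))
  Z[, 2] <- Z[, 1] * 0.8 + rnorm(100, 0, 0.5)
  vz <- vif(Z)
  for (j in 1:4) {
    r2 <- summary(lm(Z[, j] ~ Z[, -j]))$r.squared
    expect_equal(vz$vif[j], 1 / (1 - r2), tolerance = 1e-8)
  }

  # invariant under per-predictor affine rescaling
  Zs <- sweep(sweep(Z, 2, c(1, -2, 3, 100), "*"), 2, c(5, 0, -1, 2), "+")
  expect_equal(vif(Zs)$vif, vz$vif, tolerance = 1e-8)

  expect_error(vif(Z[, 1, drop = FALSE]), "two predictors")
  expect_error(vif(Z[1:3, ]), "more observations")
})
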