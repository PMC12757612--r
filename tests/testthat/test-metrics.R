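test_that("deviance has its closed forms and ties to AIC", {
  y <- rep(c(0, 1), 40)
  fit <- fsnblr_fit(y)
  expect_equal(deviance(fit), 2 * 80 * log(2), tolerance = 1e-8)

  set.seed(40)
  for (rep in 1:5) {
    inst <- random_instance(n = 120, p = 2, Kmax = 1)
    f <- tryCatch(suppressWarnings(fsnblr_fit(inst$y, inst$X, K = inst$K)),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) next
    expect_equal(deviance(f), AIC(f) - 2 * f$df, tolerance = 1e-10)
    expect_gte(deviance(f), 0)
  }
})

test_that("deviance weakly decreases as a nested model is expanded", {
  sc <- fsnblr_scenario("strong_cosine", n = 500, seed = 41)
  y <- sc$data$y
  X <- as.matrix(sc$data[, c("x1", "x2")])
  d <- c(deviance(fsnblr_fit(y)),
         deviance(fsnblr_fit(y, X, K = 0)),
         deviance(fsnblr_fit(y, X, K = c(1, 1))),
         deviance(fsnblr_fit(y, X, K = c(2, 1))))
  expect_true(all(diff(d) <= 1e-8))
})

test_that("classification at a cutoff tallies the confusion matrix correctly", {
  # trivial: confident correct predictions
  r <- classify(rep(0.7, 5), rep(1, 5))
  expect_equal(r$confusion["1", "1"], 5)
  expect_equal(sum(r$confusion), 5)

  # the boundary case: probability exactly at the cutoff is labelled 1
  expect_equal(classify(0.5, 0)$pred, 1L)

  # brute-force tally on a random instance
  set.seed(42)
  probs <- runif(50)
  truth <- rbinom(50, 1, 0.5)
  r <- classify(probs, truth)
  for (t in 0:1) for (q in 0:1) {
    expect_equal(r$confusion[t + 1, q + 1],
                 sum(truth == t & as.integer(probs >= 0.5) == q))
  }
  expect_error(classify(runif(3), c(0, 1)), "length")
  expect_error(classify(c(0.2, 1.4), c(0, 1)), "0, 1")
})

test_that("confusion metrics reproduce the imbalanced worked example and edge cases", {
  # 177 majority-class cases with 165 correct, 55 minority with 30 correct
  cm <- matrix(c(165, 12, 25, 30), 2, 2, byrow = TRUE,
               dimnames = list(truth = c("0", "1"), predicted = c("0", "1")))
  m <- confusion_metrics(cm)
  expect_equal(100 * m$accuracy, 84.05, tolerance = 0.005)
  expect_equal(100 * m$sensitivity, 93.22, tolerance = 0.005)
  expect_equal(100 * m$specificity, 54.54, tolerance = 0.01)
  expect_equal(m$positive, "0")  # majority class

  # everything correct
  all_right <- confusion_metrics(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(all_right$accuracy, 1)
  expect_equal(all_right$sensitivity, 1)
  expect_equal(all_right$specificity, 1)

  # random tables match direct ratios; accuracy * n = TP + TN exactly
  set.seed(43)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 20), 2, 2)
    mm <- confusion_metrics(tab, positive = "1")
    expect_equal(mm$accuracy, (tab[1, 1] + tab[2, 2]) / sum(tab), tolerance = 1e-12)
    expect_equal(mm$sensitivity, tab[2, 2] / sum(tab[2, ]), tolerance = 1e-12)
    expect_equal(mm$accuracy * sum(tab), tab[1, 1] + tab[2, 2], tolerance = 1e-9)
  }

  # empty class reports NA, not zero
  na_case <- confusion_metrics(matrix(c(5, 2, 0, 0), 2, 2, byrow = TRUE),
                               positive = "1")
  expect_true(is.na(na_case$sensitivity))
})

test_that("rank-based AUC equals all-pairs enumeration and is monotone-invariant", {
  expect_equal(auc_mw(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc_mw(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)

  set.seed(44)
  for (rep in 1:10) {
    truth <- c(rep(0, 10), rep(1, 10))[sample(20)]
    probs <- round(runif(20), 2)  # rounding forces some ties
    a <- auc_mw(truth, probs)
    expect_equal(a, auc_bruteforce(truth, probs), tolerance = 1e-12)
    # strictly monotone transform leaves the AUC unchanged
    expect_equal(auc_mw(truth, plogis(5 * probs - 1)), a, tolerance = 1e-12)
  }
  expect_error(auc_mw(rep(1, 5), runif(5)), "both classes")
})

test_that("Press's Q has its closed forms and symmetry about chance", {
  expect_equal(press_q(195, 232), 107.6034, tolerance = 5e-5)
  expect_equal(press_q(100, 100), 100)       # all correct, 2 groups: Q = N
  expect_equal(press_q(116, 232), 0)          # exactly chance level
  # symmetric in n_correct about N/2 for two groups
  expect_equal(press_q(150, 232), press_q(2 * 116 - 150, 232))
  expect_equal(press_q(140, 200), press_q(60, 200))
  expect_error(press_q(10, 5), "invalid")
})

test_that("classification_report and compare_models compose the elementary metrics", {
  sc <- fsnblr_scenario("strong_cosine", n = 500, seed = 45)
  y <- sc$data$y
  X <- as.matrix(sc$data[, c("x1", "x2")])
  blr <- fsnblr_fit(y, X, K = 0)
  fs <- fsnblr_fit(y, X, K = c(2, 1))

  rep_fs <- classification_report(y, fs$fitted.values)
  cl <- classify(fs$fitted.values, y)
  expect_equal(rep_fs$confusion, cl$confusion)
  expect_equal(rep_fs$auc, auc_mw(y, fs$fitted.values))
  expect_equal(rep_fs$press_q,
               press_q(sum(diag(cl$confusion)), length(y)))

  cmp <- compare_models(list(BLR = blr, FSNBLR = fs))
  expect_equal(nrow(cmp), 2L)
  expect_equal(cmp$deviance, c(deviance(blr), deviance(fs)))
  expect_equal(cmp$auc[2], rep_fs$auc)
  # the Fourier model nests the linear one: its deviance cannot be larger
  expect_lte(cmp$deviance[2], cmp$deviance[1] + 1e-8)
  expect_true(cmp$best_deviance[2])

  # identical models tie on every flag
  cmp2 <- compare_models(list(a = fs, b = fs))
  expect_true(all(cmp2$best_deviance))
  expect_true(all(cmp2$best_auc))
  expect_error(compare_models(list(one = fs)), "at least two")
})
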