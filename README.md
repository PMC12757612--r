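# fsnblr

Fourier series nonparametric binary logistic regression (FSNBLR) in R:
flexible logistic modelling of a binary outcome when the effect of a
continuous predictor on the log-odds may be nonlinear or oscillatory —
for example, classifying administrative regions as underdeveloped from
socioeconomic indicators, where grouped-data plots often show repetitive
rising patterns that a straight line in the logit cannot capture.

## The model

For a binary response `Y_i ~ Bernoulli(pi(x_i))` and p continuous
predictors, the success probability is modelled as

    logit pi(x_i) = a0 + sum_j [ b_j x_ji + sum_{k=1}^{K_j} a_kj cos(k x_ji) ]

Each predictor contributes a linear term plus a truncated cosine series;
the per-predictor harmonic count `K_j` (the "oscillation parameter")
controls how wiggly that component may be.  `K_j = 0` for every predictor
recovers plain binary logistic regression (BLR), so the familiar model is a
strict special case.

The package provides, all authored here:

* **Estimation** — Newton–Raphson maximum likelihood with the analytic
  score `X'(y - pi)` and observed Hessian `-X'WX`, step-halving, and
  coefficient covariance from the inverse observed information
  (`fsnblr()`, `fsnblr_fit()`).
* **Inference** — the simultaneous likelihood-ratio test
  `G2 = 2[L(full) - L(null)] ~ chi2_{p + sum K_j}` and per-parameter Wald
  tests `z = estimate / SE` (`lrt()`, `wald_test()`, `summary()`).
* **Order selection** — exhaustive (or greedy) AIC search over
  `K in {1..Kmax}^p` and the two-stage significant-predictor refit
  (`select_orders()`, `refit_significant()`).
* **Diagnostics** — VIF screen, deviance, confusion-matrix metrics at a
  0.5 cutoff, rank-based AUC, Press's Q, and model comparison tables
  (`vif()`, `classification_report()`, `compare_models()`).
* **Synthetic data** — seeded scenario generators with known truth,
  including a preset shaped like the motivating regional study (n = 232,
  six predictors, ~24% positive class) (`fsnblr_scenario()`).
* **Workflow** — `run_fsnblr_pipeline()` runs VIF → BLR → order search →
  FSNBLR → significant refit → comparison, writing JSON/TSV reports; a
  thin CLI lives in `inst/cli/fsnblr-cli.R`.

## Worked example

```r
library(fsnblr)

sc  <- fsnblr_scenario("strong_cosine", n = 500, seed = 3)  # known truth K = (2,1)
fit <- fsnblr(y ~ x1 + x2, data = sc$data, K = c(2, 1))
summary(fit)
#>   Parameters Estimations Std. Error z value Pr(>|z|)          Decision
#>  (Intercept)     -0.1643     0.3105  -0.529 5.97e-01 fail to reject H0
#>         b:x1      0.4943     0.0823   6.005 1.91e-09         reject H0
#>        a1:x1      1.7492     0.2113   8.279 1.24e-16         reject H0
#>        a2:x1      1.1569     0.1860   6.220 4.96e-10         reject H0
#>         b:x2     -0.1992     0.0630  -3.162 1.57e-03         reject H0
#>        a1:x2      1.1779     0.1686   6.987 2.80e-12         reject H0
#>
#> n = 500, parameters = 6, log-likelihood = -241.0125
#> Deviance: 482.0249   AIC: 494.0249
#> Simultaneous LRT: G2 = 196.9431 on 5 df, p = 1.28e-40 (reject H0 at alpha = 0.05)
```

Every slope and harmonic is detected (the intercept's true value here is
0.3, well inside its interval), and the simultaneous test overwhelmingly
rejects the intercept-only null.  The AIC search recovers the generating
orders:

```r
select_orders(y ~ x1 + x2, data = sc$data, Kmax = 2)
#> AIC order selection (exhaustive mode, Kmax = 2, 4 combinations)
#>  x1 x2      AIC converged
#>   2  1 494.0249     TRUE
#>   2  2 495.7313     TRUE
#>   1  1 536.8087     TRUE
#>   1  2 538.8069     TRUE
#> Best: K = (2,1), AIC = 494.0249
```

## Acceptance script

`scripts/acceptance.R` exercises the installed package end to end: it
generates the `regional` synthetic scenario at the given seed and runs the
complete pipeline (VIF screen, BLR fit and Wald screen, exhaustive AIC
order search with `Kmax = 3`, the Fourier fit with simultaneous LRT and
Wald tables, the significant-predictor refits, and the model-comparison
table), then writes the JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
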