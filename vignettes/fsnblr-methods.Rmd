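---
title: "Methods: Fourier-series nonparametric binary logistic regression"
author: "fsnblr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Fourier-series nonparametric binary logistic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model and its assumptions

Let $Y_i \sim \mathrm{Bernoulli}(\pi(\mathbf{x}_i))$ independently, with
$p$ continuous predictors.  The package models the log-odds additively,
each predictor contributing a linear term plus a truncated cosine series:

$$
\operatorname{logit} \pi(\mathbf{x}_i)
  = a_0 + \sum_{j=1}^{p}\Bigl( b_j x_{ji}
  + \sum_{k=1}^{K_j} a_{kj}\cos(k\,x_{ji}) \Bigr).
$$

The harmonic count $K_j$ ("oscillation parameter") governs how much
oscillatory structure predictor $j$ may carry; $K_j = 0$ leaves it linear,
so plain binary logistic regression (BLR) and the intercept-only null model
are strict special cases.  The assumptions are the usual ones: independent
observations (no spatial or panel dependence), correctly coded 0/1
response, and predictors measured without error.

Two modelling choices deserve comment because the additive cosine
formulation leaves them open:

* **One intercept.** Written naively, an additive Fourier expansion gives
  every predictor its own constant term $\tfrac12 a_{0j}$; these $p$
  constants are perfectly collinear and would make the Hessian singular by
  construction.  The package therefore estimates a single intercept $a_0$.
* **Cosine argument scale.** By default cosines are taken of the *raw*
  predictor values, which is what reported coefficient sets of this model
  family assume.  When a predictor spans hundreds of units, $\cos(kx)$
  oscillates extremely fast in raw units and the harmonic behaves like a
  high-frequency probe rather than a smooth component.  For that situation
  `rescale_cosine = TRUE` first maps each predictor linearly onto
  $[0, \pi]$ (training ranges are stored and reused for prediction).  The
  default stays raw because that is the convention the model's published
  coefficient sets use; which behaviour is scientifically preferable is
  genuinely open and both are exposed.

## Estimation

The log-likelihood $L(\theta) = \sum_i [y_i \eta_i - \log(1 + e^{\eta_i})]$
is maximized by Newton–Raphson using the exact analytic derivatives
$g(\theta) = X^\top(y - \pi)$ and $H(\theta) = -X^\top W X$ with
$W = \mathrm{diag}(\pi_i(1 - \pi_i))$:

$$\theta^{(t+1)} = \theta^{(t)} - H^{-1}(\theta^{(t)})\, g(\theta^{(t)}).$$

Numerical choices:

* **Initialization** $\theta^{(0)} = 0$, i.e. fitted probabilities $1/2$ —
  a well-conditioned start at which $H = -X^\top X/4$.  Fits are fully
  deterministic given data and options.
* **Convergence** when the max-abs coefficient change falls below
  $\varepsilon = 10^{-6}$ (the $\infty$-norm reading of a componentwise
  criterion) *and* the score is numerically zero (max-abs $< 10^{-6}$),
  with `max_iter = 100`.
* **Step-halving.** A full Newton step that would lower the log-likelihood
  is halved (up to 30 times); accepted steps therefore never decrease the
  log-likelihood, which the test suite asserts on every fit.
* **Ill-conditioning.** If the Newton system is numerically singular the
  information matrix gets a transient ridge ($10^{-8}$ times its mean
  diagonal); the reported covariance is always computed from the
  *unregularized* Hessian at the optimum, or refused if that is singular.
* **Overflow.** Probabilities are evaluated with the stable logistic form
  and clamped into the open unit interval, keeping the likelihood finite
  for quasi-separable configurations; complete separation is detected
  (log-likelihood near 0 with diverging coefficients) and flagged rather
  than reported as convergence.
* **Rank.** A rank-deficient design is refused up front, naming the
  offending columns.

The coefficient covariance is the inverse observed information
$-[H(\hat\theta)]^{-1}$.

## Inference

**Simultaneous test.** $G^2 = 2[L(\hat\theta_{\text{full}}) -
L(\hat\theta_{\text{null}})]$ against the intercept-only null, which is
*re-estimated* ($\hat a_0 = \operatorname{logit}\bar y$) — the standard
likelihood-ratio construction; the alternative reading that fixes the null
intercept at the full-model value is not used.  Under the null $G^2$ is
asymptotically $\chi^2$ with degrees of freedom equal to the number of
constrained parameters, $p + \sum_j K_j$ — this reduces to the textbook
$p(K+1)$ when all $K_j = K$ and remains correct for unequal orders.  The
acceptance suite verifies both the 5% size (empirical rate 0.047 at
$n = 500$, 1000 replicates) and the $\chi^2_4$ shape of the simulated
$G^2$ distribution (Kolmogorov–Smirnov).

**Partial tests.** For every coefficient, $z = \hat\theta_r /
\widehat{\mathrm{SE}}_r$ with the SE from the covariance diagonal,
referred to N(0, 1) two-sided; 95% intervals built this way cover the
generating truth at rate 0.954 in the well-specified simulation.  No
multiple-testing correction is applied — a deliberate caveat, matching the
workflow this package reproduces.

**Retention rule.** A predictor is kept when its *linear slope* $b_j$
rejects; all harmonics of a kept predictor are retained wholesale
(hierarchical retention), and the reduced model's orders are re-selected
by AIC on the reduced predictor set.

## Order selection and its limits

$\mathrm{AIC} = -2L + 2m$ with $m = 1 + p + \sum_j K_j$ (the intercept is
counted; the standard definition).  The default search is exhaustive over
$\{1,\dots,K_{\max}\}^p$ with $K_{\max} = 3$ — at $p = 6$ that is $3^6 =
729$ fits, done in seconds — guarded at 20 000 combinations, with a greedy
coordinate-ascent mode for larger $p$.  Unconverged combinations are
recorded and excluded from the argmin; ties break toward the smaller
$\sum K_j$, then lexicographically.

A property worth stating plainly: AIC minimization does **not** select the
true orders with probability approaching 1.  When the truth is nested in
the search space, an extra junk harmonic is retained whenever its deviance
improvement exceeds 2, which happens with asymptotic probability
$P(\chi^2_1 > 2) \approx 0.157$ per candidate.  For a $(2,1)$ truth inside
$\{1,2,3\}^2$ the joint probability of exact recovery is therefore about
0.62 *at any sample size* — the package's measured rate at $n = 3000$ —
and no strength of signal raises it.  The acceptance suite pins the
exhaustive search to an independent enumeration oracle exactly, and
documents this ceiling where a higher recovery rate is asserted.

## Classification metrics

At the (configurable) cutoff 0.5, an observation with predicted
probability exactly equal to the cutoff is classified as 1 — the boundary
must be fixed somewhere for determinism.  Accuracy, sensitivity and
specificity come from the 2×2 confusion matrix; because the motivating
application reports its "sensitivity" for the *majority* class of an
imbalanced problem, the default orientation (`positive = "majority"`)
follows that arithmetic, and the orientation is an explicit argument.
Empty classes yield `NA`, never a silent 0.  The AUC is the rank-based
Mann–Whitney statistic (ties counted one half), invariant under monotone
transforms of the scores.  Press's Q,
$(N - nK)^2 / (N(K-1))$ for $n$ correct of $N$ in $K$ groups, is compared
against $\chi^2_{1}$.  Deviance is $-2L$ (ungrouped binary data: the
saturated log-likelihood is 0).  All metrics are in-sample, as in the
workflow being reproduced; no cross-validation is offered.

## Synthetic worlds

The generators state complete data-generating processes so that every
inferential claim can be scored against a known truth:

* `regional` — the shape of the motivating study: $n = 232$, six
  predictors drawn uniformly over the empirical min–max ranges (three
  percentage scales on $[0,100]$, an enrollment rate on $[8.25, 94.92]$,
  two per-capita fiscal scales up to $\approx 589$), truth orders
  $(3,2,1,1,1,1)$ with the published coefficient magnitudes, and the
  intercept re-calibrated by bisection so the expected positive fraction
  is $55/232 \approx 0.237$ (tolerance 0.01).  Uniform marginals are a
  choice — only summary statistics of the real predictors are public — and
  a truncated-normal mode exists for matching means/variances instead.
* `null_model` — two predictors on $[0, 2\pi]$, intercept-only truth: the
  world of the simultaneous-test null.
* `blr_only` — three linear-only predictors on $[-2, 2]$ with moderate
  slopes $(0.8, -0.6, 0.4)$: the IRLS-comparable special case.
* `strong_cosine` — two predictors on $[0, 2\pi]$, orders $(2,1)$, cosine
  amplitudes $\ge 1$: strong, well-specified oscillatory signal for
  recovery, coverage and selection studies.  The $[0, 2\pi]$ support makes
  the harmonics near-orthogonal, the cleanest case for such studies.
* `one_null_predictor` — as above plus a predictor with zero effect, for
  selection-consistency checks.

Predictors are drawn independently (the screened real data show no
multicollinearity; correlated draws are for stress tests only), and
everything is deterministic given the seed.  What a green simulation test
does *not* establish: behaviour under dependent observations, measurement
error, misspecified link, or predictors whose raw-scale cosines alias the
sampling grid — none of which the generator emulates.

## Known limitations

* Inference is asymptotic; no small-sample or resampling corrections.
* No confidence-interval machinery beyond Wald intervals.
* Cosine-only basis: no sine terms, splines, interactions, or multinomial
  responses.
* In-sample classification metrics only.
* The AIC search's exact-recovery ceiling discussed above.
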