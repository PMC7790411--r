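---
title: "A ladder of survival models for clustered implant-complication data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A ladder of survival models for clustered implant-complication data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailladder)
```

## The problem

Dental implants are clustered within patients: one patient may carry up to a
dozen implants, and complications (implant loss, peri-implantitis, technical
failures) on different implants of the same patient are correlated because
they share that patient's anatomy, susceptibility and behaviour. Analysing
such time-to-event data as if records were independent understates
uncertainty and can bias effect estimates. The standard remedy is a *shared
frailty*: an unobserved positive factor, one per patient, that multiplies
the hazard of every record in the cluster. Here frailties are gamma
distributed with mean 1 and variance $\theta$; $\theta = 0$ means no
clustering effect.

`frailladder` fits and compares a ladder of survival regression models for
such data — from the semiparametric Cox model, through fully parametric
families, to flexible parametric (spline-based) models — each with and
without shared gamma frailty, and selects among them by AIC/BIC with a
spline-significance screen.

## The models

**Cox proportional hazards.** $h(t \mid x) = h_0(t) e^{x\beta}$, estimated
by maximizing the Breslow-form partial log-likelihood over risk sets
$R_j = \{k : t_{0k} < t_{(j)} \le t_k\}$ (delayed entry is honoured; ties
use the Breslow approximation, the form in which the partial likelihood is
usually written — the paper trail for the implemented formulas is the
standard survival-analysis literature). The baseline cumulative hazard is
the Breslow estimator. With shared gamma frailty, the cluster log-frailties
$v_i$ enter as offsets; for fixed $\theta$ the penalized partial likelihood
in $(\beta, v)$ is maximized by an EM iteration whose E-step replaces each
cluster's frailty with its posterior mean
$(1/\theta + D_i)/(1/\theta + A_i)$ ($D_i$ = events, $A_i$ = accumulated
hazard in cluster $i$), and $\theta$ is then estimated by Brent search of
the profile marginal log-likelihood on the $\log\theta$ scale over
$[10^{-6}, 10]$ with tolerance $10^{-6}$.

**Parametric families.** Exponential and Weibull in both proportional
hazards (PH) and accelerated failure time (AFT) form; log-logistic,
log-normal and generalized gamma in AFT form only. Each family contributes
$d \log h(t) + \log S(t)$ per record. Two random-effect mechanisms mirror
the two parameterizations: PH families take the hazard-multiplicative
mean-1 gamma frailty, whose cluster marginal has the closed form
$$\Big[\prod_j h_j^{d_j}\Big]\,
  \frac{\Gamma(1/\theta + D)}{\Gamma(1/\theta)}\,\theta^{D}
  \,(1 + \theta \textstyle\sum_j H_j)^{-(1/\theta + D)},$$
and AFT families take a normal random intercept on log time, marginalized
by 15-node *adaptive* Gauss–Hermite quadrature (each cluster's integrand is
re-centered at its posterior mode and re-scaled by the curvature there; a
non-adaptive rule was measurably inaccurate for event-rich clusters). The
gamma-ratio terms are evaluated as $\sum_{k=0}^{D-1}\log(1+k\theta)$, which
is exact for integer event counts and stays accurate as
$\theta \rightarrow 0$, where the naive `lgamma` difference cancels
catastrophically.

**Flexible parametric (Royston–Parmar).** The log cumulative hazard is a
restricted cubic spline of log time plus covariate effects:
$\ln H(t \mid x) = s(\ln t \mid \gamma, k_0) + x\beta$. With `df` degrees
of freedom the basis is $\{\ln t\}$ plus `df − 1` curvature terms
$z_j = (x-k_j)_+^3 - \phi_j (x-k_1)_+^3 - (1-\phi_j)(x-k_k)_+^3$,
$\phi_j = (k_k - k_j)/(k_k - k_1)$, with internal knots at the centiles
$100j/\mathrm{df}$ of the uncensored log event times and boundary knots at
their extremes. `df = 1` *is* the Weibull PH model — an identity the test
suite asserts to $10^{-4}$ on every synthetic cohort. Each record
contributes $d(\ln s'(\ln t) + \eta - \ln t) - e^{\eta}$; the $-d\ln t$
term makes the reported likelihood the true hazard-based one, directly
comparable with the parametric families. Shared gamma frailty uses the same
closed-form cluster marginal with $H = e^{\eta}$. Optimization is BFGS with
analytic gradients for all parameters (including $\log\theta$), warm-started
from a regression of the Kaplan–Meier log cumulative hazard on the basis.
Monotonicity of $\hat H$ is not hard-constrained — matching common
practice — but is diagnosed after the fit: a warning reports any event time
with $s' \le 0$, and optimization rejects such regions through a smooth
penalty.

**Orthogonalization.** The curvature columns are near-collinear with
$\ln t$; by default they are orthogonalized (QR, numerically equivalent to
Gram–Schmidt) against the intercept and each other over the uncensored log
times, with the invertible transform stored on the basis. The fit is
invariant to this choice (tested to $10^{-6}$), so whether the linear term
is included in the sweep is immaterial to reported likelihoods; reported
`_rcs` spline slopes are on the orthogonalized scale, as is conventional.

## Model selection

`aic(ll, k)` and `bic(ll, k, n)` use $-2\ell + 2k$ and $-2\ell + k\ln n$
with $k$ the number of *freely estimated* parameters, counting ancillary,
spline and frailty terms. The effective sample size $n$ is a visible
argument (default: number of records) rather than a hidden constant,
because its choice — records, patients or events — changes the BIC penalty
materially and published comparison tables are often not explicit about it.

`select_best()` picks the minimum-BIC row; when the winner is a flexible
model, fits whose AIC is within a relative near-tie tolerance (default
0.1%, matching the view that sub-0.1% AIC changes are negligible) are
re-screened: extra spline curvature is accepted only when *every* added
slope is significant at 0.05, otherwise the simpler df stands.

One property the ladder does **not** have: likelihoods need not increase
monotonically in `df`. The knots move with `df`, so the bases are not
nested; only the `df = 1` (Weibull) rung is a guaranteed floor, because
every basis contains $\{1, \ln t\}$. Empirically the dips are tiny (of
order $10^{-2}$ log-likelihood units; an independent spline-survival
implementation shows the same behaviour on the same data), and the tests
assert exactly that corrected property: an exact Weibull floor plus a
small-dip bound between higher rungs.

## The synthetic cohort generator

Because the motivating study's patient records are not public, every test
runs on seeded synthetic cohorts whose *defaults are fixed once* at the
study's published scale:

* 595 patients; covariate margins at the study's observed distribution
  (periodontal status 60/24/16%, extent of treatment, age bands, sex,
  smoking, implant product, retention);
* true hazard ratios at the study's adjusted estimates (periodontitis
  1.449, full-jaw 4.641, partial-jaw 2.338, male 1.272, ...);
* ~4 ± 2.8 implants per patient, truncated to 1–12, when the per-implant
  expansion is requested (the frailty-recovery scenarios);
* administrative censoring at 3287 days (~9 years);
* patient-level gamma frailty with $\theta = 0.5$ — the study never prints
  its estimated frailty variance, so this is a scenario parameter chosen as
  a moderate, clinically plausible degree of clustering, not a published
  value;
* a Weibull baseline ($\lambda = 1.377 \times 10^{-4}$, shape 0.967)
  calibrated once, semi-analytically, so that the marginal cohort
  reproduces the study's two printed Kaplan–Meier anchors (25% survival at
  820 days, median at 2476 days). The study's printed totals are not fully
  mutually consistent — 469 events among 595 subjects would put 79% of
  subjects past their first event, yet the printed 75% quantile is "cannot
  be computed", and the printed person-time equals the full follow-up
  horizon for every subject, i.e. observation continued beyond the first
  event. The quartile anchors pin the survival curve itself and were
  therefore chosen as the calibration targets; the resulting single-failure
  incidence (~0.00027/day) brackets the printed 0.000241/day.

Event times are drawn by inverse transform: $T = H_0^{-1}(E/(\alpha
e^{x\beta}))$ with $E$ standard exponential and $\alpha$ the cluster
frailty, so the generated data satisfy the proportional-hazards and
frailty assumptions of the models *exactly*. That is what passing recovery
tests demonstrate: correct estimation under the assumed model, not
robustness to real-data features the generator does not emulate —
covariate dependence (edentulous patients necessarily have full-jaw
restorations in reality; a joint table can be supplied), informative
dropout, recurrent events, or measurement error in event timing.
`calibrate_baseline()` computes the marginal survival exactly by
enumerating covariate-level combinations (the margins are independent) and
integrating the frailty in closed form, then solves the two-target
calibration by nested root finding; infeasible target pairs produce an
error listing the feasible region.

## Numerical choices

* Cox Newton iteration: gradient tolerance $10^{-8}$ relative, 100
  iterations, step halving; risk-set sums via two cumulative sums (by exit
  and by entry order), $O(n \log n)$.
* Frailty EM: penalized-likelihood change below $10^{-8}$ and frailty
  movement below $10^{-6}$; warm starts across the outer $\theta$ search.
* Spline fits: BFGS, relative tolerance $10^{-12}$, analytic gradients;
  covariance from a finite-difference Hessian of the analytic gradient.
* Ties between events and censorings at the same time: events first (the
  censored record stays in the risk set), the standard product-limit
  convention; the source analyses do not state a convention.
* Quantile survival times: smallest observed event time with
  $S(t) \le 1-q$, no interpolation; the "cbc" (cannot be computed) sentinel
  appears whenever the curve never reaches $1-q$.
* The proportional-hazards check is the Grambsch–Therneau global score test
  on scaled Schoenfeld residuals with the identity time transform, with an
  explicit column subset: the published test has 4 degrees of freedom
  against 14 model columns, and which covariates were tested is not
  recoverable, so the choice is the caller's.
* Degenerate inputs: empty cohorts, non-positive intervals, unknown factor
  levels, single-cluster frailty requests, and infeasible knot placements
  are rejected with specific errors; constant covariate columns are dropped
  with a warning rather than producing a singular fit.

## Problem sizes used by the test-suite

The simulation-backed tests run at the sizes a desk check affords, chosen
as the package's own trade-off between Monte-Carlo error and runtime:
equivalence checks on 20 cohorts of 300 patients; parameter recovery on
200 replicates of the full 595-cluster per-implant design (with matched
frailty-free replicates); type-I-error calibration of the proportionality
test on 500 cohorts of 150 patients with a reduced covariate set; and
selection behaviour on 100 seeds of 250-cluster cohorts generated from a
df = 2 spline truth with genuine curvature.

## Known limitations

* Left truncation is supported for frailty-free likelihoods only; frailty
  plus delayed entry is rejected (the conditional-likelihood correction
  interacts with the frailty posterior and the motivating data enter at
  time zero).
* The flexible model offers the log-cumulative-hazard (PH) scale only; no
  proportional-odds or probit variants, and no time-dependent effects.
* Recurrent events are out of scope: analyses are single-failure per
  subject (first complication), with the per-implant expansion available
  for clustering structure, not for within-implant recurrences.
* The "gamma" family is the generalized gamma in AFT form, the convention
  of the software tradition the comparison grid descends from.
* AFT coefficient tables report time ratios, not hazard ratios; the
  `scale` column of `summary_table()` says which is which.
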