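# frailladder

Comparative survival modelling of clustered time-to-event data with shared
frailty, built around the kind of question dental-implant epidemiology
raises: complications occur on implants that are clustered within patients,
so which survival regression model — Cox, parametric, or flexible
parametric, with or without a patient-level frailty — describes the timing
of first complications best, and what do the adjusted hazard ratios look
like under the winner?

The package is aimed at biostatisticians who need the whole ladder in one
place, estimated from scratch with a common data model and a common
comparison table:

* **Cox proportional hazards** via the Breslow-form partial likelihood
  (delayed entry, ties, strata), with shared mean-1 gamma frailty of
  variance θ estimated by EM inside a profile-likelihood search, and the
  Grambsch–Therneau global test of the proportional-hazards assumption;
* **parametric families** — exponential, Weibull (PH and AFT),
  log-logistic, log-normal, generalized gamma (AFT) — with closed-form
  gamma-frailty marginals for PH families and adaptive Gauss–Hermite
  integration of a normal log-time intercept for AFT families;
* **flexible parametric (Royston–Parmar) models**: restricted cubic splines
  of log time on the log-cumulative-hazard scale,
  `ln H(t|x) = s(ln t) + xβ`, with internal knots at centiles of the
  uncensored log event times, optional shared gamma frailty, and analytic
  gradients throughout (`df = 1` reduces exactly to Weibull PH);
* **model selection**: AIC/BIC comparison tables and a best-model rule that
  tempers minimum-BIC with a spline-slope significance screen;
* **a seeded synthetic-cohort generator** at the scale of a 595-patient,
  9-year implant cohort (published covariate margins, published adjusted
  hazard ratios, ~4 implants per patient, gamma frailty), so that every
  estimator in the package can be exercised and stress-tested without any
  private data;
* **descriptives**: person-time incidence rates, Kaplan–Meier curves and
  quartile survival times with an explicit "cbc" (cannot be computed)
  sentinel under heavy censoring.

## Worked example

Generate a clustered cohort at the study scale (595 patients, ~4 implants
each sharing a patient-level frailty of variance 0.5), then fit and compare
models:

```r
library(frailladder)

cfg <- synthetic_config(per_implant = TRUE, frailty_theta = 0.5, seed = 42)
co  <- generate_cohort(cfg)$cohort
co
#> A cohort of 2697 records in 595 clusters
#>   events: 1567  person-days: 5,608,786
#>   covariates: periodontal, extent, age_group, sex, ever_smoker, product, retention

cohort_incidence(co)
#> 1567 events / 5,608,786 person-days = 0.000279 per day

fit <- fit_rp(co, df = 2, frailty = TRUE, null_fit = FALSE)
fit
#> Flexible parametric survival fit, df = 2, shared gamma frailty (theta = 0.4817)
#>   n = 2697, events = 1567, loglik = -14072.7262, k = 18
#>                               HR conf_low conf_high      p
#> periodontal=Periodontitis 1.3793   1.1362    1.6744 0.0012
#> extent=Full jaw           4.2659   3.3581    5.4191 0.0000
#> extent=Partial jaw        2.3201   1.8721    2.8753 0.0000
#> ...
#>   spline terms (exp scale):
#>   term estimate conf_low conf_high      p
#>  _rcs1   3.2896   3.0754    3.5186 0.0000
#>  _rcs2   0.9867   0.9441    1.0312 0.5517
```

The estimated frailty variance (0.48) and the hazard ratios recover the
generative truth (θ = 0.5; HR 1.449 for periodontitis, 4.641/2.338 for
full/partial-jaw restorations) within one-replicate sampling error. The
`_rcs` rows are the exponentiated spline slopes of the baseline log
cumulative hazard; here the second slope is not significant because the
generator's default baseline is Weibull (no genuine curvature), which is
exactly what the selection rule then concludes:

```r
wb   <- fit_parametric(co, "weibull", "PH")
rp1  <- fit_rp(co, df = 1, null_fit = FALSE)
rp2  <- fit_rp(co, df = 2, null_fit = FALSE)
comp <- model_comparison(list(Weibull = wb, `df = 1` = rp1,
                              `df = 2` = rp2, `df = 2` = fit))
comp
#>   frailty          class   model  ll_null ll_model  k     AIC     BIC
#> 1   FALSE     Parametric Weibull -14348.8 -14180.7 16 28393.4 28487.8
#> 2   FALSE Flexible Model  df = 1       NA -14180.7 16 28393.4 28487.8
#> 3   FALSE Flexible Model  df = 2       NA -14179.3 17 28392.6 28492.9
#> 4    TRUE Flexible Model  df = 2       NA -14072.7 18 28181.5 28287.7

select_best(comp, rp_fits = list(`df=2` = fit))
#> Selected model: df = 2 (with frailty)
#>   BIC = 28287.65  AIC = 28181.45
```

The frailty model dominates by more than 200 BIC points — ignoring the
clustering would be the wrong call on these data. The `df = 1` and Weibull
rows carry identical likelihoods, the exact reduction the test-suite
asserts on every cohort.

`run_analysis()` wraps the full pipeline — descriptive table, Cox ± frailty
and the proportionality test, the parametric grid, the flexible ladder,
comparison, selection, best-model hazard-ratio table and tidy curve
exports — into one call that writes plain CSV/text artifacts.

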