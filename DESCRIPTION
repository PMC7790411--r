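Package: frailladder
Title: Comparative Survival Modelling of Clustered Time-to-Event Data with Shared Frailty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and compares a ladder of survival regression models for
    clustered, right-censored time-to-event data such as dental-implant
    complication records: Cox proportional hazards with and without shared
    gamma frailty (profile-likelihood estimation of the frailty variance),
    parametric proportional-hazards and accelerated-failure-time families
    (exponential, Weibull, log-logistic, log-normal, generalized gamma) with
    cluster-level random effects, and flexible parametric (Royston-Parmar)
    models on the log cumulative hazard scale using restricted cubic splines
    of log time, with optional shared gamma frailty. Includes Kaplan-Meier
    descriptives with incidence rates and quantile survival times,
    AIC/BIC-based model comparison and a best-model decision rule, a seeded
    generator of clustered synthetic cohorts for parameter-recovery studies,
    and a one-call analysis pipeline that exports comparison tables and
    hazard/survival curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    flexsurv,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
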