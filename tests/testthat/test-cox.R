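test_that("partial log-likelihood at beta = 0 counts risk-set sizes", {
  co <- tie_cohort()
  ll0 <- cox_partial_loglik(c(0, 0), co)
  # failure times 3, 5 (d = 2), 8; risk sets of size 6, 5, 2
  expect_equal(ll0, -(log(6) + 2 * log(5) + log(2)))

  two <- as_cohort(data.frame(subject_id = 1:2, cluster_id = 1:2,
                              exit_time = c(1, 2), event = 1,
                              g = c("a", "b")),
                   covariate_spec(g = c("a", "b")))
  expect_equal(cox_partial_loglik(0, two), log(1 / 2))
})

test_that("partial log-likelihood matches brute-force risk-set enumeration", {
  co <- tie_cohort()
  set.seed(31)
  for (i in 1:10) {
    beta <- rnorm(2, sd = 0.8)
    expect_equal(cox_partial_loglik(beta, co),
                 brute_partial_loglik(beta, co), tolerance = 1e-10)
  }
  # also with delayed entry
  co2 <- co
  co2$data$entry_time <- c(0, 0, 4, 1, 6, 2)
  for (i in 1:5) {
    beta <- rnorm(2, sd = 0.8)
    expect_equal(cox_partial_loglik(beta, co2),
                 brute_partial_loglik(beta, co2), tolerance = 1e-10)
  }
})

test_that("Cox estimates agree with the reference implementation", {
  gen <- generate_cohort(small_config(n = 200, seed = 13))
  co <- gen$cohort
  fit <- fit_cox(co)
  d <- co$data
  X <- build_design(co)
  ref <- survival::coxph(survival::Surv(d$exit_time, d$event) ~ X,
                         ties = "breslow")
  expect_lt(max(abs(fit$beta - unname(coef(ref)))), 1e-4)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
  expect_equal(fit$loglik_null, ref$loglik[1], tolerance = 1e-8)
  expect_gte(fit$loglik, fit$loglik_null)

  # delayed entry handled identically
  d2 <- d
  d2$entry_time <- pmin(d$exit_time * 0.3, 200)
  co2 <- as_cohort(d2, co$spec)
  fit2 <- fit_cox(co2)
  ref2 <- survival::coxph(
    survival::Surv(d2$entry_time, d2$exit_time, d2$event) ~ X,
    ties = "breslow")
  expect_lt(max(abs(fit2$beta - unname(coef(ref2)))), 1e-4)
})

test_that("a single binary covariate with true HR 1.5 is recovered", {
  cfg <- synthetic_config(
    n_patients = 2000,
    covariate_margins = list(g = c(ref = 0.5, exp = 0.5)),
    true_hr = c(`g=exp` = 1.5), frailty_theta = 0, seed = 17)
  co <- generate_cohort(cfg)$cohort
  fit <- fit_cox(co)
  se <- sqrt(diag(fit$covariance))
  expect_gt(log(1.5), fit$beta - 1.96 * se)
  expect_lt(log(1.5), fit$beta + 1.96 * se)
})

test_that("constant covariates are excluded and flagged", {
  co <- tie_cohort()
  co$data$grp <- factor("x", levels = c("x", "y"))
  expect_warning(fit <- fit_cox(co), "constant")
  expect_named(fit$beta, "sz=l")
})

test_that("partial likelihood is a rank statistic", {
  co <- std_cohort()
  fit1 <- fit_cox(co)
  co2 <- co
  co2$data$exit_time <- co$data$exit_time^1.7 / 50  # monotone rescaling
  fit2 <- fit_cox(co2)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-6)
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-5)
})

test_that("Breslow baseline hazard is a valid non-decreasing step function", {
  co <- std_cohort()
  fit <- fit_cox(co)
  bh <- fit$baseline_cumhaz
  expect_true(all(diff(bh$cumhaz) >= 0))
  expect_true(all(bh$cumhaz > 0))
  ref <- survival::basehaz(
    survival::coxph(survival::Surv(co$data$exit_time, co$data$event) ~
                      build_design(co), ties = "breslow"), centered = FALSE)
  at_events <- ref$hazard[match(bh$time, ref$time)]
  expect_equal(bh$cumhaz, at_events, tolerance = 1e-6)
})

test_that("chi-squared upper tail reproduces the reported p-value", {
  res <- ph_test_result(5.50, 4)
  expect_equal(round(res$p_value, 3), 0.240)
  expect_equal(ph_test_result(0, 3)$p_value, 1)
})

test_that("the global proportional-hazards test runs and is well-formed", {
  fit <- std_cox_fit()
  res <- ph_test(fit)
  expect_s3_class(res, "ph_test_result")
  expect_equal(res$df, length(fit$beta))
  expect_gte(res$p_value, 0)
  expect_lte(res$p_value, 1)
  sub <- ph_test(fit, columns = names(fit$beta)[1:3])
  expect_equal(sub$df, 3L)
  expect_error(ph_test(fit, columns = "nope"), "unknown column")
})

test_that("stratified fits give each stratum its own baseline", {
  gen <- generate_cohort(small_config(n = 250, seed = 23))
  co <- gen$cohort
  fit <- fit_cox(co, strata = "sex")
  expect_false(any(grepl("^sex=", names(fit$beta))))
  d <- co$data
  X <- build_design(co)
  X <- X[, setdiff(colnames(X), "sex=Male"), drop = FALSE]
  ref <- survival::coxph(
    survival::Surv(d$exit_time, d$event) ~ X + survival::strata(d$sex),
    ties = "breslow")
  expect_lt(max(abs(fit$beta - unname(coef(ref)))), 1e-4)
  expect_equal(length(fit$baseline_cumhaz), 2L)
})
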