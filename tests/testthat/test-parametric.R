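test_that("Weibull with shape 1 collapses to the exponential likelihood", {
  co <- std_cohort()
  params_w <- list(intercept = log(3e-4), beta = rep(0.1, 14),
                   anc = c(log_shape = 0))
  params_e <- list(intercept = log(3e-4), beta = rep(0.1, 14),
                   anc = numeric(0))
  expect_equal(loglik_parametric(params_w, co, "weibull", "PH"),
               loglik_parametric(params_e, co, "exponential", "PH"))
})

test_that("invalid family/parameterization pairs are rejected", {
  co <- toy_cohort()
  expect_error(fit_parametric(co, "loglogistic", "PH"), "AFT")
  expect_error(fit_parametric(co, "gamma", "PH"), "AFT")
  expect_error(fit_parametric(co, "nope", "PH"), "unknown family")
})

test_that("gamma-frailty marginal likelihood matches dense integration", {
  cfg <- small_config(n = 4, theta = 0.4, per_implant = TRUE, seed = 9)
  co <- generate_cohort(cfg)$cohort
  X <- build_design(co)
  params <- list(intercept = log(2e-4), beta = rep(0.1, ncol(X)),
                 anc = c(log_shape = log(1.1)), theta = 0.4)
  ll <- loglik_parametric(params, co, "weibull", "PH",
                          frailty_kind = "gamma")
  d <- co$data
  lp <- params$intercept + as.vector(X %*% params$beta)
  logh <- lp + log(1.1) + (1.1 - 1) * log(d$exit_time)
  logH <- lp + 1.1 * log(d$exit_time)
  ci <- as.integer(factor(d$cluster_id))
  oracle <- sum(vapply(sort(unique(ci)), function(g) {
    idx <- which(ci == g)
    trapz_marginal_cluster(
      function(x) {  # frailty alpha = exp(x), includes Jacobian
        sum(d$event[idx] * (x + logh[idx])) -
          exp(x) * sum(exp(logH[idx])) + x
      },
      function(x) dgamma(exp(x), shape = 1 / 0.4, scale = 0.4, log = TRUE),
      -12, 6)
  }, numeric(1)))
  expect_equal(ll, oracle, tolerance = 1e-8)
})

test_that("adaptive quadrature matches dense integration for the normal intercept", {
  cfg <- small_config(n = 4, theta = 0.4, per_implant = TRUE, seed = 9)
  co <- generate_cohort(cfg)$cohort
  X <- build_design(co)
  d <- co$data
  params <- list(intercept = 8, beta = rep(0.1, ncol(X)),
                 anc = c(log_scale = log(0.9)), sd_u = 0.7)
  ll <- loglik_parametric(params, co, "lognormal", "AFT",
                          frailty_kind = "normal")
  lp <- params$intercept + as.vector(X %*% params$beta)
  ci <- as.integer(factor(d$cluster_id))
  sig <- 0.9
  oracle <- sum(vapply(sort(unique(ci)), function(g) {
    idx <- which(ci == g)
    trapz_marginal_cluster(
      function(u) {
        w <- (log(d$exit_time[idx]) - lp[idx] - u) / sig
        logS <- pnorm(w, lower.tail = FALSE, log.p = TRUE)
        logh <- dnorm(w, log = TRUE) - log(sig) -
          log(d$exit_time[idx]) - logS
        sum(d$event[idx] * logh - (-logS))
      },
      function(u) dnorm(u, 0, 0.7, log = TRUE),
      -6, 6)
  }, numeric(1)))
  expect_equal(ll, oracle, tolerance = 1e-6)
})

test_that("a zero random-effect variance reproduces the fixed-effect fit", {
  co <- std_cohort()
  X <- build_design(co)
  params <- list(intercept = 8.2, beta = rep(0.05, ncol(X)),
                 anc = c(log_scale = log(1.1)))
  fixed <- loglik_parametric(params, co, "lognormal", "AFT")
  params$sd_u <- 0
  mixed <- loglik_parametric(params, co, "lognormal", "AFT",
                             frailty_kind = "normal")
  expect_equal(mixed, fixed, tolerance = 1e-6)
  params$sd_u <- NULL
  params$theta <- 1e-10
  co_ph <- std_cohort()
  params_ph <- list(intercept = log(2e-4), beta = rep(0.05, ncol(X)),
                    anc = c(log_shape = 0))
  base <- loglik_parametric(params_ph, co_ph, "weibull", "PH")
  params_ph$theta <- 1e-10
  frail <- loglik_parametric(params_ph, co_ph, "weibull", "PH",
                             frailty_kind = "gamma")
  expect_equal(frail, base, tolerance = 1e-6)
})

test_that("PH and AFT parameterizations are exact reparameterizations", {
  gen <- generate_cohort(small_config(n = 150, seed = 19))
  co <- gen$cohort
  ep <- fit_parametric(co, "exponential", "PH")
  ea <- fit_parametric(co, "exponential", "AFT")
  expect_equal(ep$loglik, ea$loglik, tolerance = 1e-6)
  expect_equal(ep$beta, -ea$beta, tolerance = 1e-4)

  wp <- fit_parametric(co, "weibull", "PH")
  wa <- fit_parametric(co, "weibull", "AFT")
  expect_equal(wp$loglik, wa$loglik, tolerance = 1e-6)
  g <- exp(wa$ancillary[["log_shape"]])
  expect_equal(wp$beta, -g * wa$beta, tolerance = 1e-3)
})

test_that("AFT fits agree with the reference implementation", {
  gen <- generate_cohort(small_config(n = 200, seed = 29))
  d <- gen$cohort$data
  X <- build_design(gen$cohort)
  fit <- fit_parametric(gen$cohort, "lognormal", "AFT")
  ref <- survival::survreg(survival::Surv(d$exit_time, d$event) ~ X,
                           dist = "lognormal")
  expect_lt(max(abs(fit$beta - unname(coef(ref)[-1L]))), 1e-3)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-4)
})

test_that("Weibull PH truth is recovered within 10% at n = 500", {
  cfg <- synthetic_config(
    n_patients = 500,
    covariate_margins = list(g = c(ref = 0.5, exp = 0.5)),
    true_hr = c(`g=exp` = 2.0),
    baseline = weibull_baseline(2e-5, 1.3),
    frailty_theta = 0, seed = 31)
  co <- generate_cohort(cfg)$cohort
  fit <- fit_parametric(co, "weibull", "PH")
  expect_lt(abs(exp(fit$beta[["g=exp"]]) - 2.0) / 2.0, 0.10)
  expect_lt(abs(exp(fit$ancillary[["log_shape"]]) - 1.3) / 1.3, 0.10)
})

test_that("model nesting orders the likelihoods", {
  co <- std_cohort()
  we <- std_weibull_fit()
  ex <- fit_parametric(co, "exponential", "PH")
  expect_gte(we$loglik + 1e-6, ex$loglik)
})

test_that("predicted curves satisfy the survival identities", {
  co <- std_cohort()
  fit <- std_weibull_fit()
  times <- c(1e-6, 1, 10, 100, 1000, 3000)
  pred <- predict_parametric(fit, list(periodontal = "Periodontitis"),
                             times)
  expect_equal(pred$survival, exp(-pred$cumhaz))
  expect_lt(abs(pred$survival[1L] - 1), 1e-6)
  expect_true(all(diff(pred$cumhaz) >= 0))
  expect_true(all(pred$hazard >= 0))
  expect_error(predict_parametric(fit, list(), c(-1, 5)), "positive")

  ex <- fit_parametric(co, "exponential", "PH")
  pe <- predict_parametric(ex, list(), times)
  lam <- exp(ex$intercept)
  expect_equal(pe$hazard, rep(unname(lam), length(times)))
  expect_equal(pe$cumhaz, unname(lam) * times)
})

test_that("the marginal gamma-frailty curve tends to the conditional one", {
  gen <- generate_cohort(small_config(n = 100, theta = 0.5,
                                      per_implant = TRUE, seed = 37))
  fit <- fit_parametric(gen$cohort, "weibull", "PH", frailty_kind = "gamma")
  small_theta <- fit
  small_theta$theta_or_var <- 1e-8
  times <- c(10, 100, 1000, 3000)
  cond <- predict_parametric(small_theta, list(), times)
  marg <- predict_parametric(small_theta, list(), times, type = "marginal")
  expect_equal(marg$survival, cond$survival, tolerance = 1e-6)
})
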