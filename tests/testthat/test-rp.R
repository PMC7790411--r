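test_that("the df = 1 spline likelihood is exactly Weibull PH", {
  co <- std_cohort()
  uncens <- log(co$data$exit_time[co$data$event == 1])
  basis <- place_knots(1, uncens)  # raw {ln t} basis, no transform
  lam <- 2.4e-4; shp <- 0.9
  beta <- seq(-0.2, 0.2, length.out = 14)
  ll_rp <- rp_loglik(list(gamma = c(log(lam), shp), beta = beta), co, basis)
  ll_wb <- loglik_parametric(
    list(intercept = log(lam), beta = beta,
         anc = c(log_shape = log(shp))), co, "weibull", "PH")
  expect_equal(ll_rp, ll_wb, tolerance = 1e-8)
})

test_that("an all-censored cohort contributes only -sum(exp(eta))", {
  co <- std_cohort()
  uncens <- log(co$data$exit_time[co$data$event == 1])
  basis <- place_knots(2, uncens)
  cens <- co
  cens$data$event <- rep(0, nrow(cens$data))
  gamma <- c(-8, 1.1, 0.02)
  beta <- rep(0.1, 14)
  Z <- rcs_eval(basis, log(cens$data$exit_time))
  eta <- gamma[1] + as.vector(Z %*% gamma[-1]) +
    as.vector(build_design(cens) %*% beta)
  expect_equal(rp_loglik(list(gamma = gamma, beta = beta), cens, basis),
               -sum(exp(eta)))
})

test_that("the spline likelihood matches a term-by-term summation", {
  co <- as_cohort(
    data.frame(subject_id = paste0("s", 1:8), cluster_id = paste0("s", 1:8),
               exit_time = c(100, 250, 400, 700, 1100, 1600, 2400, 3000),
               event = c(1, 1, 0, 1, 1, 0, 1, 0),
               g = rep(c("a", "b"), 4)),
    covariate_spec(g = c("a", "b")))
  basis <- place_knots(2, log(co$data$exit_time[co$data$event == 1]))
  gamma <- c(-7.5, 1.05, 0.01)
  beta <- 0.3
  d <- co$data
  x <- log(d$exit_time)
  z <- rcs_eval(basis, x); dz <- rcs_deriv(basis, x)
  ll_terms <- 0
  for (i in 1:8) {
    eta_i <- gamma[1] + sum(z[i, ] * gamma[-1]) + beta * (d$g[i] == "b")
    sp_i <- sum(dz[i, ] * gamma[-1])
    ll_terms <- ll_terms +
      d$event[i] * (log(sp_i) + eta_i - x[i]) - exp(eta_i)
  }
  expect_equal(rp_loglik(list(gamma = gamma, beta = beta), co, basis),
               ll_terms, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  co <- frail_cohort()
  fit <- fit_rp(co, df = 2, null_fit = FALSE)
  parts <- frailladder:::rp_parts(co, fit$basis)
  p <- ncol(parts$X)
  for (frailty in c(FALSE, TRUE)) {
    par <- c(fit$gamma, fit$beta * 0.9, if (frailty) log(0.4))
    an <- frailladder:::rp_ll_grad(par, parts, 2L, p, frailty)
    fd <- vapply(seq_along(par), function(i) {
      h <- 1e-6 * max(1, abs(par[i]))
      up <- par; up[i] <- up[i] + h
      dn <- par; dn[i] <- dn[i] - h
      (frailladder:::rp_ll_grad(up, parts, 2L, p, frailty)$ll -
         frailladder:::rp_ll_grad(dn, parts, 2L, p, frailty)$ll) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(an$grad - fd) / (1 + abs(fd))), 1e-5)
  }
})

test_that("fitted spline models agree with the reference implementation", {
  co <- std_cohort()
  fit <- fit_rp(co, df = 2, null_fit = FALSE)
  d <- co$data
  X <- build_design(co)
  ref <- flexsurv::flexsurvspline(
    survival::Surv(d$exit_time, d$event) ~ X, k = 1, scale = "hazard")
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-4)
})

test_that("df = 1 fits coincide with the Weibull PH fit", {
  co <- std_cohort()
  rp1 <- fit_rp(co, df = 1, null_fit = FALSE)
  wb <- std_weibull_fit()
  expect_lt(abs(rp1$loglik - wb$loglik), 1e-4)
  expect_equal(rp1$beta, wb$beta, tolerance = 1e-3)
})

test_that("predictions satisfy the cumulative-hazard identities", {
  co <- std_cohort()
  fit <- fit_rp(co, df = 3, null_fit = FALSE)
  times <- c(5, 50, 500, 1500, 3000)
  pred <- predict_rp(fit, list(extent = "Full jaw"), times)
  expect_equal(pred$survival, exp(-pred$cumhaz))
  expect_true(all(diff(pred$cumhaz) > 0))
  expect_error(predict_rp(fit, list(), c(0, 5)), "positive")

  # df = 1 predictions equal the closed-form Weibull survival
  wb <- std_weibull_fit()
  uncens <- log(co$data$exit_time[co$data$event == 1])
  basis1 <- place_knots(1, uncens)
  mapped <- structure(
    list(basis = basis1,
         gamma = c(wb$intercept, exp(wb$ancillary[["log_shape"]])),
         beta = wb$beta, theta = 0, spec = co$spec, df = 1L),
    class = "rp_fit")
  pr <- predict_rp(mapped, list(sex = "Male"), times)
  lam <- exp(wb$intercept); g <- exp(wb$ancillary[["log_shape"]])
  S_closed <- exp(-lam * times^g * exp(wb$beta[["sex=Male"]]))
  expect_equal(pr$survival, S_closed, tolerance = 1e-12)
})

test_that("the fitted cumulative hazard is monotone on a dense grid", {
  co <- frail_cohort()
  fit <- fit_rp(co, df = 4, null_fit = FALSE)
  tmax <- max(co$data$exit_time)
  grid <- seq(tmax / 500, tmax, length.out = 500)
  for (pat in list(list(), list(periodontal = "Periodontitis"))) {
    pred <- predict_rp(fit, pat, grid)
    expect_true(all(diff(pred$cumhaz) > 0))
  }
})

test_that("marginal frailty survival matches dense numeric integration", {
  co <- frail_cohort()
  fit <- fit_rp(co, df = 2, frailty = TRUE, null_fit = FALSE)
  times <- c(100, 800, 2400)
  marg <- predict_rp(fit, list(), times, type = "marginal")
  cond <- predict_rp(fit, list(), times)
  th <- fit$theta
  num <- vapply(cond$cumhaz, function(H) {
    integrate(function(a) exp(-a * H) *
                dgamma(a, shape = 1 / th, scale = th),
              0, Inf, rel.tol = 1e-10)$value
  }, numeric(1))
  expect_equal(marg$survival, num, tolerance = 1e-6)
})

test_that("frailty variance and effects are recovered on matched truth", {
  co <- frail_cohort()  # theta = 0.5, study-scale effects
  fit <- fit_rp(co, df = 2, frailty = TRUE, null_fit = FALSE)
  expect_gt(fit$theta, 0.2)
  expect_lt(fit$theta, 0.9)
  b <- fit$beta[["periodontal=Periodontitis"]]
  se <- sqrt(diag(fit$covariance))[["periodontal=Periodontitis"]]
  expect_lt(abs(b - log(1.449)), 4 * se)
  # spline-slope report has the _rcs layout on the exp scale
  expect_named(fit$spline_terms,
               c("term", "estimate", "conf_low", "conf_high", "p"))
  expect_equal(fit$spline_terms$term, c("_rcs1", "_rcs2"))
  expect_true(all(fit$spline_terms$conf_low < fit$spline_terms$estimate))
})

test_that("the df ladder is monotone and starts at the Weibull", {
  co <- std_cohort()
  fits <- df_ladder(co, dfs = 1:4, null_fit = FALSE)
  lls <- vapply(fits, function(f) f$loglik, numeric(1))
  # every df >= 2 basis spans the Weibull rung, so df = 1 is a floor
  expect_true(all(lls[-1] >= lls[[1]] - 1e-6))
  # between higher rungs the knots move with df (bases are not nested);
  # likelihoods may dip by at most a knot-shift-sized amount
  expect_true(all(diff(lls) >= -0.05))
  expect_lt(abs(lls[["df=1"]] - std_weibull_fit()$loglik), 1e-4)
  # on Weibull-truth data the improvement beyond df = 1 is small
  expect_lt(lls[["df=4"]] - lls[["df=1"]],
            0.01 * abs(lls[["df=1"]]))
})

test_that("a failing df is logged and the ladder continues", {
  co <- as_cohort(
    data.frame(subject_id = 1:10, cluster_id = 1:10,
               exit_time = c(3, 5, 8, 12, 20, 33, 50, 80, 120, 200),
               event = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)))
  expect_message(fits <- df_ladder(co, dfs = c(1, 6), null_fit = FALSE),
                 "df = 6 fit failed")
  expect_named(fits, "df=1")
  expect_named(attr(fits, "failures"), "df=6")
})
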