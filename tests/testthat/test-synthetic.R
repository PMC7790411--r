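test_that("generation is bit-reproducible from (config, seed)", {
  cfg <- synthetic_config(n_patients = 80, per_implant = TRUE, seed = 5)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort$data, g2$cohort$data)
  expect_identical(g1$truth$frailties, g2$truth$frailties)
  g3 <- generate_cohort(synthetic_config(n_patients = 80,
                                         per_implant = TRUE, seed = 6))
  expect_false(identical(g1$cohort$data, g3$cohort$data))
})

test_that("the default cohort matches the study's scale", {
  gen <- generate_cohort(synthetic_config(seed = 1))
  co <- gen$cohort
  expect_equal(n_records(co), 595L)
  expect_equal(n_clusters(co), 595L)
  rate <- cohort_incidence(co)$rate
  expect_gt(rate, 0.00015)
  expect_lt(rate, 0.00035)
  expect_true(all(co$data$exit_time <= 3287))
})

test_that("a flat exponential truth reproduces its rate", {
  cfg <- synthetic_config(
    n_patients = 5000,
    covariate_margins = list(g = c(only = 1)),
    true_hr = c(),
    baseline = weibull_baseline(3e-4, 1),
    frailty_theta = 0, admin_censor_days = 36500, seed = 12)
  co <- generate_cohort(cfg)$cohort
  expect_lt(abs(cohort_incidence(co)$rate - 3e-4) / 3e-4, 0.05)
})

test_that("uncensored draws follow the generative survival law", {
  cfg <- synthetic_config(
    n_patients = 2000,
    covariate_margins = list(g = c(only = 1)),
    true_hr = c(),
    baseline = weibull_baseline(2e-4, 0.8),
    frailty_theta = 0, admin_censor_days = 1e9, seed = 14)
  co <- generate_cohort(cfg)$cohort
  ks <- suppressWarnings(
    ks.test(co$data$exit_time, function(q) {
      1 - exp(-2e-4 * q^0.8)
    }))
  expect_gt(ks$p.value, 0.01)
})

test_that("frailty draws have mean near 1 and variance near theta", {
  cfg <- synthetic_config(n_patients = 4000, frailty_theta = 0.5, seed = 15)
  truth <- generate_cohort(cfg)$truth
  expect_lt(abs(mean(truth$frailties) - 1), 0.05)
  expect_lt(abs(var(truth$frailties) - 0.5), 0.07)
})

test_that("implants per patient follow the truncated count distribution", {
  cfg <- synthetic_config(n_patients = 2000, per_implant = TRUE, seed = 16)
  gen <- generate_cohort(cfg)
  sizes <- table(gen$cohort$data$cluster_id)
  expect_true(all(sizes >= 1 & sizes <= 12))
  # rounding + truncation to [1, 12] shifts the mean up slightly
  expect_lt(abs(mean(sizes) - 4.0), 0.6)
})

test_that("censoring tightens as the administrative horizon shrinks", {
  frac <- vapply(c(500, 1500, 3287), function(cd) {
    cfg <- synthetic_config(n_patients = 400, admin_censor_days = cd,
                            seed = 18)
    mean(generate_cohort(cfg)$cohort$data$event == 0)
  }, numeric(1))
  expect_true(all(diff(frac) < 0))
})

test_that("calibration recovers an exponential rate analytically", {
  cfg <- synthetic_config(covariate_margins = list(g = c(only = 1)),
                          true_hr = c(), frailty_theta = 0,
                          admin_censor_days = 3287)
  r <- 2.5e-4
  bl <- calibrate_baseline(r, log(2) / r, cfg, shape_bounds = c(0.5, 2))
  expect_equal(bl$shape, 1, tolerance = 1e-3)
  expect_equal(bl$lambda, r, tolerance = 1e-3 * r)

  # monotone: doubling the target rate doubles lambda at shape ~ 1
  bl2 <- calibrate_baseline(2 * r, log(2) / (2 * r), cfg,
                            shape_bounds = c(0.5, 2))
  expect_gt(bl2$lambda, bl$lambda * 1.8)
})

test_that("calibrated targets are met by a large simulation", {
  cfg <- synthetic_config()
  target_rate <- 2.9e-4; target_median <- 2476
  bl <- calibrate_baseline(target_rate, target_median, cfg)
  cfg2 <- synthetic_config(n_patients = 10000, baseline = bl, seed = 19)
  co <- generate_cohort(cfg2)$cohort
  expect_lt(abs(cohort_incidence(co)$rate - target_rate) / target_rate,
            0.05)
  med <- survival_quantile(km_fit(co), 0.5)
  expect_lt(abs(med$time - target_median) / target_median, 0.05)
})

test_that("an infeasible target pair reports the feasible region", {
  cfg <- synthetic_config()
  expect_error(calibrate_baseline(1e-5, 2476, cfg), "feasible|infeasible")
})

test_that("a small recovery study reports bias, rmse and coverage", {
  cfg <- small_config(n = 120, theta = 0, seed = 60)
  res <- recovery_study(cfg, n_replicates = 3,
                        models = list(list(type = "cox")))
  s <- res$summary
  expect_named(s, c("model", "parameter", "truth", "mean_estimate",
                    "bias", "rmse", "coverage", "n_ok"))
  expect_true(all(s$n_ok <= 3))
  expect_equal(unique(s$model), "cox")
  expect_equal(s$truth[s$parameter == "periodontal=Periodontitis"],
               log(1.449))
  expect_equal(res$failures[["cox"]], 0L)
})

test_that("configurations round-trip through YAML", {
  cfg <- synthetic_config(n_patients = 77, frailty_theta = 0.3,
                          per_implant = TRUE, seed = 42)
  path <- withr::local_tempfile(fileext = ".yml")
  write_synthetic_config(cfg, path)
  back <- read_synthetic_config(path)
  expect_equal(back$n_patients, cfg$n_patients)
  expect_equal(back$covariate_margins, cfg$covariate_margins)
  expect_equal(back$true_hr, cfg$true_hr)
  expect_equal(back$baseline$lambda, cfg$baseline$lambda)
  expect_identical(generate_cohort(back)$cohort$data,
                   generate_cohort(cfg)$cohort$data)
})

test_that("invalid margins are rejected", {
  expect_error(
    synthetic_config(covariate_margins = list(g = c(a = 0.5, b = 0.4))),
    "sum to 1")
  expect_error(
    synthetic_config(covariate_margins = list(g = c(0.5, 0.5))),
    "named")
})
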