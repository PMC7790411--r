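make_comparison <- function(df) {
  class(df) <- c("comparison_table", "data.frame")
  df
}

stub_rp <- function(df, frailty, p_values) {
  structure(
    list(df = df, frailty = frailty,
         spline_terms = data.frame(term = paste0("_rcs", seq_len(df)),
                                   estimate = 1, conf_low = 1,
                                   conf_high = 1, p = p_values)),
    class = "rp_fit")
}

test_that("information criteria reproduce the printed comparison rows", {
  expect_equal(round(aic(-2633.63, 17), 2), 5301.26)
  expect_equal(round(aic(-2577.24, 17), 2), 5188.48)
  expect_equal(round(aic(-3900.89, 20), 2), 7841.78)
  expect_equal(round(aic(-1130.46, 20), 2), 2300.92)
  expect_equal(aic(0, 0), 0)
})

test_that("BIC uses the explicit sample size", {
  expect_equal(bic(-100, 0, 500), 200)
  expect_equal(bic(-2633.63, 17, 595), -2 * (-2633.63) + 17 * log(595))
  expect_error(bic(-1, 2, 0), "n must be")
  # BIC exceeds AIC once log(n) > 2 and parameters are penalized
  expect_gt(bic(-50, 3, 100), aic(-50, 3))
})

test_that("comparison rows satisfy the AIC/BIC identities exactly", {
  co <- std_cohort()
  fits <- list(Cox = std_cox_fit(), Weibull = std_weibull_fit(),
               `df = 1` = fit_rp(co, df = 1),
               `df = 2` = fit_rp(co, df = 2))
  comp <- model_comparison(fits)
  expect_equal(comp$AIC, -2 * comp$ll_model + 2 * comp$k)
  expect_equal(comp$BIC, -2 * comp$ll_model + comp$k * log(n_records(co)))
  expect_true(all(comp$ll_model >= comp$ll_null))
  # spline df = 1 and Weibull rows carry the same likelihood
  expect_lt(abs(comp$ll_model[comp$model == "df = 1"] -
                  comp$ll_model[comp$model == "Weibull"]), 1e-4)
  # grouped frailty-free first, Cox before parametric before flexible
  expect_equal(comp$class, c("Cox", "Parametric", "Flexible Model",
                             "Flexible Model"))
})

test_that("a single row is selected trivially", {
  rows <- make_comparison(data.frame(
    frailty = FALSE, class = "Cox", model = "Cox",
    ll_null = -110, ll_model = -100, k = 3,
    AIC = 206, BIC = 212, stringsAsFactors = FALSE))
  dec <- select_best(rows)
  expect_equal(dec$chosen$model, "Cox")
})

test_that("the frailty df = 2 flexible model wins a study-like table", {
  # orderings mimic the published comparison: flexible frailty fits have
  # the lowest criteria, BIC minimal at df = 2, AIC near-tied for df >= 2,
  # and only df = 2 has all spline slopes significant
  ll <- c(-988.24, -972.51, -971.73, -969.99)
  k <- 19:22
  n <- 595
  rows <- make_comparison(data.frame(
    frailty = c(FALSE, FALSE, rep(TRUE, 4)),
    class = c("Cox", "Parametric", rep("Flexible Model", 4)),
    model = c("Cox", "Weibull", paste("df =", 1:4)),
    ll_null = c(-2717.70, -1187.65, rep(-1143.70, 4)),
    ll_model = c(-2633.63, -1134.54, ll),
    k = c(17, 19, k),
    AIC = c(5301.26, 2307.07, -2 * ll + 2 * k),
    BIC = c(5384.09, 2399.64, -2 * ll + k * log(n)),
    stringsAsFactors = FALSE))
  rp_fits <- list(
    `df=1` = stub_rp(1, TRUE, 1e-5),
    `df=2` = stub_rp(2, TRUE, c(1e-5, 1e-4)),
    `df=3` = stub_rp(3, TRUE, c(1e-5, 1e-4, 0.107)),
    `df=4` = stub_rp(4, TRUE, c(1e-5, 1e-4, 0.2, 0.4)))
  dec <- select_best(rows, rp_fits = rp_fits, aic_tol = 0.001)
  expect_equal(dec$chosen$model, "df = 2")
  expect_true(dec$chosen$frailty)

  # selection does not depend on row order
  shuffled <- make_comparison(rows[c(4, 1, 6, 2, 3, 5), ])
  dec2 <- select_best(shuffled, rp_fits = rp_fits, aic_tol = 0.001)
  expect_equal(dec2$chosen$model, dec$chosen$model)
})

test_that("extra curvature is accepted only when every added slope earns it", {
  ll <- c(-980, -972.4, -972.0)
  k <- 19:21
  rows <- make_comparison(data.frame(
    frailty = TRUE, class = "Flexible Model",
    model = paste("df =", 1:3),
    ll_null = -1000, ll_model = ll, k = k,
    AIC = -2 * ll + 2 * k, BIC = -2 * ll + k * log(595),
    stringsAsFactors = FALSE))
  rp_all_sig <- list(`df=1` = stub_rp(1, TRUE, 1e-4),
                     `df=2` = stub_rp(2, TRUE, c(1e-4, 1e-3)),
                     `df=3` = stub_rp(3, TRUE, c(1e-4, 1e-3, 0.01)))
  dec <- select_best(rows, rp_fits = rp_all_sig, aic_tol = 0.01)
  expect_equal(dec$chosen$model, "df = 3")
})
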