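#' Akaike information criterion
#'
#' `AIC = -2 * loglik + 2 * k`, where `k` is the number of freely estimated
#' parameters. Lower values indicate a better fit; AIC weights complexity by
#' a constant 2 and does not involve the sample size.
#'
#' @param ll Log-likelihood at the optimum.
#' @param k Number of estimated parameters (>= 0).
#' @return AIC value.
#' @examples
#' aic(-2633.63, 17)  # 5301.26
#' @export
aic <- function(ll, k) {
  stopifnot(k >= 0)
  -2 * ll + 2 * k
}

#' Bayesian information criterion
#'
#' `BIC = -2 * loglik + k * log(n)`. The effective sample size `n` is an
#' explicit argument because its choice (records, subjects, events) is a
#' modelling decision that materially changes the penalty.
#'
#' @inheritParams aic
#' @param n Effective sample size (>= 1).
#' @return BIC value.
#' @export
bic <- function(ll, k, n) {
  stopifnot(k >= 0)
  if (n < 1) stop("n must be >= 1")
  -2 * ll + k * log(n)
}

fit_row_info <- function(fit, label = NULL) {
  if (inherits(fit, "cox_fit")) {
    frail <- fit$theta > 0
    list(frailty = frail, class = "Cox",
         model = if (!is.null(label)) label
                 else if (!is.null(fit$strata)) "Cox with strata"
                 else if (frail) "Cox frailty" else "Cox",
         ll_null = fit$loglik_null, ll_model = fit$loglik,
         k = length(fit$beta) + as.integer(frail))
  } else if (inherits(fit, "parametric_fit")) {
    list(frailty = fit$frailty_kind != "none", class = "Parametric",
         model = if (!is.null(label)) label else {
           nm <- c(exponential = "Exponential", weibull = "Weibull",
                   loglogistic = "Log Logistic", lognormal = "Log Normal",
                   gamma = "Gamma")[[fit$family]]
           nm
         },
         ll_null = fit$loglik_null, ll_model = fit$loglik, k = fit$k)
  } else if (inherits(fit, "rp_fit")) {
    list(frailty = fit$frailty, class = "Flexible Model",
         model = if (!is.null(label)) label else paste0("df = ", fit$df),
         ll_null = fit$loglik_null, ll_model = fit$loglik, k = fit$k)
  } else {
    stop("unsupported fit class: ", paste(class(fit), collapse = "/"))
  }
}

#' Model comparison table
#'
#' One row per fitted model with its null and fitted log-likelihoods,
#' parameter count, AIC and BIC, grouped by frailty flag (frailty-free
#' first) and then by model class (Cox, parametric, flexible).
#'
#' @param fits List of fitted models (`cox_fit`, `parametric_fit`,
#'   `rp_fit`), optionally named (names become row labels).
#' @param n Effective sample size for BIC; default the `n` of each fit.
#' @return A data frame of class `comparison_table` with columns `frailty`,
#'   `class`, `model`, `ll_null`, `ll_model`, `k`, `AIC`, `BIC`.
#' @export
model_comparison <- function(fits, n = NULL) {
  stopifnot(length(fits) >= 1L)
  labels <- names(fits)
  rows <- lapply(seq_along(fits), function(i) {
    info <- fit_row_info(fits[[i]],
                         label = if (!is.null(labels) && labels[i] != "")
                           labels[i] else NULL)
    n_i <- if (is.null(n)) fits[[i]]$n else n
    data.frame(frailty = info$frailty, class = info$class,
               model = info$model, ll_null = info$ll_null,
               ll_model = info$ll_model, k = info$k,
               AIC = aic(info$ll_model, info$k),
               BIC = bic(info$ll_model, info$k, n_i),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class_order <- c(Cox = 1L, Parametric = 2L, `Flexible Model` = 3L)
  out <- out[order(out$frailty, class_order[out$class]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Write a comparison table as CSV
#'
#' Column headers follow the conventional comparison layout: `Frailty`,
#' `Class`, `Model`, `ll(null)`, `ll(model)`, `df`, `AIC`, `BIC`.
#'
#' @param comparison A `comparison_table`.
#' @param path Output CSV path.
#' @export
write_comparison <- function(comparison, path) {
  out <- data.frame(
    Frailty = ifelse(comparison$frailty, "Yes", "None"),
    Class = comparison$class,
    Model = comparison$model,
    `ll(null)` = round(comparison$ll_null, 2),
    `ll(model)` = round(comparison$ll_model, 2),
    df = comparison$k,
    AIC = round(comparison$AIC, 2),
    BIC = round(comparison$BIC, 2),
    check.names = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Select the best model from a comparison table
#'
#' The minimum-BIC row wins. When the winner is a flexible (spline) model
#' and the flexible fits are supplied, a significance screen refines the
#' choice among near-tied fits: flexible fits whose AIC lies within
#' `aic_tol` (relative, default 0.1%) of the best flexible AIC are
#' near-tied, and among them the selected df is the largest whose every
#' spline slope is significant at `alpha` -- i.e. extra curvature is
#' accepted only when each added slope earns it, otherwise the simpler df
#' stands.
#'
#' @param comparison A `comparison_table`.
#' @param rp_fits Optional named list of `rp_fit` objects matching the
#'   flexible rows (names like `"df=2"` or labels equal to the `model`
#'   column).
#' @param aic_tol Relative AIC near-tie tolerance (fraction; 0.001 = 0.1%).
#' @param alpha Significance level for the spline-slope screen.
#' @return A list of class `selection_decision` with `chosen` (the chosen
#'   row) and `rationale` (character vector describing the criteria
#'   applied, in order).
#' @export
select_best <- function(comparison, rp_fits = NULL, aic_tol = 0.001,
                        alpha = 0.05) {
  stopifnot(inherits(comparison, "comparison_table"),
            nrow(comparison) >= 1L)
  best_idx <- which.min(comparison$BIC)
  chosen <- comparison[best_idx, , drop = FALSE]
  rationale <- sprintf("minimum BIC = %.2f at %s%s", chosen$BIC,
                       chosen$model,
                       if (chosen$frailty) " (frailty)" else "")

  if (!is.null(rp_fits) && chosen$class == "Flexible Model") {
    flex <- comparison[comparison$class == "Flexible Model" &
                         comparison$frailty == chosen$frailty, ,
                       drop = FALSE]
    a_min <- min(flex$AIC)
    near <- flex[abs(flex$AIC - a_min) / abs(a_min) <= aic_tol, ,
                 drop = FALSE]
    rationale <- c(rationale, sprintf(
      "%d flexible fit(s) within %.2f%% of the best flexible AIC",
      nrow(near), 100 * aic_tol))
    get_fit <- function(model_label) {
      for (key in c(model_label, gsub(" ", "", model_label))) {
        if (!is.null(rp_fits[[key]])) return(rp_fits[[key]])
      }
      for (f in rp_fits) {
        if (paste0("df = ", f$df) == model_label &&
            f$frailty == chosen$frailty) return(f)
      }
      NULL
    }
    eligible <- character(0)
    for (ml in near$model) {
      f <- get_fit(ml)
      if (!is.null(f) && all(f$spline_terms$p < alpha)) {
        eligible <- c(eligible, ml)
      }
    }
    if (length(eligible)) {
      dfs <- as.integer(sub(".*?(\\d+)$", "\\1", eligible))
      pick <- eligible[which.max(dfs)]
      chosen <- comparison[comparison$model == pick &
                             comparison$frailty == chosen$frailty &
                             comparison$class == "Flexible Model", ,
                           drop = FALSE][1L, , drop = FALSE]
      rationale <- c(rationale, sprintf(
        "largest near-tied df with all spline slopes significant at %.2f: %s",
        alpha, pick))
    } else {
      rationale <- c(rationale,
                     "no near-tied fit has all spline slopes significant; ",
                     "minimum-BIC row retained")
    }
  }
  structure(list(chosen = chosen, rationale = rationale),
            class = "selection_decision")
}

#' @export
print.selection_decision <- function(x, ...) {
  cat("Selected model:", x$chosen$model,
      if (x$chosen$frailty) "(with frailty)" else "(no frailty)", "\n")
  cat("  BIC =", round(x$chosen$BIC, 2), " AIC =", round(x$chosen$AIC, 2),
      "\n")
  for (r in x$rationale) cat("  -", r, "\n")
  invisible(x)
}
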