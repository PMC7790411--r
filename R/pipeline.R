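#' Tabular summary of a fitted model (hazard-ratio layout)
#'
#' Term-by-term table with the exponentiated coefficient, 95% Wald interval
#' and p-value. For flexible parametric fits the `_rcs` spline-slope rows
#' follow the covariate rows; for AFT parametric fits the exponentiated
#' coefficient is a time ratio rather than a hazard ratio (the `scale`
#' column says which).
#'
#' @param fit A `cox_fit`, `parametric_fit` or `rp_fit`.
#' @return A data frame with columns `term`, `estimate`, `conf_low`,
#'   `conf_high`, `p`, `scale`.
#' @export
summary_table <- function(fit) {
  UseMethod("summary_table")
}

wald_rows <- function(terms, coefs, ses, scale) {
  data.frame(term = terms,
             estimate = exp(coefs),
             conf_low = exp(coefs - 1.96 * ses),
             conf_high = exp(coefs + 1.96 * ses),
             p = 2 * stats::pnorm(-abs(coefs / ses)),
             scale = rep_len(scale, length(terms)),
             stringsAsFactors = FALSE)
}

#' @export
summary_table.cox_fit <- function(fit) {
  se <- sqrt(diag(fit$covariance))
  wald_rows(names(fit$beta), unname(fit$beta), unname(se), "hazard ratio")
}

#' @export
summary_table.parametric_fit <- function(fit) {
  if (length(fit$beta) == 0L) {
    return(wald_rows(character(0), numeric(0), numeric(0), character(0)))
  }
  se <- sqrt(diag(fit$covariance))[1L + seq_along(fit$beta)]
  scale <- if (fit$parameterization == "PH") "hazard ratio" else "time ratio"
  wald_rows(names(fit$beta), unname(fit$beta), unname(se), scale)
}

#' @export
summary_table.rp_fit <- function(fit) {
  se_all <- sqrt(diag(fit$covariance))
  out <- if (length(fit$beta)) {
    se <- se_all[fit$df + 1L + seq_along(fit$beta)]
    wald_rows(names(fit$beta), unname(fit$beta), unname(se), "hazard ratio")
  } else {
    wald_rows(character(0), numeric(0), numeric(0), character(0))
  }
  rcs <- fit$spline_terms
  rcs$scale <- "spline slope"
  rbind(out, rcs[, c("term", "estimate", "conf_low", "conf_high", "p",
                     "scale")])
}

#' Export hazard and survival curves for covariate patterns
#'
#' Tidy curve export: one row per (model, pattern, time) with hazard,
#' cumulative hazard and survival, for plotting or comparison across
#' models. For frailty models both the conditional (frailty = 1) and the
#' population-marginal curve are emitted.
#'
#' @param fits Named list of fitted models supporting prediction
#'   (`parametric_fit`, `rp_fit`).
#' @param patterns Named list of covariate patterns, e.g.
#'   `list(healthy = list(periodontal = "Healthy"))`.
#' @param times Positive time grid.
#' @param path Optional CSV output path.
#' @return The tidy curve data frame, invisibly when `path` is given.
#' @export
export_curves <- function(fits, patterns, times, path = NULL) {
  rows <- list()
  for (fi in seq_along(fits)) {
    fit <- fits[[fi]]
    fit_nm <- names(fits)[fi]
    pred_fun <- if (inherits(fit, "rp_fit")) predict_rp
                else if (inherits(fit, "parametric_fit")) predict_parametric
                else stop("cannot export curves for class ",
                          paste(class(fit), collapse = "/"))
    has_frailty <- (inherits(fit, "rp_fit") && fit$theta > 0) ||
      (inherits(fit, "parametric_fit") && fit$frailty_kind == "gamma" &&
         fit$theta_or_var > 0)
    types <- if (has_frailty) c("conditional", "marginal") else "conditional"
    for (pi in seq_along(patterns)) {
      for (ty in types) {
        cur <- pred_fun(fit, patterns[[pi]], times, type = ty)
        cur$model <- fit_nm
        cur$pattern <- names(patterns)[pi]
        cur$type <- ty
        rows[[length(rows) + 1L]] <- cur
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("model", "pattern", "type", "time", "hazard", "cumhaz",
                 "survival")]
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Run the full comparative survival analysis
#'
#' End-to-end pipeline on a cohort (or a freshly generated synthetic one):
#' descriptive table, Cox with and without shared gamma frailty plus the
#' proportional-hazards test, the parametric family grid, the flexible
#' parametric df ladder with and without frailty, the AIC/BIC comparison
#' table, the best-model decision, the best model's hazard-ratio table and
#' curve exports. Each artifact is written as plain CSV/text under
#' `outdir`; a failed model is logged and skipped rather than aborting the
#' run.
#'
#' @param cohort A `cohort`, or `NULL` to generate one from `config`.
#' @param config A `synthetic_config` used when `cohort` is `NULL`.
#' @param outdir Output directory (created if needed).
#' @param dfs Degrees-of-freedom ladder for the flexible model.
#' @param families Parametric families to fit (PH for exponential/Weibull,
#'   AFT otherwise; AFT families use a normal random intercept as their
#'   frailty variant).
#' @param frailty Logical; also fit the frailty/random-effect variants.
#' @param bic_n Effective sample size for BIC (default: number of records).
#' @param curve_pattern_category Covariate whose levels define the exported
#'   curve patterns (default the first covariate).
#' @return A list with `fits`, `comparison`, `decision`, `ph_test`,
#'   `table1`, `failures` and `outdir`, invisibly.
#' @export
run_analysis <- function(cohort = NULL, config = NULL, outdir,
                         dfs = 1:6,
                         families = c("exponential", "weibull",
                                      "loglogistic", "lognormal", "gamma"),
                         frailty = TRUE, bic_n = NULL,
                         curve_pattern_category = NULL) {
  if (is.null(cohort)) {
    if (is.null(config)) stop("supply a cohort or a synthetic_config")
    cohort <- generate_cohort(config)$cohort
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "curves"), showWarnings = FALSE)
  log_lines <- c(sprintf("frailladder run: %s", format(Sys.time())),
                 sprintf("records = %d, clusters = %d, events = %d",
                         n_records(cohort), n_clusters(cohort),
                         sum(cohort$data$event)))

  tab1 <- table1(cohort)
  utils::write.csv(tab1, file.path(outdir, "table1.csv"), row.names = FALSE)

  fits <- list()
  failures <- character(0)
  try_fit <- function(label, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[label]] <<- conditionMessage(res)
      log_lines <<- c(log_lines,
                      sprintf("FAILED %s: %s", label, conditionMessage(res)))
    } else {
      fits[[label]] <<- res
    }
  }

  try_fit("Cox", fit_cox(cohort))
  if (frailty) try_fit("Cox frailty", fit_cox_frailty(cohort))

  for (fam in families) {
    par_kind <- if (fam %in% c("exponential", "weibull")) "PH" else "AFT"
    label <- c(exponential = "Exponential", weibull = "Weibull",
               loglogistic = "Log Logistic", lognormal = "Log Normal",
               gamma = "Gamma")[[fam]]
    try_fit(label, fit_parametric(cohort, fam, par_kind))
    if (frailty) {
      fr_kind <- if (par_kind == "PH") "gamma" else "normal"
      try_fit(paste(label, "frailty"),
              fit_parametric(cohort, fam, par_kind, frailty_kind = fr_kind))
    }
  }

  rp_free <- df_ladder(cohort, dfs, frailty = FALSE)
  for (nm in names(rp_free)) fits[[paste0("Flexible ", nm)]] <- rp_free[[nm]]
  rp_frail <- list()
  if (frailty) {
    rp_frail <- df_ladder(cohort, dfs, frailty = TRUE)
    for (nm in names(rp_frail)) {
      fits[[paste0("Flexible frailty ", nm)]] <- rp_frail[[nm]]
    }
    failures <- c(failures, attr(rp_free, "failures"),
                  attr(rp_frail, "failures"))
  } else {
    failures <- c(failures, attr(rp_free, "failures"))
  }

  pht <- NULL
  if (!is.null(fits$Cox) && length(fits$Cox$beta)) {
    pht <- ph_test(fits$Cox)
    writeLines(sprintf(
      "Global proportional-hazards test: X2 = %.2f, df = %d, p = %.3f",
      pht$chi2, pht$df, pht$p_value), file.path(outdir, "ph_test.txt"))
  }

  comp_fits <- fits
  names(comp_fits) <- sub("^Flexible (frailty )?", "", names(comp_fits))
  comparison <- model_comparison(comp_fits, n = bic_n)
  write_comparison(comparison, file.path(outdir, "comparison.csv"))

  rp_for_selection <- if (frailty && length(rp_frail)) rp_frail else rp_free
  decision <- select_best(comparison, rp_fits = rp_for_selection)
  best_label <- decision$chosen$model
  best_fit <- if (decision$chosen$class == "Flexible Model") {
    pool <- if (decision$chosen$frailty) rp_frail else rp_free
    pool[[gsub(" ", "", best_label)]]
  } else {
    fits[[best_label]]
  }
  if (!is.null(best_fit) &&
      inherits(best_fit, c("cox_fit", "parametric_fit", "rp_fit"))) {
    utils::write.csv(summary_table(best_fit),
                     file.path(outdir, "best_model.csv"), row.names = FALSE)
  }
  log_lines <- c(log_lines, paste("selected:", best_label),
                 paste("rationale:", paste(decision$rationale,
                                           collapse = " | ")))

  # curve export for the levels of one covariate (e.g. periodontal status)
  if (length(cohort$spec)) {
    cat_nm <- curve_pattern_category
    if (is.null(cat_nm)) cat_nm <- names(cohort$spec)[1L]
    patterns <- lapply(cohort$spec[[cat_nm]], function(lv) {
      stats::setNames(list(lv), cat_nm)
    })
    names(patterns) <- cohort$spec[[cat_nm]]
    curve_fits <- Filter(function(f) inherits(f, c("parametric_fit",
                                                   "rp_fit")), fits)
    tmax <- max(cohort$data$exit_time)
    times <- seq(tmax / 200, tmax, length.out = 200L)
    export_curves(curve_fits, patterns, times,
                  file.path(outdir, "curves", "curves.csv"))
  }

  writeLines(c(log_lines,
               sprintf("models fitted = %d, failed = %d", length(fits),
                       length(failures))),
             file.path(outdir, "run_log.txt"))

  invisible(list(fits = fits, comparison = comparison, decision = decision,
                 ph_test = pht, table1 = tab1, failures = failures,
                 outdir = outdir))
}
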