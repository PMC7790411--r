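# Risk-set machinery for the Cox partial likelihood (Breslow ties).
#
# Records enter the risk set of a failure time t when entry < t <= exit.
# Because entry < exit always holds, {entry >= t} is a subset of
# {exit >= t}, so risk-set sums are differences of two cumulative sums,
# one ordered by exit time and one by entry time.

cox_sums <- function(X, entry, exit, event, lp, need = c("ll", "grad", "info")) {
  ft <- sort(unique(exit[event == 1]))
  n <- length(exit)
  p <- ncol(X)
  w <- exp(lp)

  ord_exit <- order(exit)
  ord_entry <- order(entry)
  exit_s <- exit[ord_exit]
  entry_s <- entry[ord_entry]
  # counts of records with exit < t (resp. entry < t) for each failure time
  cnt_exit_lt <- findInterval(ft, exit_s, left.open = TRUE)
  cnt_entry_lt <- findInterval(ft, entry_s, left.open = TRUE)

  risk_sum <- function(v) {
    # v: per-record quantities; returns risk-set totals per failure time
    cs_exit <- cumsum(v[ord_exit])
    cs_entry <- cumsum(v[ord_entry])
    tot <- cs_exit[n]
    after_exit <- tot - c(0, cs_exit)[cnt_exit_lt + 1L]
    after_entry <- tot - c(0, cs_entry)[cnt_entry_lt + 1L]
    after_exit - after_entry
  }

  S0 <- risk_sum(w)
  out <- list(failure_times = ft, S0 = S0)

  ev_idx <- which(event == 1)
  ft_of_event <- match(exit[ev_idx], ft)
  out$d <- as.numeric(tabulate(ft_of_event, nbins = length(ft)))

  if (any(c("ll") %in% need)) {
    lp_event_sum <- rowsum(lp[ev_idx], ft_of_event)[, 1L]
    out$lp_event <- numeric(length(ft))
    out$lp_event[sort(unique(ft_of_event))] <- lp_event_sum
  }
  if (any(c("grad", "info") %in% need) && p > 0L) {
    S1 <- matrix(0, length(ft), p)
    for (j in seq_len(p)) S1[, j] <- risk_sum(w * X[, j])
    out$S1 <- S1
    xd <- rowsum(X[ev_idx, , drop = FALSE], ft_of_event)
    Xd <- matrix(0, length(ft), p)
    Xd[sort(unique(ft_of_event)), ] <- xd
    out$Xd <- Xd
  }
  if ("info" %in% need && p > 0L) {
    S2 <- array(0, c(length(ft), p, p))
    for (a in seq_len(p)) {
      for (b in a:p) {
        s <- risk_sum(w * X[, a] * X[, b])
        S2[, a, b] <- s
        S2[, b, a] <- s
      }
    }
    out$S2 <- S2
  }
  out
}

#' Cox partial log-likelihood (Breslow form)
#'
#' Evaluates the partial log-likelihood over the ordered failure times, with
#' risk sets `{k : entry_k < t_(j) <= exit_k}` and the Breslow treatment of
#' tied failures: each failure time contributes the covariate linear
#' predictors of its failures minus `d_j` times the log of the risk-set sum
#' of `exp(lp)`.
#'
#' @param beta Coefficient vector (one per design column).
#' @param cohort A `cohort` with at least one event.
#' @param offset Optional per-record offset added to the linear predictor
#'   (used, e.g., for fixed log-frailties).
#' @return The partial log-likelihood value.
#' @export
cox_partial_loglik <- function(beta, cohort, offset = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data
  if (sum(d$event) < 1) stop("no events in cohort")
  X <- build_design(cohort)
  if (length(beta) != ncol(X)) {
    stop("beta has length ", length(beta), " but the design has ",
         ncol(X), " columns")
  }
  if (is.null(offset)) offset <- rep(0, nrow(X))
  lp <- as.vector(X %*% beta) + offset
  s <- cox_sums(X, d$entry_time, d$exit_time, d$event, lp, need = "ll")
  sum(s$lp_event - s$d * log(s$S0))
}

cox_newton <- function(X, entry, exit, event, offset,
                       tol = 1e-8, max_iter = 100L, beta_init = NULL) {
  p <- ncol(X)
  beta <- if (is.null(beta_init)) rep(0, p) else beta_init
  ll_of <- function(b) {
    lp <- as.vector(X %*% b) + offset
    s <- cox_sums(X, entry, exit, event, lp, need = "ll")
    sum(s$lp_event - s$d * log(s$S0))
  }
  ll <- ll_of(beta)
  ll_null <- if (all(beta == 0)) ll else ll_of(rep(0, p))
  converged <- FALSE
  info <- NULL
  for (it in seq_len(max_iter)) {
    lp <- as.vector(X %*% beta) + offset
    s <- cox_sums(X, entry, exit, event, lp)
    xbar <- s$S1 / s$S0
    grad <- colSums(s$Xd - s$d * xbar)
    info <- matrix(0, p, p)
    for (j in seq_along(s$failure_times)) {
      info <- info + s$d[j] * (s$S2[j, , ] / s$S0[j] -
                                 tcrossprod(xbar[j, ]))
    }
    if (max(abs(grad)) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(info, grad), error = function(e) NULL)
    if (is.null(step)) {
      step <- grad / (max(abs(diag(info))) + 1e-10)
    }
    # step halving
    new_beta <- beta + step
    new_ll <- ll_of(new_beta)
    halvings <- 0L
    while ((!is.finite(new_ll) || new_ll < ll - 1e-12) && halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- ll_of(new_beta)
      halvings <- halvings + 1L
    }
    beta <- new_beta
    ll <- new_ll
  }
  if (!converged) {
    stop("Cox Newton iteration did not converge within ", max_iter,
         " iterations (last gradient norm ", signif(max(abs(grad)), 3), ")")
  }
  if (any(abs(beta) > 15)) {
    warning("very large coefficient(s); possible separation / monotone ",
            "likelihood")
  }
  list(beta = beta, loglik = ll, loglik_null = ll_null, info = info)
}

breslow_cumhaz <- function(X, entry, exit, event, lp) {
  s <- cox_sums(X, entry, exit, event, lp, need = "ll")
  data.frame(time = s$failure_times,
             cumhaz = cumsum(s$d / s$S0))
}

#' Fit a Cox proportional hazards model
#'
#' Maximizes the Breslow-form partial likelihood by Newton iteration with
#' step halving (gradient tolerance `1e-8`, 100-iteration cap). The
#' covariance matrix is the inverse observed information and the baseline
#' cumulative hazard is the Breslow estimator. Covariate columns that are
#' constant over the records carry no information and are excluded with a
#' warning.
#'
#' @param cohort A `cohort`.
#' @param strata Optional covariate name; the partial likelihood is summed
#'   over strata, each with its own baseline hazard.
#' @param offset Optional per-record offset on the log-hazard scale.
#' @return An object of class `cox_fit` with elements `beta`, `covariance`,
#'   `loglik`, `loglik_null`, `theta` (0 for a plain Cox model),
#'   `log_frailties` (empty), `baseline_cumhaz` (per stratum when
#'   stratified), `dropped_terms` and `n_events`.
#' @export
fit_cox <- function(cohort, strata = NULL, offset = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data
  X <- build_design(cohort)
  if (is.null(offset)) offset <- rep(0, nrow(X))

  strat_id <- if (is.null(strata)) {
    rep(1L, nrow(d))
  } else {
    if (!strata %in% names(cohort$spec)) {
      stop("'", strata, "' is not a covariate of this cohort")
    }
    as.integer(d[[strata]])
  }
  for (sid in unique(strat_id)) {
    if (sum(d$event[strat_id == sid]) < 1) {
      stop("every stratum must contain at least one event")
    }
  }
  # exclude stratification variable's own dummies when stratifying
  if (!is.null(strata)) {
    drop_cols <- grep(paste0("^", strata, "="), colnames(X))
    if (length(drop_cols)) X <- X[, -drop_cols, drop = FALSE]
  }

  keep <- which(apply(X, 2L, function(col) stats::var(col) > 0))
  dropped <- setdiff(colnames(X), colnames(X)[keep])
  if (length(dropped)) {
    warning("constant covariate column(s) excluded: ",
            paste(dropped, collapse = ", "))
  }
  Xk <- X[, keep, drop = FALSE]
  p <- ncol(Xk)

  strat_levels <- sort(unique(strat_id))
  pieces <- lapply(strat_levels, function(sid) {
    idx <- strat_id == sid
    list(X = Xk[idx, , drop = FALSE], entry = d$entry_time[idx],
         exit = d$exit_time[idx], event = d$event[idx],
         offset = offset[idx])
  })

  if (p == 0L) {
    ll <- sum(vapply(pieces, function(pc) {
      s <- cox_sums(pc$X, pc$entry, pc$exit, pc$event, pc$offset, need = "ll")
      sum(s$lp_event - s$d * log(s$S0))
    }, numeric(1)))
    fit <- list(beta = numeric(0), loglik = ll, loglik_null = ll,
                info = matrix(0, 0, 0))
  } else if (length(pieces) == 1L) {
    pc <- pieces[[1L]]
    fit <- cox_newton(pc$X, pc$entry, pc$exit, pc$event, pc$offset)
  } else {
    # stratified Newton: sum log-likelihood, gradient and information
    beta <- rep(0, p)
    ll_of <- function(b) {
      sum(vapply(pieces, function(pc) {
        lp <- as.vector(pc$X %*% b) + pc$offset
        s <- cox_sums(pc$X, pc$entry, pc$exit, pc$event, lp, need = "ll")
        sum(s$lp_event - s$d * log(s$S0))
      }, numeric(1)))
    }
    ll <- ll_of(beta)
    ll_null <- ll
    converged <- FALSE
    info <- NULL
    for (it in seq_len(100L)) {
      grad <- rep(0, p)
      info <- matrix(0, p, p)
      for (pc in pieces) {
        lp <- as.vector(pc$X %*% beta) + pc$offset
        s <- cox_sums(pc$X, pc$entry, pc$exit, pc$event, lp)
        xbar <- s$S1 / s$S0
        grad <- grad + colSums(s$Xd - s$d * xbar)
        for (j in seq_along(s$failure_times)) {
          info <- info + s$d[j] * (s$S2[j, , ] / s$S0[j] -
                                     tcrossprod(xbar[j, ]))
        }
      }
      if (max(abs(grad)) < 1e-8 * (1 + abs(ll))) {
        converged <- TRUE
        break
      }
      step <- solve(info, grad)
      new_beta <- beta + step
      new_ll <- ll_of(new_beta)
      halvings <- 0L
      while ((!is.finite(new_ll) || new_ll < ll - 1e-12) && halvings < 30L) {
        step <- step / 2
        new_beta <- beta + step
        new_ll <- ll_of(new_beta)
        halvings <- halvings + 1L
      }
      beta <- new_beta
      ll <- new_ll
    }
    if (!converged) stop("stratified Cox fit did not converge")
    fit <- list(beta = beta, loglik = ll, loglik_null = ll_null, info = info)
  }

  names(fit$beta) <- colnames(Xk)
  covariance <- if (p > 0L) solve(fit$info) else matrix(0, 0, 0)
  dimnames(covariance) <- list(colnames(Xk), colnames(Xk))

  bh <- lapply(pieces, function(pc) {
    lp <- if (p > 0L) as.vector(pc$X %*% fit$beta) + pc$offset else pc$offset
    breslow_cumhaz(pc$X, pc$entry, pc$exit, pc$event, lp)
  })
  baseline <- if (length(bh) == 1L) bh[[1L]] else bh

  structure(
    list(beta = fit$beta, covariance = covariance,
         loglik = fit$loglik, loglik_null = fit$loglik_null,
         theta = 0, log_frailties = numeric(0),
         baseline_cumhaz = baseline,
         dropped_terms = dropped, strata = strata,
         n_events = sum(d$event), n = nrow(d),
         cohort = cohort, offset = offset),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional hazards fit",
      if (x$theta > 0) sprintf("with shared gamma frailty (theta = %.4f)",
                               x$theta) else "", "\n")
  cat(sprintf("  n = %d, events = %d, loglik = %.4f (null %.4f)\n",
              x$n, x$n_events, x$loglik, x$loglik_null))
  if (length(x$beta)) {
    se <- sqrt(diag(x$covariance))
    tab <- data.frame(coef = x$beta, HR = exp(x$beta), se = se,
                      p = 2 * stats::pnorm(-abs(x$beta / se)))
    print(round(tab, 4))
  }
  invisible(x)
}

# Per-event (unscaled) Schoenfeld residuals and event times, Breslow ties.
schoenfeld_residuals <- function(fit, columns) {
  cohort <- fit$cohort
  d <- cohort$data
  X <- build_design(cohort)[, names(fit$beta), drop = FALSE]
  lp <- as.vector(X %*% fit$beta) + fit$offset
  s <- cox_sums(X, d$entry_time, d$exit_time, d$event, lp)
  ev_idx <- which(d$event == 1)
  j_of_event <- match(d$exit_time[ev_idx], s$failure_times)
  xbar <- s$S1 / s$S0
  resid <- X[ev_idx, , drop = FALSE] - xbar[j_of_event, , drop = FALSE]
  list(resid = resid[, columns, drop = FALSE],
       times = d$exit_time[ev_idx],
       info = s)
}

#' Construct a proportional-hazards test result from its statistic
#'
#' Builds a `ph_test_result` from a chi-squared statistic and its degrees of
#' freedom; the p-value is the upper tail of the chi-squared distribution.
#'
#' @param chi2 Chi-squared statistic (non-negative).
#' @param df Degrees of freedom.
#' @return An object of class `ph_test_result` with `chi2`, `df`, `p_value`.
#' @examples
#' ph_test_result(5.50, 4)  # p = 0.240
#' @export
ph_test_result <- function(chi2, df) {
  stopifnot(chi2 >= 0, df >= 1)
  structure(
    list(chi2 = chi2, df = df,
         p_value = stats::pchisq(chi2, df, lower.tail = FALSE)),
    class = "ph_test_result"
  )
}

#' @export
print.ph_test_result <- function(x, ...) {
  cat(sprintf("Proportional-hazards test: X2 = %.2f, df = %d, p = %.3f\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Global test of the proportional-hazards assumption
#'
#' Grambsch-Therneau score test based on scaled Schoenfeld residuals with
#' the identity time transform: with per-event residuals `s_k` at event
#' times `g_k`, the statistic is
#' `T = d * u' I^-1 u / sum((g - gbar)^2)` where `u = sum((g_k - gbar) s_k)`,
#' `I` is the observed information of the fit and `d` the number of events.
#' Under proportional hazards `T` is chi-squared with as many degrees of
#' freedom as covariate columns tested.
#'
#' @param fit A plain (non-frailty) `cox_fit`.
#' @param columns Optional character vector of design-column names to test;
#'   default all fitted columns.
#' @return A `ph_test_result`.
#' @export
ph_test <- function(fit, columns = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$theta > 0) stop("ph_test applies to the plain Cox fit")
  if (length(fit$beta) == 0L) stop("no covariates to test")
  if (is.null(columns)) columns <- names(fit$beta)
  if (!all(columns %in% names(fit$beta))) {
    stop("unknown column(s): ",
         paste(setdiff(columns, names(fit$beta)), collapse = ", "))
  }
  d_events <- fit$n_events
  if (d_events <= length(columns)) {
    stop("fewer events than covariate columns tested")
  }
  sr <- schoenfeld_residuals(fit, columns)
  g <- sr$times - mean(sr$times)
  u <- colSums(g * sr$resid)
  s <- sr$info
  p_all <- length(fit$beta)
  info <- matrix(0, p_all, p_all)
  xbar <- s$S1 / s$S0
  for (j in seq_along(s$failure_times)) {
    info <- info + s$d[j] * (s$S2[j, , ] / s$S0[j] - tcrossprod(xbar[j, ]))
  }
  dimnames(info) <- list(names(fit$beta), names(fit$beta))
  info_ss <- info[columns, columns, drop = FALSE]
  chi2 <- as.numeric(d_events * crossprod(u, solve(info_ss, u)) / sum(g^2))
  ph_test_result(chi2, length(columns))
}
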