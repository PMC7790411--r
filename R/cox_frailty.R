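# Shared gamma frailty for the Cox model, estimated by maximum profile
# likelihood: for fixed theta the penalized partial likelihood in
# (beta, v_1..v_G) is maximized by an EM iteration (the E-step replaces each
# cluster's frailty by its posterior mean), and theta is then found by
# one-dimensional search of the profile marginal log-likelihood.

# Marginal profile log-likelihood penalty terms: for each cluster,
#   (1/theta)(v_i - e^{v_i}) + (1/theta + D_i)(1 - log(1/theta + D_i))
#   - log(theta)/theta + lgamma(1/theta + D_i) - lgamma(1/theta)
frailty_profile_penalty <- function(v, D, theta) {
  a <- 1 / theta
  sum(a * (v - exp(v)) + (a + D) * (1 - log(a + D)) - log(theta) * a +
        lgamma(a + D) - lgamma(a))
}

# EM inner loop at fixed theta; returns converged (beta, v) and components.
cox_frailty_em <- function(X, entry, exit, event, cluster_idx, theta,
                           beta0 = NULL, v0 = NULL,
                           tol = 1e-8, max_iter = 200L) {
  G <- max(cluster_idx)
  p <- ncol(X)
  v <- if (is.null(v0)) rep(0, G) else v0
  beta <- beta0
  D <- as.numeric(tabulate(cluster_idx[event == 1], nbins = G))
  ppl_old <- -Inf
  fit <- NULL
  for (it in seq_len(max_iter)) {
    offset <- v[cluster_idx]
    if (p > 0L) {
      fit <- cox_newton(X, entry, exit, event, offset, beta_init = beta)
      beta <- fit$beta
      lp_fix <- as.vector(X %*% beta)
    } else {
      lp_fix <- rep(0, length(exit))
      s <- cox_sums(X, entry, exit, event, offset, need = "ll")
      fit <- list(beta = numeric(0),
                  loglik = sum(s$lp_event - s$d * log(s$S0)),
                  info = matrix(0, 0, 0))
    }
    # Breslow baseline with current frailties in the risk denominators
    s <- cox_sums(X, entry, exit, event, lp_fix + offset, need = "ll")
    h0_steps <- s$d / s$S0
    H0_at <- function(t) {
      idx <- findInterval(t, s$failure_times)
      c(0, cumsum(h0_steps))[idx + 1L]
    }
    # expected cumulative hazard per cluster, frailty excluded
    rec_H <- (H0_at(exit) - H0_at(entry)) * exp(lp_fix)
    A <- as.numeric(rowsum(rec_H, cluster_idx, reorder = TRUE))
    v_new <- log((1 / theta + D) / (1 / theta + A))
    ppl <- fit$loglik + sum((v_new - exp(v_new)) / theta)
    delta <- max(abs(v_new - v))
    v <- v_new
    if (is.finite(ppl_old) && abs(ppl - ppl_old) < tol && delta < 1e-6) break
    ppl_old <- ppl
  }
  offset <- v[cluster_idx]
  if (p > 0L) {
    fit <- cox_newton(X, entry, exit, event, offset, beta_init = beta)
  } else {
    s <- cox_sums(X, entry, exit, event, offset, need = "ll")
    fit <- list(beta = numeric(0),
                loglik = sum(s$lp_event - s$d * log(s$S0)),
                loglik_null = NA, info = matrix(0, 0, 0))
  }
  marginal <- fit$loglik + frailty_profile_penalty(v, D, theta)
  list(beta = fit$beta, v = v, D = D, loglik_cox = fit$loglik,
       marginal = marginal, info = fit$info)
}

#' Fit a Cox model with shared gamma frailty
#'
#' Each cluster (patient) carries an unobserved multiplicative frailty on
#' the hazard, gamma-distributed with mean 1 and variance `theta`. For fixed
#' `theta`, the penalized partial likelihood in the coefficients and the log
#' frailties is maximized by an EM iteration; `theta` itself is estimated by
#' Brent search of the profile marginal log-likelihood over `log(theta)`.
#' The reported `loglik` is the marginal profile log-likelihood at the
#' optimum, and `loglik_null` is the same quantity with all coefficients
#' forced to zero at the profiled `theta` (the frailties re-estimated).
#'
#' @param cohort A `cohort` with at least two clusters and one event.
#' @param theta Optional fixed frailty variance; `NULL` (default) profiles
#'   it. `theta = 0` returns the plain Cox fit.
#' @param theta_bounds Search interval for the profile; a profiled optimum
#'   within tolerance of the upper bound triggers a warning.
#' @return A `cox_fit` with positive `theta`, per-cluster `log_frailties`,
#'   and the marginal profile log-likelihood in `loglik`.
#' @export
fit_cox_frailty <- function(cohort, theta = NULL,
                            theta_bounds = c(1e-6, 10)) {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data
  if (sum(d$event) < 1) stop("no events in cohort")
  cluster_f <- factor(d$cluster_id)
  G <- nlevels(cluster_f)
  if (G < 2L) stop("frailty variance is unidentifiable with a single cluster")
  if (!is.null(theta) && theta == 0) return(fit_cox(cohort))
  cluster_idx <- as.integer(cluster_f)
  X <- build_design(cohort)
  keep <- which(apply(X, 2L, function(col) stats::var(col) > 0))
  dropped <- setdiff(colnames(X), colnames(X)[keep])
  if (length(dropped)) {
    warning("constant covariate column(s) excluded: ",
            paste(dropped, collapse = ", "))
  }
  X <- X[, keep, drop = FALSE]

  state <- new.env(parent = emptyenv())
  state$beta <- NULL
  state$v <- NULL
  profile_ll <- function(log_theta) {
    em <- cox_frailty_em(X, d$entry_time, d$exit_time, d$event, cluster_idx,
                         exp(log_theta), beta0 = state$beta, v0 = state$v)
    state$beta <- em$beta
    state$v <- em$v
    em$marginal
  }

  if (is.null(theta)) {
    opt <- stats::optimize(profile_ll, interval = log(theta_bounds),
                           maximum = TRUE, tol = 1e-6)
    theta_hat <- exp(opt$maximum)
    if (log(theta_bounds[2L]) - opt$maximum < 1e-3) {
      warning("profiled frailty variance is at the upper search bound")
    }
  } else {
    theta_hat <- theta
  }

  em <- cox_frailty_em(X, d$entry_time, d$exit_time, d$event, cluster_idx,
                       theta_hat, beta0 = state$beta, v0 = state$v)
  # null model: beta = 0 at the profiled theta, frailties re-estimated
  em0 <- cox_frailty_em(matrix(numeric(0), nrow(d), 0L), d$entry_time,
                        d$exit_time, d$event, cluster_idx, theta_hat)

  names(em$beta) <- colnames(X)
  covariance <- if (ncol(X) > 0L) solve(em$info) else matrix(0, 0, 0)
  dimnames(covariance) <- list(colnames(X), colnames(X))
  lp <- if (ncol(X) > 0L) as.vector(X %*% em$beta) else rep(0, nrow(d))
  baseline <- breslow_cumhaz(X, d$entry_time, d$exit_time, d$event,
                             lp + em$v[cluster_idx])
  names(em$v) <- levels(cluster_f)

  structure(
    list(beta = em$beta, covariance = covariance,
         loglik = em$marginal, loglik_null = em0$marginal,
         theta = theta_hat, log_frailties = em$v,
         baseline_cumhaz = baseline,
         dropped_terms = dropped, strata = NULL,
         n_events = sum(d$event), n = nrow(d),
         cohort = cohort, offset = em$v[cluster_idx]),
    class = "cox_fit"
  )
}
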