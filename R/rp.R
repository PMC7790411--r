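# Flexible parametric (Royston-Parmar) survival model on the log
# cumulative hazard scale: ln H(t | x) = s(ln t | gamma, knots) + x beta,
# where s is a restricted cubic spline of log time. With df = 1 the spline
# is gamma0 + gamma1 ln t and the model is exactly Weibull PH. The log
# hazard is ln s'(ln t) + eta - ln t, so each record contributes
# d * (ln s' + eta - ln t) - exp(eta) to the log-likelihood; the optional
# shared gamma frailty is marginalized per cluster in closed form.

rp_parts <- function(cohort, basis) {
  d <- cohort$data
  if (any(d$exit_time <= 0)) stop("all exit times must be positive")
  logt <- log(d$exit_time)
  list(
    X = build_design(cohort),
    Z = rcs_eval(basis, logt),
    dZ = rcs_deriv(basis, logt),
    logt = logt,
    event = d$event,
    cluster_idx = as.integer(factor(d$cluster_id))
  )
}

# Core likelihood + gradient in packed parameters c(gamma0..gammadf, beta,
# [log_theta]); returns list(ll, grad). Monotonicity violations (s' <= 0 at
# an event time) are rejected with a smooth penalty so the optimizer backs
# away from them.
rp_ll_grad <- function(par, parts, df, p, frailty) {
  gamma <- par[seq_len(df + 1L)]
  beta <- if (p > 0L) par[df + 1L + seq_len(p)] else numeric(0)
  eta <- gamma[1L] + as.vector(parts$Z %*% gamma[-1L]) +
    (if (p > 0L) as.vector(parts$X %*% beta) else 0)
  sp <- as.vector(parts$dZ %*% gamma[-1L])
  ev <- parts$event == 1

  if (any(sp[ev] <= 0)) {
    viol <- sum(pmax(0, -sp[ev]) + 1e-3)
    grad_pen <- c(0, -colSums(parts$dZ[ev, , drop = FALSE] *
                                (sp[ev] <= 0)), rep(0, p),
                  if (frailty) 0)
    return(list(ll = -1e8 * viol, grad = 1e8 * grad_pen))
  }

  E <- exp(eta)
  if (!frailty) {
    ll <- sum(ev * (log(sp) + eta - parts$logt)) - sum(E)
    w <- ifelse(ev, 1, 0) - E          # d_i - exp(eta_i)
    g_gamma0 <- sum(w)
    g_gamma <- colSums(parts$dZ * (ev / sp)) + colSums(parts$Z * w)
    g_beta <- if (p > 0L) colSums(parts$X * w) else numeric(0)
    return(list(ll = ll, grad = c(g_gamma0, g_gamma, g_beta)))
  }

  theta <- exp(par[length(par)])
  ci <- parts$cluster_idx
  G <- max(ci)
  D <- tabulate(ci[ev], nbins = G)
  Hsum <- as.numeric(rowsum(E, ci, reorder = TRUE))
  ll <- sum(ev * (log(sp) + eta - parts$logt)) +
    sum(lgamma_ratio_stable(D, theta) -
          (1 / theta + D) * log1p(theta * Hsum))
  # per-record shrink factor (1 + theta D_g) / (1 + theta H_g)
  cfac <- ((1 + theta * D) / (1 + theta * Hsum))[ci]
  w <- ifelse(ev, 1, 0) - cfac * E
  g_gamma0 <- sum(w)
  g_gamma <- colSums(parts$dZ * (ev / sp)) + colSums(parts$Z * w)
  g_beta <- if (p > 0L) colSums(parts$X * w) else numeric(0)
  # d/d log(theta): theta * d/dtheta of the ratio and shrink terms
  maxD <- max(D)
  kfrac <- if (maxD > 0) {
    cs <- cumsum((theta * (seq_len(maxD) - 1)) /
                   (1 + theta * (seq_len(maxD) - 1)))
    out <- numeric(G); out[D > 0] <- cs[D[D > 0]]; out
  } else numeric(G)
  g_ltheta <- sum(kfrac + log1p(theta * Hsum) / theta -
                    (1 + theta * D) * Hsum / (1 + theta * Hsum))
  list(ll = ll, grad = c(g_gamma0, g_gamma, g_beta, g_ltheta))
}

#' Log-likelihood of a flexible parametric survival model
#'
#' Evaluates the log cumulative hazard scale likelihood: each record
#' contributes `d * (ln s'(ln t) + eta - ln t) - exp(eta)` with
#' `eta = s(ln t) + x beta`, so `H = exp(eta)`, `S = exp(-H)` and
#' `h = s'(ln t) H / t`. With `theta > 0` the shared mean-1 gamma frailty is
#' marginalized per cluster in closed form.
#'
#' @param params List with `gamma` (spline coefficients, length `df + 1`
#'   including the intercept), `beta` (one per design column) and optional
#'   `theta` (gamma frailty variance, default 0).
#' @param cohort A `cohort` with positive exit times.
#' @param basis An `rcs_basis` built from this cohort's uncensored log
#'   times (see [place_knots()]).
#' @return Log-likelihood value (`-Inf`-like penalized value when the
#'   spline slope is non-positive at an event time).
#' @export
rp_loglik <- function(params, cohort, basis) {
  stopifnot(inherits(cohort, "cohort"), inherits(basis, "rcs_basis"))
  parts <- rp_parts(cohort, basis)
  p <- ncol(parts$X)
  theta <- params$theta
  frailty <- !is.null(theta) && theta > 0
  par <- c(params$gamma, params$beta, if (frailty) log(theta))
  rp_ll_grad(par, parts, basis$df, p, frailty)$ll
}

rp_initial_gamma <- function(parts, basis) {
  # regress the log Nelson-Aalen-type cumulative hazard from the KM curve
  # on the spline columns at the event times
  sf <- survival::survfit(
    survival::Surv(exp(parts$logt), parts$event) ~ 1, conf.type = "none")
  keep <- sf$n.event > 0 & sf$surv > 0 & sf$surv < 1
  if (sum(keep) < basis$df + 1L) {
    # fall back: exponential-like start
    return(c(log(mean(parts$event) / mean(exp(parts$logt))),
             1, rep(0, basis$df - 1L)))
  }
  logH <- log(-log(sf$surv[keep]))
  zz <- rcs_eval(basis, log(sf$time[keep]))
  co <- stats::coef(stats::lm(logH ~ zz))
  co[is.na(co)] <- 0
  unname(co)
}

#' Fit a flexible parametric (Royston-Parmar) survival model
#'
#' Maximum (marginal) likelihood on the log cumulative hazard scale with a
#' restricted cubic spline of log time (internal knots at centiles of the
#' uncensored log event times, boundary knots at their extremes, basis
#' orthogonalized by default). Optimization is quasi-Newton with analytic
#' gradients; the frailty variance is profiled on the log scale. Spline
#' coefficients are initialized by regressing the Kaplan-Meier log
#' cumulative hazard on the basis; the frailty fit warm-starts from the
#' frailty-free fit. Monotonicity of the fitted cumulative hazard is
#' diagnosed after the fit (a warning is issued if `s'` is non-positive at
#' any uncensored event time).
#'
#' @param cohort A `cohort` with positive exit times. Delayed entry is not
#'   supported by this model.
#' @param df Spline degrees of freedom, 1..9 (`df = 1` is Weibull PH).
#' @param frailty Logical; add a shared mean-1 gamma frailty per cluster.
#' @param orthogonalize Logical; orthogonalize the spline basis (the fit is
#'   invariant to this choice).
#' @param null_fit Logical; also fit the covariate-free model of the same
#'   df and frailty structure to report `loglik_null`.
#' @return An object of class `rp_fit`: `basis`, `gamma` (spline
#'   coefficients incl. intercept), `beta`, `theta`, `loglik`,
#'   `loglik_null`, `covariance` (free parameters, frailty on log scale),
#'   `k`, `spline_terms` (exp-scale `_rcs` slopes with CIs and Wald p).
#' @export
fit_rp <- function(cohort, df, frailty = FALSE, orthogonalize = TRUE,
                   null_fit = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data
  if (any(d$entry_time > 0)) {
    stop("delayed entry is not supported by the flexible parametric model")
  }
  if (frailty && n_clusters(cohort) < 2L) {
    stop("frailty requires at least two clusters")
  }
  uncens <- log(d$exit_time[d$event == 1])
  basis <- place_knots(df, uncens)
  if (orthogonalize) basis <- orthogonalize_basis(basis, uncens)
  parts <- rp_parts(cohort, basis)
  p <- ncol(parts$X)

  gamma0 <- rp_initial_gamma(parts, basis)
  par0 <- c(gamma0, rep(0, p))

  fit_one <- function(par_init, with_frailty) {
    negll <- function(par) -rp_ll_grad(par, parts, df, p, with_frailty)$ll
    neggr <- function(par) -rp_ll_grad(par, parts, df, p, with_frailty)$grad
    opt <- stats::optim(par_init, negll, neggr, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-12))
    if (opt$convergence != 0) {
      stop("flexible parametric fit did not converge (optim code ",
           opt$convergence, ") at df = ", df)
    }
    opt
  }

  opt_free <- fit_one(par0, FALSE)
  if (frailty) {
    opt <- fit_one(c(opt_free$par, log(0.2)), TRUE)
  } else {
    opt <- opt_free
  }

  negll_final <- function(par) -rp_ll_grad(par, parts, df, p, frailty)$ll
  neggr_final <- function(par) -rp_ll_grad(par, parts, df, p, frailty)$grad
  hess <- stats::optimHess(opt$par, negll_final, neggr_final)
  covariance <- tryCatch(solve(hess), error = function(e) {
    warning("singular information matrix in flexible parametric fit")
    matrix(NA_real_, length(opt$par), length(opt$par))
  })
  par_names <- c(paste0("gamma", 0:df), colnames(parts$X),
                 if (frailty) "log_theta")
  dimnames(covariance) <- list(par_names, par_names)

  gamma <- opt$par[seq_len(df + 1L)]
  beta <- if (p > 0L) opt$par[df + 1L + seq_len(p)] else numeric(0)
  names(beta) <- colnames(parts$X)
  theta <- if (frailty) exp(opt$par[length(opt$par)]) else 0

  sp_ev <- as.vector(parts$dZ[parts$event == 1, , drop = FALSE] %*%
                       gamma[-1L])
  if (any(sp_ev <= 0)) {
    warning("fitted log cumulative hazard is non-monotone at ",
            sum(sp_ev <= 0), " event time(s)")
  }

  # exp-scale spline slope report (the _rcs rows of the fit summary)
  se_gamma <- sqrt(diag(covariance))[2:(df + 1L)]
  spline_terms <- data.frame(
    term = paste0("_rcs", seq_len(df)),
    estimate = exp(gamma[-1L]),
    conf_low = exp(gamma[-1L] - 1.96 * se_gamma),
    conf_high = exp(gamma[-1L] + 1.96 * se_gamma),
    p = 2 * stats::pnorm(-abs(gamma[-1L] / se_gamma)),
    stringsAsFactors = FALSE
  )

  ll_null <- NA_real_
  if (null_fit) {
    if (p == 0L) {
      ll_null <- -opt$value
    } else {
      null_cohort <- cohort
      null_cohort$spec <- covariate_spec()
      nf <- fit_rp(null_cohort, df = df, frailty = frailty,
                   orthogonalize = orthogonalize, null_fit = FALSE)
      ll_null <- nf$loglik
    }
  }

  structure(
    list(basis = basis, gamma = gamma, beta = beta, theta = theta,
         loglik = -opt$value, loglik_null = ll_null,
         covariance = covariance, k = length(opt$par),
         spline_terms = spline_terms,
         frailty = frailty, df = df,
         n = nrow(d), n_events = sum(d$event), spec = cohort$spec),
    class = "rp_fit"
  )
}

#' @export
print.rp_fit <- function(x, ...) {
  cat(sprintf(
    "Flexible parametric survival fit, df = %d%s\n", x$df,
    if (x$frailty) sprintf(", shared gamma frailty (theta = %.4f)", x$theta)
    else ""))
  cat(sprintf("  n = %d, events = %d, loglik = %.4f, k = %d\n",
              x$n, x$n_events, x$loglik, x$k))
  if (length(x$beta)) {
    se <- sqrt(diag(x$covariance))[x$df + 1L + seq_along(x$beta)]
    tab <- data.frame(HR = exp(x$beta),
                      conf_low = exp(x$beta - 1.96 * se),
                      conf_high = exp(x$beta + 1.96 * se),
                      p = 2 * stats::pnorm(-abs(x$beta / se)))
    print(round(tab, 4))
  }
  cat("  spline terms (exp scale):\n")
  print(cbind(x$spline_terms[, "term", drop = FALSE],
              round(x$spline_terms[, -1L], 4)), row.names = FALSE)
  invisible(x)
}

#' Predicted curves from a flexible parametric fit
#'
#' Evaluates `eta(t, x) = s(ln t) + x beta`, `H = exp(eta)`,
#' `S = exp(-H)` and `h = s'(ln t) H / t` for one covariate pattern.
#' For frailty fits, `type = "conditional"` is the frailty = 1 curve and
#' `type = "marginal"` the gamma-integrated population curve
#' `S_m = (1 + theta H)^(-1/theta)`.
#'
#' @param fit An `rp_fit`.
#' @param covariates Named covariate pattern (reference levels when absent).
#' @param times Positive time grid in days.
#' @param type `"conditional"` or `"marginal"`.
#' @return A data frame with `time`, `hazard`, `cumhaz`, `survival`.
#' @export
predict_rp <- function(fit, covariates = list(), times,
                       type = c("conditional", "marginal")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "rp_fit"))
  if (any(times <= 0) || any(!is.finite(times))) {
    stop("times must be positive and finite")
  }
  logt <- log(times)
  Z <- rcs_eval(fit$basis, logt)
  dZ <- rcs_deriv(fit$basis, logt)
  xrow <- pattern_row(fit$spec, covariates, names(fit$beta))
  eta <- fit$gamma[1L] + as.vector(Z %*% fit$gamma[-1L]) +
    sum(xrow * fit$beta)
  sp <- as.vector(dZ %*% fit$gamma[-1L])
  H <- exp(eta)
  h <- sp * H / times
  if (type == "marginal" && fit$theta > 0) {
    th <- fit$theta
    h <- h / (1 + th * H)
    H <- log1p(th * H) / th
  }
  data.frame(time = times, hazard = h, cumhaz = H, survival = exp(-H))
}

#' Fit the flexible model at several degrees of freedom
#'
#' One fit per requested df on the same cohort, as used for the
#' log-likelihood/AIC/BIC ladder of the model comparison. A df whose fit
#' fails is reported in the `failures` attribute and the ladder continues.
#'
#' @param cohort A `cohort`.
#' @param dfs Integer vector of degrees of freedom.
#' @param frailty Logical, shared gamma frailty.
#' @param ... Passed to [fit_rp()].
#' @return Named list of `rp_fit` objects (`"df=1"`, ...), with attribute
#'   `failures` (named character vector of error messages, possibly empty).
#' @export
df_ladder <- function(cohort, dfs = 1:6, frailty = FALSE, ...) {
  fits <- list()
  failures <- character(0)
  for (df in dfs) {
    res <- tryCatch(fit_rp(cohort, df = df, frailty = frailty, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[paste0("df=", df)] <- conditionMessage(res)
      message("df = ", df, " fit failed: ", conditionMessage(res))
    } else {
      fits[[paste0("df=", df)]] <- res
    }
  }
  attr(fits, "failures") <- failures
  fits
}
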