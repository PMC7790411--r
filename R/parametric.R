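# Parametric survival families in PH and AFT parameterizations.
#
# Each family supplies the per-record log hazard and log cumulative hazard
# given the linear predictor lp (intercept + x beta) and ancillary
# parameters on the log scale. PH families act multiplicatively on the
# hazard; AFT families shift log event time. Supported pairs follow the
# convention that exponential and Weibull admit both parameterizations
# while log-logistic, log-normal and (generalized) gamma are AFT only.

parametric_families <- function() {
  list(
    exponential = list(anc = character(0), param = c("PH", "AFT")),
    weibull     = list(anc = "log_shape", param = c("PH", "AFT")),
    loglogistic = list(anc = "log_scale", param = "AFT"),
    lognormal   = list(anc = "log_scale", param = "AFT"),
    gamma       = list(anc = c("log_sigma", "Q"), param = "AFT")
  )
}

check_family <- function(family, parameterization) {
  fams <- parametric_families()
  if (!family %in% names(fams)) {
    stop("unknown family '", family, "'; one of ",
         paste(names(fams), collapse = ", "))
  }
  if (!parameterization %in% fams[[family]]$param) {
    stop("family '", family, "' supports only the ",
         paste(fams[[family]]$param, collapse = "/"),
         " parameterization")
  }
  fams[[family]]
}

# log h(t) and log H(t) per record; lp includes the intercept.
family_loghaz <- function(family, parameterization, t, lp, anc) {
  logt <- log(t)
  if (family == "exponential") {
    s <- if (parameterization == "PH") 1 else -1
    return(list(logh = s * lp, logH = s * lp + logt))
  }
  if (family == "weibull") {
    g <- exp(anc[["log_shape"]])
    if (parameterization == "PH") {
      # ln H = lp + g * ln t  (lp = ln(lambda) + x beta)
      return(list(logh = lp + anc[["log_shape"]] + (g - 1) * logt,
                  logH = lp + g * logt))
    }
    # AFT: H = (t e^{-lp})^g
    return(list(logh = anc[["log_shape"]] + (g - 1) * logt - g * lp,
                logH = g * (logt - lp)))
  }
  if (family == "loglogistic") {
    sig <- exp(anc[["log_scale"]])
    w <- (logt - lp) / sig
    logS <- -log1p(exp(w))
    logh <- -anc[["log_scale"]] - logt + w + logS
    return(list(logh = logh, logH = log(log1p(exp(w)))))
  }
  if (family == "lognormal") {
    sig <- exp(anc[["log_scale"]])
    w <- (logt - lp) / sig
    logS <- stats::pnorm(w, lower.tail = FALSE, log.p = TRUE)
    logh <- stats::dnorm(w, log = TRUE) - anc[["log_scale"]] - logt - logS
    return(list(logh = logh, logH = log(-logS)))
  }
  if (family == "gamma") {
    # generalized gamma, AFT location lp, scale sigma, shape Q
    sig <- exp(anc[["log_sigma"]])
    q <- anc[["Q"]]
    h <- flexsurv::hgengamma(t, mu = lp, sigma = sig, Q = q)
    H <- flexsurv::Hgengamma(t, mu = lp, sigma = sig, Q = q)
    return(list(logh = log(h), logH = log(H)))
  }
  stop("unreachable")
}

# Closed-form cluster-marginal log-likelihood under mean-1 gamma frailty:
# integrating the gamma density against prod_j (alpha h_j)^{d_j}
# exp(-alpha H_j) gives, per cluster with D events and total cumulative
# hazard Hsum,
#   sum_j d_j log h_j + D log(theta) + lgamma(1/theta + D) - lgamma(1/theta)
#   - (1/theta + D) log(1 + theta Hsum).
# Because D is an integer event count, the gamma-ratio terms collapse to
# sum_{k=0}^{D-1} log(1 + k theta), which stays accurate as theta -> 0
# (the lgamma difference cancels catastrophically there).
lgamma_ratio_stable <- function(D, theta) {
  maxD <- max(D)
  if (maxD == 0) return(numeric(length(D)))
  cs <- cumsum(log1p(theta * seq_len(maxD) - theta))  # k = 0..maxD-1
  out <- numeric(length(D))
  out[D > 0] <- cs[D[D > 0]]
  out
}

gamma_frailty_marginal <- function(d, logh, H, cluster_idx, theta) {
  G <- max(cluster_idx)
  D <- tabulate(cluster_idx[d == 1], nbins = G)
  Hsum <- as.numeric(rowsum(H, cluster_idx, reorder = TRUE))
  ev_part <- sum(logh[d == 1])
  ev_part + sum(lgamma_ratio_stable(D, theta) -
                  (1 / theta + D) * log1p(theta * Hsum))
}

# Normal random intercept marginalized by 15-node Gauss-Hermite quadrature.
gh_nodes_cache <- new.env(parent = emptyenv())
gh_nodes <- function(n = 15L) {
  key <- as.character(n)
  if (is.null(gh_nodes_cache[[key]])) {
    gh_nodes_cache[[key]] <- pracma::gaussHermite(n)
  }
  gh_nodes_cache[[key]]
}

# Adaptive Gauss-Hermite quadrature over the cluster-level normal
# intercept: each cluster's integrand is re-centered at its posterior mode
# and re-scaled by the curvature there, so the 15 nodes cover the region
# where the integrand actually lives even for clusters with many events.
normal_intercept_marginal <- function(family, parameterization, t, d, lp,
                                      anc, cluster_idx, sd_u, nodes = 15L) {
  gh <- gh_nodes(nodes)
  G <- max(cluster_idx)
  if (sd_u < 1e-8) {
    hz <- family_loghaz(family, parameterization, t, lp, anc)
    return(sum(d * hz$logh - exp(hz$logH)))
  }
  # per-cluster joint log density q(u) = sum_j [d log h + log S](lp + u)
  #                                     + log phi(u; 0, sd_u)
  q_of <- function(u_vec) {
    hz <- family_loghaz(family, parameterization, t, lp + u_vec[cluster_idx],
                        anc)
    contrib <- d * hz$logh - exp(hz$logH)
    as.numeric(rowsum(contrib, cluster_idx, reorder = TRUE)) +
      stats::dnorm(u_vec, 0, sd_u, log = TRUE)
  }
  # vectorized Newton search for the per-cluster mode
  u <- rep(0, G)
  h <- 1e-3 * sd_u
  for (it in 1:25) {
    q0 <- q_of(u); qp <- q_of(u + h); qm <- q_of(u - h)
    g1 <- (qp - qm) / (2 * h)
    g2 <- pmin((qp - 2 * q0 + qm) / h^2, -1 / sd_u^2 * 1e-3)
    step <- -g1 / g2
    step <- pmax(pmin(step, 4 * sd_u), -4 * sd_u)
    u <- u + step
    if (max(abs(step)) < 1e-8 * sd_u) break
  }
  q0 <- q_of(u); qp <- q_of(u + h); qm <- q_of(u - h)
  tau <- 1 / sqrt(pmax(-(qp - 2 * q0 + qm) / h^2, 1e-12))
  # integral: sqrt(2) tau sum_k w_k e^{x_k^2} exp(q(mode + sqrt(2) tau x_k))
  qmat <- matrix(0, G, length(gh$x))
  for (k in seq_along(gh$x)) {
    qmat[, k] <- q_of(u + sqrt(2) * tau * gh$x[k])
  }
  lw <- log(gh$w) + gh$x^2
  a <- sweep(qmat, 2L, lw, "+")
  m <- apply(a, 1L, max)
  sum(m + log(rowSums(exp(a - m))) + 0.5 * log(2) + log(tau))
}

#' Censored-data log-likelihood of a parametric survival model
#'
#' Evaluates `sum(d * log h + log S)` for the requested family and
#' parameterization, with `S = exp(-H)`. Three frailty kinds are supported:
#' `"none"`; `"gamma"` -- a cluster-level multiplicative mean-1 gamma
#' frailty on the hazard, marginalized in closed form (PH families); and
#' `"normal"` -- a cluster-level normal intercept on log time (AFT
#' families), marginalized by 15-node Gauss-Hermite quadrature. Delayed
#' entry is supported for frailty-free likelihoods only (conditional
#' likelihood, subtracting `H(entry)`).
#'
#' @param params Named list with `intercept`, `beta` (vector matching the
#'   design columns), `anc` (named ancillary parameters, log scale, e.g.
#'   `log_shape` for Weibull), and for frailty models `theta` (gamma
#'   frailty variance) or `sd_u` (random-intercept SD).
#' @param cohort A `cohort`.
#' @param family One of `"exponential"`, `"weibull"`, `"loglogistic"`,
#'   `"lognormal"`, `"gamma"` (generalized gamma).
#' @param parameterization `"PH"` or `"AFT"`.
#' @param frailty_kind `"none"`, `"gamma"` or `"normal"`.
#' @return Log-likelihood value.
#' @export
loglik_parametric <- function(params, cohort, family,
                              parameterization = "PH",
                              frailty_kind = "none") {
  stopifnot(inherits(cohort, "cohort"))
  check_family(family, parameterization)
  d <- cohort$data
  if (any(d$exit_time <= 0)) stop("event/censoring times must be positive")
  X <- build_design(cohort)
  beta <- params$beta
  if (is.null(beta)) beta <- rep(0, ncol(X))
  lp <- params$intercept + if (ncol(X)) as.vector(X %*% beta) else 0
  t <- d$exit_time
  ev <- d$event
  anc <- params$anc

  if (frailty_kind == "none") {
    hz <- family_loghaz(family, parameterization, t, lp, anc)
    ll <- sum(ev * hz$logh - exp(hz$logH))
    if (any(d$entry_time > 0)) {
      idx <- which(d$entry_time > 0)
      hz0 <- family_loghaz(family, parameterization, d$entry_time[idx],
                           lp[idx], anc)
      ll <- ll + sum(exp(hz0$logH))
    }
    return(ll)
  }
  if (any(d$entry_time > 0)) {
    stop("delayed entry is not supported together with frailty")
  }
  cluster_idx <- as.integer(factor(d$cluster_id))
  if (frailty_kind == "gamma") {
    hz <- family_loghaz(family, parameterization, t, lp, anc)
    return(gamma_frailty_marginal(ev, hz$logh, exp(hz$logH), cluster_idx,
                                  params$theta))
  }
  if (frailty_kind == "normal") {
    return(normal_intercept_marginal(family, parameterization, t, ev, lp,
                                     anc, cluster_idx, params$sd_u))
  }
  stop("unknown frailty_kind '", frailty_kind, "'")
}

parametric_par_pack <- function(par, p, anc_names, frailty_kind) {
  out <- list(intercept = par[1L],
              beta = if (p > 0L) par[1L + seq_len(p)] else numeric(0))
  pos <- 1L + p
  anc <- numeric(0)
  for (nm in anc_names) {
    pos <- pos + 1L
    anc[nm] <- par[pos]
  }
  out$anc <- anc
  if (frailty_kind == "gamma") out$theta <- exp(par[pos + 1L])
  if (frailty_kind == "normal") out$sd_u <- exp(par[pos + 1L])
  out
}

#' Fit a parametric survival model, optionally with cluster random effects
#'
#' Maximum (marginal) likelihood via quasi-Newton optimization; ancillary
#' parameters and frailty variances are estimated on the log scale to keep
#' them positive. Starting values come from the no-covariate exponential
#' rate (events / person-time).
#'
#' @inheritParams loglik_parametric
#' @return An object of class `parametric_fit` with `family`,
#'   `parameterization`, `frailty_kind`, `intercept`, `beta`, `ancillary`,
#'   `theta_or_var` (gamma frailty variance or random-intercept variance, 0
#'   when none), `loglik`, `loglik_null` (intercept + ancillary only, same
#'   frailty structure), `covariance` (all free parameters, internal scale)
#'   and `k` (number of free parameters).
#' @export
fit_parametric <- function(cohort, family, parameterization = "PH",
                           frailty_kind = "none") {
  stopifnot(inherits(cohort, "cohort"))
  fam <- check_family(family, parameterization)
  if (frailty_kind != "none" && n_clusters(cohort) < 2L) {
    stop("frailty requires at least two clusters")
  }
  if (frailty_kind == "gamma" && parameterization != "PH") {
    stop("gamma (hazard-multiplicative) frailty is defined for PH ",
         "parameterizations; use frailty_kind = 'normal' for AFT models")
  }
  X <- build_design(cohort)
  p <- ncol(X)
  anc_names <- fam$anc

  rate <- cohort_incidence(cohort)$rate
  intercept0 <- switch(parameterization,
                       PH = log(rate), AFT = -log(rate))
  anc0 <- vapply(anc_names, function(nm) {
    if (nm == "Q") 1 else 0
  }, numeric(1))
  par0 <- c(intercept0, rep(0, p), anc0)
  if (frailty_kind != "none") par0 <- c(par0, log(0.25))

  negll <- function(par) {
    params <- parametric_par_pack(par, p, anc_names, frailty_kind)
    ll <- tryCatch(
      loglik_parametric(params, cohort, family, parameterization,
                        frailty_kind),
      error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  opt <- stats::optim(par0, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop("parametric fit did not converge (optim code ", opt$convergence,
         "): ", family, " ", parameterization, " frailty=", frailty_kind)
  }
  hess <- stats::optimHess(opt$par, negll)
  covariance <- tryCatch(solve(hess), error = function(e) {
    warning("singular information matrix; covariance unavailable")
    matrix(NA_real_, length(opt$par), length(opt$par))
  })
  par_names <- c("intercept", colnames(X), anc_names,
                 if (frailty_kind == "gamma") "log_theta"
                 else if (frailty_kind == "normal") "log_sd_u")
  dimnames(covariance) <- list(par_names, par_names)

  # null model: intercept + ancillary (+ frailty variance), no covariates
  null_cohort <- cohort
  null_cohort$spec <- covariate_spec()
  null_fit_ll <- {
    npar0 <- c(intercept0, anc0)
    if (frailty_kind != "none") npar0 <- c(npar0, log(0.25))
    nnegll <- function(par) {
      params <- parametric_par_pack(par, 0L, anc_names, frailty_kind)
      ll <- tryCatch(
        loglik_parametric(params, null_cohort, family, parameterization,
                          frailty_kind),
        error = function(e) -Inf)
      if (!is.finite(ll)) return(1e10)
      -ll
    }
    -stats::optim(npar0, nnegll, method = "BFGS",
                  control = list(maxit = 500, reltol = 1e-12))$value
  }

  params <- parametric_par_pack(opt$par, p, anc_names, frailty_kind)
  beta <- params$beta
  names(beta) <- colnames(X)
  structure(
    list(family = family, parameterization = parameterization,
         frailty_kind = frailty_kind,
         intercept = params$intercept, beta = beta,
         ancillary = params$anc,
         theta_or_var = if (frailty_kind == "gamma") params$theta
                        else if (frailty_kind == "normal") params$sd_u^2
                        else 0,
         loglik = -opt$value, loglik_null = null_fit_ll,
         covariance = covariance, k = length(opt$par),
         n = n_records(cohort), n_events = sum(cohort$data$event),
         spec = cohort$spec),
    class = "parametric_fit"
  )
}

#' @export
print.parametric_fit <- function(x, ...) {
  cat(sprintf("%s %s survival model (frailty: %s)\n",
              x$family, x$parameterization, x$frailty_kind))
  cat(sprintf("  n = %d, events = %d, loglik = %.4f (null %.4f), k = %d\n",
              x$n, x$n_events, x$loglik, x$loglik_null, x$k))
  cat("  intercept:", signif(x$intercept, 6), "\n")
  if (length(x$ancillary)) {
    cat("  ancillary:", paste(names(x$ancillary), signif(x$ancillary, 4),
                              sep = " = ", collapse = ", "), "\n")
  }
  if (x$theta_or_var > 0) {
    cat("  frailty/random-effect variance:", signif(x$theta_or_var, 4), "\n")
  }
  if (length(x$beta)) print(round(cbind(coef = x$beta, HR = exp(x$beta)), 4))
  invisible(x)
}

#' Predicted hazard, cumulative hazard and survival curves
#'
#' Evaluates `h(t)`, `H(t)` and `S(t) = exp(-H(t))` for one covariate
#' pattern on a time grid. For gamma-frailty fits the population-marginal
#' survival `S_m(t) = (1 + theta H(t))^(-1/theta)` (and the corresponding
#' marginal hazard) can be requested; the conditional curve is the
#' frailty = 1 curve.
#'
#' @param fit A `parametric_fit`.
#' @param covariates Named list/vector of covariate levels (categories not
#'   supplied sit at their reference level).
#' @param times Positive time grid in days.
#' @param type `"conditional"` (frailty = 1) or `"marginal"`
#'   (gamma-frailty-integrated; identical to conditional when there is no
#'   gamma frailty).
#' @return A data frame with `time`, `hazard`, `cumhaz`, `survival`.
#' @export
predict_parametric <- function(fit, covariates = list(), times,
                               type = c("conditional", "marginal")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "parametric_fit"))
  if (any(times <= 0)) stop("times must be positive")
  xrow <- pattern_row(fit$spec, covariates, names(fit$beta))
  lp <- fit$intercept + sum(xrow * fit$beta)
  hz <- family_loghaz(fit$family, fit$parameterization, times, rep(lp, length(times)),
                      fit$ancillary)
  H <- exp(hz$logH)
  h <- exp(hz$logh)
  if (type == "marginal" && fit$frailty_kind == "gamma" &&
      fit$theta_or_var > 0) {
    th <- fit$theta_or_var
    h <- h / (1 + th * H)
    Hm <- log1p(th * H) / th
    H <- Hm
  }
  data.frame(time = times, hazard = h, cumhaz = H, survival = exp(-H))
}

# Build a single design row for a named covariate pattern.
pattern_row <- function(spec, covariates, design_names) {
  xrow <- stats::setNames(rep(0, length(design_names)), design_names)
  for (nm in names(covariates)) {
    if (!nm %in% names(spec)) stop("unknown covariate '", nm, "'")
    lv <- as.character(covariates[[nm]])
    if (!lv %in% spec[[nm]]) {
      stop("unknown level '", lv, "' for covariate '", nm, "'")
    }
    col <- paste0(nm, "=", lv)
    if (col %in% design_names) xrow[col] <- 1
  }
  xrow
}
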