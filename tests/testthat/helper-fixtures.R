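# Shared fixtures, built in code. Expensive objects are cached for the
# duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Four subjects: events at 2 and 4, censorings at 3 and 5; one binary
# covariate. Hand product-limit: S(2) = 3/4, S(4) = 3/8.
toy_cohort <- function() {
  as_cohort(
    data.frame(
      subject_id = paste0("s", 1:4),
      cluster_id = paste0("s", 1:4),
      exit_time = c(2, 3, 4, 5),
      event = c(1, 0, 1, 0),
      arm = c("a", "b", "a", "b")
    ),
    covariate_spec(arm = c("a", "b"))
  )
}

# Six records with one tied failure time, two covariates; used for
# brute-force partial-likelihood checks.
tie_cohort <- function() {
  as_cohort(
    data.frame(
      subject_id = paste0("s", 1:6),
      cluster_id = paste0("c", c(1, 1, 2, 2, 3, 3)),
      exit_time = c(3, 5, 5, 7, 8, 9),
      event = c(1, 1, 1, 0, 1, 0),
      grp = c("x", "y", "y", "x", "y", "x"),
      sz = c("s", "s", "l", "l", "s", "l")
    ),
    covariate_spec(grp = c("x", "y"), sz = c("s", "l"))
  )
}

# Small covariate structure for fast simulation-heavy tests.
small_margins <- function() {
  list(periodontal = c(Healthy = 0.6, Periodontitis = 0.25,
                       `No teeth` = 0.15),
       sex = c(Female = 0.55, Male = 0.45))
}

small_true_hr <- function() {
  c(`periodontal=Periodontitis` = 1.449, `periodontal=No teeth` = 1.05,
    `sex=Male` = 1.272)
}

small_config <- function(n = 200, theta = 0, seed = 1, ...) {
  synthetic_config(n_patients = n, covariate_margins = small_margins(),
                   true_hr = small_true_hr(), frailty_theta = theta,
                   seed = seed, ...)
}

# Default-structure cohort, 300 patients, no frailty (cached).
std_cohort <- function() {
  cached("std_cohort",
         generate_cohort(synthetic_config(n_patients = 300,
                                          frailty_theta = 0,
                                          seed = 7))$cohort)
}

std_cox_fit <- function() cached("std_cox", fit_cox(std_cohort()))

std_weibull_fit <- function() {
  cached("std_weibull", fit_parametric(std_cohort(), "weibull", "PH"))
}

# Clustered frailty cohort: 300 patients x ~4 implants, theta = 0.5.
frail_cohort <- function() {
  cached("frail_cohort",
         generate_cohort(synthetic_config(n_patients = 300,
                                          frailty_theta = 0.5,
                                          per_implant = TRUE,
                                          seed = 3))$cohort)
}

# Brute-force Breslow partial log-likelihood, straight from the formula:
# sum over ordered failure times of [sum_{D_j} x_i beta
#   - d_j log(sum_{R_j} exp(x_k beta))], risk set entry < t <= exit.
brute_partial_loglik <- function(beta, cohort) {
  d <- cohort$data
  X <- build_design(cohort)
  lp <- as.vector(X %*% beta)
  ft <- sort(unique(d$exit_time[d$event == 1]))
  ll <- 0
  for (t in ft) {
    Dj <- which(d$event == 1 & d$exit_time == t)
    Rj <- which(d$entry_time < t & d$exit_time >= t)
    ll <- ll + sum(lp[Dj]) - length(Dj) * log(sum(exp(lp[Rj])))
  }
  ll
}

# Dense-grid log-scale integration oracle for cluster-marginal likelihoods
# (integrate() on the product of densities underflows; this does not).
trapz_marginal_cluster <- function(logdens_of_u, prior_log, lo, hi,
                                   n = 20001L) {
  u <- seq(lo, hi, length.out = n)
  lf <- vapply(u, function(uv) logdens_of_u(uv) + prior_log(uv), numeric(1))
  m <- max(lf)
  m + log(sum(exp(lf - m)) * (u[2L] - u[1L]))
}
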