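#' Incidence rate from event count and person-time
#'
#' Events per day of observed risk time: the number of new complications
#' during the observation period divided by the time each person was
#' observed, totalled over all persons.
#'
#' @param events Non-negative event count.
#' @param person_time Total at-risk time in days; must be positive.
#' @return A list of class `incidence_result` with `events`, `person_time`
#'   and `rate` (events per day).
#' @examples
#' incidence_rate(469, 1947391)  # 0.000241 complications per day
#' @export
incidence_rate <- function(events, person_time) {
  stopifnot(length(events) == 1L, length(person_time) == 1L)
  if (!is.finite(person_time) || person_time <= 0) {
    stop("person_time must be positive")
  }
  if (!is.finite(events) || events < 0) stop("events must be >= 0")
  structure(
    list(events = events, person_time = person_time,
         rate = events / person_time),
    class = "incidence_result"
  )
}

#' @export
print.incidence_result <- function(x, ...) {
  cat(sprintf("%d events / %s person-days = %.6f per day\n",
              x$events, format(x$person_time, big.mark = ","), x$rate))
  invisible(x)
}

#' Incidence rate of a cohort
#'
#' @param cohort A `cohort`.
#' @return An `incidence_result` for the whole cohort.
#' @export
cohort_incidence <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  incidence_rate(sum(cohort$data$event), person_time(cohort))
}

km_from_survfit <- function(sf) {
  keep <- sf$n.event > 0
  structure(
    list(event_times = sf$time[keep],
         survival = sf$surv[keep],
         at_risk = sf$n.risk[keep],
         n_events = sf$n.event[keep]),
    class = "km_estimate"
  )
}

#' Kaplan-Meier product-limit estimate
#'
#' Nonparametric estimate of the survival function, optionally stratified by
#' one categorical covariate. Ties between events and censorings at the same
#' time follow the product-limit convention: events precede censorings, so a
#' record censored at an event time is still in the risk set of that event.
#' Delayed entry (`entry_time > 0`) is honoured.
#'
#' @param cohort A `cohort`.
#' @param group_by Optional name of a covariate in the cohort's
#'   specification; one estimate per level is returned. Levels with no
#'   records are skipped with a message.
#' @return For `group_by = NULL`, a `km_estimate` (fields `event_times`,
#'   `survival`, `at_risk`, `n_events`); otherwise a named list of
#'   `km_estimate` objects.
#' @export
km_fit <- function(cohort, group_by = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data
  if (sum(d$event) < 1) stop("km_fit requires at least one event")
  surv_obj <- survival::Surv(d$entry_time, d$exit_time, d$event)
  if (is.null(group_by)) {
    sf <- survival::survfit(surv_obj ~ 1, conf.type = "none")
    return(km_from_survfit(sf))
  }
  if (!group_by %in% names(cohort$spec)) {
    stop("'", group_by, "' is not a covariate of this cohort")
  }
  out <- list()
  for (lv in cohort$spec[[group_by]]) {
    idx <- d[[group_by]] == lv
    if (!any(idx)) {
      message("km_fit: level '", lv, "' of '", group_by,
              "' has no records; skipped")
      next
    }
    di <- d[idx, , drop = FALSE]
    if (sum(di$event) == 0) {
      out[[lv]] <- structure(
        list(event_times = numeric(0), survival = numeric(0),
             at_risk = integer(0), n_events = integer(0)),
        class = "km_estimate")
      next
    }
    sf <- survival::survfit(
      survival::Surv(di$entry_time, di$exit_time, di$event) ~ 1,
      conf.type = "none")
    out[[lv]] <- km_from_survfit(sf)
  }
  out
}

#' Quantile survival time with a "cannot be computed" sentinel
#'
#' The q-th quantile survival time is the smallest observed event time at
#' which the Kaplan-Meier curve has fallen to `1 - q` or below (no
#' interpolation). When the curve never reaches `1 - q` -- as happens under
#' heavy censoring -- the quantile cannot be computed and the sentinel is
#' returned (rendered as `"cbc"` in tabular output).
#'
#' @param km A `km_estimate`.
#' @param q Quantile as a fraction in (0, 1); `q = 0.5` is the median.
#' @return A list of class `quantile_survival` with `quantile`, `time`
#'   (`NA_real_` when not computable) and `computable`.
#' @export
survival_quantile <- function(km, q) {
  stopifnot(inherits(km, "km_estimate"), length(q) == 1L)
  if (!is.finite(q) || q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  hit <- which(km$survival <= 1 - q + 1e-12)
  structure(
    list(quantile = q,
         time = if (length(hit)) km$event_times[hit[1L]] else NA_real_,
         computable = length(hit) > 0),
    class = "quantile_survival"
  )
}

#' @export
print.quantile_survival <- function(x, ...) {
  cat(sprintf("%g%% survival time: %s\n", 100 * x$quantile,
              if (x$computable) format(x$time) else "cbc"))
  invisible(x)
}

quantile_label <- function(qs) {
  if (qs$computable) format(qs$time) else "cbc"
}

table1_rows <- function(d, label, n_total) {
  pt <- sum(d$exit_time - d$entry_time)
  ev <- sum(d$event)
  if (ev > 0) {
    sf <- survival::survfit(
      survival::Surv(d$entry_time, d$exit_time, d$event) ~ 1,
      conf.type = "none")
    km <- km_from_survfit(sf)
    qs <- lapply(c(0.25, 0.5, 0.75), function(q) survival_quantile(km, q))
  } else {
    qs <- replicate(3, structure(
      list(quantile = NA_real_, time = NA_real_, computable = FALSE),
      class = "quantile_survival"), simplify = FALSE)
  }
  data.frame(
    level = label,
    n = nrow(d),
    pct = round(100 * nrow(d) / n_total, 1),
    days_at_risk = pt,
    incidence_rate = sprintf("%.6f", ev / pt),
    q25 = quantile_label(qs[[1L]]),
    median = quantile_label(qs[[2L]]),
    q75 = quantile_label(qs[[3L]]),
    stringsAsFactors = FALSE
  )
}

#' Descriptive table of incidence rates and quartile survival times
#'
#' For each level of each requested covariate, and for the cohort as a
#' whole: number of records (with percentage within the category), days at
#' risk, incidence rate per day (6 decimals), and the 25%, 50% (median) and
#' 75% survival times from the group's Kaplan-Meier curve, with the literal
#' `"cbc"` where a quantile cannot be computed.
#'
#' @param cohort A `cohort`.
#' @param categories Covariate names to tabulate; default all in the spec.
#' @return A data frame with columns `category`, `level`, `n`, `pct`,
#'   `days_at_risk`, `incidence_rate`, `q25`, `median`, `q75`.
#' @export
table1 <- function(cohort, categories = names(cohort$spec)) {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data
  out <- list()
  for (cat_nm in categories) {
    if (!cat_nm %in% names(cohort$spec)) {
      stop("'", cat_nm, "' is not a covariate of this cohort")
    }
    for (lv in cohort$spec[[cat_nm]]) {
      di <- d[d[[cat_nm]] == lv, , drop = FALSE]
      if (nrow(di) == 0L) next
      row <- table1_rows(di, lv, nrow(d))
      row <- cbind(category = cat_nm, row)
      out[[length(out) + 1L]] <- row
    }
  }
  total <- cbind(category = "Total", table1_rows(d, "Total", nrow(d)))
  out[[length(out) + 1L]] <- total
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
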