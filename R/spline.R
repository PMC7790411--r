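#' Restricted cubic spline basis on log time
#'
#' Places the knots of a restricted cubic spline of log time for a flexible
#' parametric (Royston-Parmar) survival model. With `df` degrees of freedom
#' the basis has `df` columns: the linear term `ln t` plus `df - 1` curvature
#' terms, one per internal knot. Internal knots sit at the centiles
#' `100 * j / df`, `j = 1, ..., df - 1`, of the uncensored log event times;
#' boundary knots sit at the minimum and maximum uncensored log event time.
#' `df = 1` places no internal knots and the basis is `{ln t}` alone, which
#' makes the resulting survival model exactly Weibull.
#'
#' @param df Degrees of freedom, an integer in 1..9 (at most 9 knots are
#'   supported).
#' @param uncensored_log_times Log event times of the uncensored records.
#' @return An object of class `rcs_basis`: list with `df`, `internal_knots`,
#'   `boundary_knots` and `transform` (`NULL` until [orthogonalize_basis()]
#'   is applied).
#' @export
place_knots <- function(df, uncensored_log_times) {
  df <- as.integer(df)
  if (is.na(df) || df < 1L) stop("df must be a positive integer")
  if (df > 9L) stop("df must not exceed 9 (at most 9 knots)")
  x <- uncensored_log_times[is.finite(uncensored_log_times)]
  if (length(x) < 1L) stop("no finite uncensored log times supplied")
  if (df >= 2L && length(unique(x)) < df + 1L) {
    stop("need at least df + 1 distinct uncensored times (have ",
         length(unique(x)), ") for df = ", df)
  }
  internal <- if (df == 1L) numeric(0) else {
    unname(stats::quantile(x, probs = seq_len(df - 1L) / df, type = 7))
  }
  boundary <- range(x)
  if (df >= 2L &&
      (any(internal <= boundary[1L]) || any(internal >= boundary[2L]))) {
    stop("internal knots must lie strictly between the boundary knots; ",
         "the uncensored time distribution is too concentrated")
  }
  structure(
    list(df = df, internal_knots = internal, boundary_knots = boundary,
         transform = NULL),
    class = "rcs_basis"
  )
}

#' @export
print.rcs_basis <- function(x, ...) {
  cat("Restricted cubic spline basis on log time, df =", x$df, "\n")
  cat("  boundary knots:", paste(signif(x$boundary_knots, 6), collapse = ", "),
      "\n")
  if (length(x$internal_knots)) {
    cat("  internal knots:",
        paste(signif(x$internal_knots, 6), collapse = ", "), "\n")
  }
  if (!is.null(x$transform)) cat("  (orthogonalized)\n")
  invisible(x)
}

pos3 <- function(u) pmax(u, 0)^3
pos2 <- function(u) pmax(u, 0)^2

raw_rcs_eval <- function(basis, x) {
  k1 <- basis$boundary_knots[1L]
  kk <- basis$boundary_knots[2L]
  z <- matrix(0, nrow = length(x), ncol = basis$df)
  z[, 1L] <- x
  if (basis$df >= 2L) {
    for (j in seq_along(basis$internal_knots)) {
      kj <- basis$internal_knots[j]
      phi <- (kk - kj) / (kk - k1)
      z[, j + 1L] <- pos3(x - kj) - phi * pos3(x - k1) -
        (1 - phi) * pos3(x - kk)
    }
  }
  colnames(z) <- paste0("z", seq_len(basis$df))
  z
}

raw_rcs_deriv <- function(basis, x) {
  k1 <- basis$boundary_knots[1L]
  kk <- basis$boundary_knots[2L]
  dz <- matrix(0, nrow = length(x), ncol = basis$df)
  dz[, 1L] <- 1
  if (basis$df >= 2L) {
    for (j in seq_along(basis$internal_knots)) {
      kj <- basis$internal_knots[j]
      phi <- (kk - kj) / (kk - k1)
      dz[, j + 1L] <- 3 * (pos2(x - kj) - phi * pos2(x - k1) -
                             (1 - phi) * pos2(x - kk))
    }
  }
  colnames(dz) <- paste0("z", seq_len(basis$df))
  dz
}

#' Evaluate a restricted cubic spline basis
#'
#' Column 1 is the linear term `z1 = x`; columns `j >= 2` are the truncated
#' cubic curvature terms
#' `z_j = (x - k_j)+^3 - phi_j (x - k_1)+^3 - (1 - phi_j) (x - k_k)+^3` with
#' `phi_j = (k_k - k_j) / (k_k - k_1)` and `(u)+^3 = max(0, u)^3`, where
#' `k_1`, `k_k` are the boundary knots. The restriction forces the spline to
#' be linear beyond the boundary knots; values of `x` outside the boundaries
#' are therefore permitted. If the basis carries an orthogonalization
#' transform it is applied last.
#'
#' @param basis An `rcs_basis`.
#' @param x Numeric vector of log-time values.
#' @return A numeric matrix, one row per element of `x`, `df` columns.
#' @export
rcs_eval <- function(basis, x) {
  stopifnot(inherits(basis, "rcs_basis"), is.numeric(x), all(is.finite(x)))
  z <- raw_rcs_eval(basis, x)
  if (!is.null(basis$transform)) {
    w <- cbind(1, z) %*% basis$transform
    z <- w[, -1L, drop = FALSE]
    colnames(z) <- paste0("z", seq_len(basis$df))
  }
  z
}

#' First derivative of a restricted cubic spline basis
#'
#' Analytic derivative of each basis column with respect to `x`; consistent
#' with any stored orthogonalization transform (the intercept column of the
#' transform differentiates to zero).
#'
#' @inheritParams rcs_eval
#' @return A numeric matrix, one row per element of `x`, `df` columns.
#' @export
rcs_deriv <- function(basis, x) {
  stopifnot(inherits(basis, "rcs_basis"), is.numeric(x), all(is.finite(x)))
  dz <- raw_rcs_deriv(basis, x)
  if (!is.null(basis$transform)) {
    w <- cbind(0, dz) %*% basis$transform
    dz <- w[, -1L, drop = FALSE]
    colnames(dz) <- paste0("z", seq_len(basis$df))
  }
  dz
}

#' Gram-Schmidt orthogonalization of the spline basis
#'
#' The derived curvature columns can be highly correlated with each other and
#' with `ln t`; orthogonalizing them over a sample of log times stabilizes
#' estimation. The columns (together with an implicit intercept) are
#' orthogonalized by QR decomposition -- numerically equivalent to
#' Gram-Schmidt -- over `sample_x`, and the invertible linear transform is
#' stored on the basis so that fitted models and predictions are invariant
#' to whether orthogonalization is used.
#'
#' @param basis An `rcs_basis` (untransformed).
#' @param sample_x Log-time sample over which to orthogonalize; must contain
#'   at least `df + 1` distinct values.
#' @return The basis with its `transform` set.
#' @export
orthogonalize_basis <- function(basis, sample_x) {
  stopifnot(inherits(basis, "rcs_basis"))
  if (!is.null(basis$transform)) stop("basis is already orthogonalized")
  x <- sample_x[is.finite(sample_x)]
  if (length(unique(x)) < basis$df + 1L) {
    stop("need at least df + 1 distinct sample points to orthogonalize")
  }
  w <- cbind(1, raw_rcs_eval(basis, x))
  qrw <- qr(w)
  if (qrw$rank < ncol(w)) stop("spline design is rank deficient over sample_x")
  r <- qr.R(qrw)
  # fix signs so the diagonal of R is positive (columns keep orientation)
  s <- sign(diag(r))
  r <- r * s  # row-wise scaling flips the corresponding Q columns
  tr <- backsolve(r, diag(ncol(w))) * sqrt(length(x))
  dimnames(tr) <- NULL
  basis$transform <- tr
  basis
}

#' Serialize / restore a spline basis
#'
#' JSON round-trip of knots, degrees of freedom and the orthogonalization
#' transform, so that a fitted model's predictions are reproducible from
#' stored text.
#'
#' @param basis An `rcs_basis`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (or `path` invisibly); `basis_from_json` returns the
#'   restored `rcs_basis`.
#' @export
basis_to_json <- function(basis, path = NULL) {
  stopifnot(inherits(basis, "rcs_basis"))
  obj <- list(df = basis$df,
              internal_knots = basis$internal_knots,
              boundary_knots = basis$boundary_knots,
              transform = basis$transform)
  json <- jsonlite::toJSON(obj, digits = NA, null = "null", auto_unbox = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

#' @rdname basis_to_json
#' @param json JSON string or file path produced by [basis_to_json()].
#' @export
basis_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json)
  obj <- jsonlite::fromJSON(paste(json, collapse = ""))
  tr <- obj$transform
  if (!is.null(tr)) tr <- matrix(unlist(tr), nrow = obj$df + 1L)
  structure(
    list(df = as.integer(obj$df),
         internal_knots = as.numeric(obj$internal_knots),
         boundary_knots = as.numeric(obj$boundary_knots),
         transform = tr),
    class = "rcs_basis"
  )
}
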