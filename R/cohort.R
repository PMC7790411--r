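#' Define the categorical covariate structure of a cohort
#'
#' A covariate specification lists, for each modelled categorical covariate,
#' its ordered levels. The first level of each category is the reference
#' level and contributes no column to the design matrix.
#'
#' @param ... Named character vectors; each name is a covariate (a column of
#'   the cohort data) and each vector its ordered levels, reference first.
#' @return An object of class `covariate_spec`.
#' @examples
#' covariate_spec(periodontal = c("Healthy", "Periodontitis", "No teeth"))
#' @export
covariate_spec <- function(...) {
  spec <- list(...)
  if (length(spec) == 0L) {
    return(structure(list(), class = "covariate_spec"))
  }
  if (is.null(names(spec)) || any(names(spec) == "")) {
    stop("every covariate in a covariate_spec must be named")
  }
  for (nm in names(spec)) {
    lv <- spec[[nm]]
    if (!is.character(lv) || length(lv) < 1L || anyDuplicated(lv)) {
      stop("levels of '", nm, "' must be a character vector of distinct labels")
    }
  }
  structure(spec, class = "covariate_spec")
}

#' Covariate specification of the implant-complication study design
#'
#' Seven categorical covariates with the level sets and reference levels used
#' in the adjusted analysis of the Swedish implant-complication cohort:
#' periodontal status, extent of treatment, age group, sex, ever-smoker
#' status, dental product and retention of restoration.
#'
#' @return A `covariate_spec` with 7 categories and 14 non-reference levels.
#' @export
implant_covariate_spec <- function() {
  covariate_spec(
    periodontal = c("Healthy", "Periodontitis", "No teeth"),
    extent      = c("Single", "Full jaw", "Partial jaw"),
    age_group   = c("<50", "50-59", "60-69", "70-79"),
    sex         = c("Female", "Male"),
    ever_smoker = c("No", "Yes"),
    product     = c("Type A", "Type B", "Type C", "Type D"),
    retention   = c("Screw-retained", "Cemented", "Both")
  )
}

#' Construct a validated cohort of clustered time-to-event records
#'
#' A cohort holds one row per analysis record: the at-risk interval
#' `(entry_time, exit_time]` in days, the event indicator (1 = complication
#' observed at `exit_time`, 0 = censored), a cluster identifier (the patient,
#' when records are implants) and the categorical covariates named in the
#' covariate specification.
#'
#' @param data A data frame with columns `subject_id`, `cluster_id`,
#'   `entry_time`, `exit_time`, `event`, plus one column per covariate in
#'   `spec`. `entry_time` is optional and defaults to 0 (time is measured
#'   from implant insertion).
#' @param spec A [covariate_spec()].
#' @return An object of class `cohort`: a list with elements `data`
#'   (validated data frame, covariates as factors) and `spec`.
#' @export
as_cohort <- function(data, spec = covariate_spec()) {
  stopifnot(inherits(spec, "covariate_spec"), is.data.frame(data))
  data <- as.data.frame(data)
  required <- c("subject_id", "cluster_id", "exit_time", "event")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("cohort data lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"entry_time" %in% names(data)) data$entry_time <- 0
  if (nrow(data) == 0L) stop("cohort has no records")

  for (col in c("entry_time", "exit_time", "event")) {
    v <- data[[col]]
    if (!is.numeric(v)) stop("column '", col, "' must be numeric")
    if (anyNA(v)) {
      stop("column '", col, "' has missing values (row ",
           which(is.na(v))[1L], ")")
    }
  }
  if (any(data$entry_time < 0)) stop("entry_time must be >= 0")
  bad <- which(data$exit_time <= data$entry_time)
  if (length(bad)) {
    stop("exit_time must be strictly greater than entry_time (row ",
         bad[1L], ")")
  }
  if (!all(data$event %in% c(0, 1))) stop("event must be 0 or 1")

  for (nm in names(spec)) {
    if (!nm %in% names(data)) stop("covariate column '", nm, "' not found")
    lev <- spec[[nm]]
    vals <- as.character(data[[nm]])
    unknown <- setdiff(unique(vals[!is.na(vals)]), lev)
    if (length(unknown)) {
      stop("unknown level(s) for '", nm, "': ",
           paste(unknown, collapse = ", "))
    }
    if (anyNA(vals)) {
      stop("covariate '", nm, "' has missing values; drop or complete them ",
           "before constructing the cohort (see read_cohort)")
    }
    data[[nm]] <- factor(vals, levels = lev)
  }

  keep <- c("subject_id", "cluster_id", "entry_time", "exit_time", "event",
            names(spec))
  data <- data[, keep, drop = FALSE]
  rownames(data) <- NULL
  structure(list(data = data, spec = spec), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  d <- x$data
  cat("A cohort of", nrow(d), "records in",
      length(unique(d$cluster_id)), "clusters\n")
  cat("  events:", sum(d$event), " person-days:",
      format(sum(d$exit_time - d$entry_time), big.mark = ","), "\n")
  if (length(x$spec)) {
    cat("  covariates:", paste(names(x$spec), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of records in a cohort
#' @param x A `cohort`.
#' @export
n_records <- function(x) {
  stopifnot(inherits(x, "cohort"))
  nrow(x$data)
}

#' Number of clusters (patients) in a cohort
#' @param x A `cohort`.
#' @export
n_clusters <- function(x) {
  stopifnot(inherits(x, "cohort"))
  length(unique(x$data$cluster_id))
}

#' Read a cohort from CSV
#'
#' Reads a comma-separated file with a header row and the columns
#' `subject_id`, `cluster_id`, `entry_time` (optional, defaults to 0),
#' `exit_time`, `event`, plus the covariate columns named in `spec`.
#' Records with a missing value in any modelled covariate are dropped with a
#' message reporting the count (no imputation is performed); records with
#' malformed or invalid time fields are an error.
#'
#' @param path Path to a CSV file.
#' @param spec A [covariate_spec()]. May also be a path to a YAML/JSON file
#'   as written by [write_covariate_spec()].
#' @return A `cohort`. The number of dropped records is available as
#'   `attr(cohort, "n_dropped")`.
#' @export
read_cohort <- function(path, spec = covariate_spec()) {
  if (is.character(spec)) spec <- read_covariate_spec(spec)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  for (col in intersect(c("entry_time", "exit_time", "event"), names(raw))) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad)) {
        stop("malformed numeric value in column '", col, "', row ", bad[1L],
             ": '", v[bad[1L]], "'")
      }
      raw[[col]] <- conv
    }
  }
  # drop records with missing modelled covariates, mirroring the exclusion
  # of incomplete subjects from the analysis
  incomplete <- rep(FALSE, nrow(raw))
  for (nm in names(spec)) {
    if (!nm %in% names(raw)) stop("covariate column '", nm, "' not found")
    incomplete <- incomplete | is.na(raw[[nm]])
  }
  n_dropped <- sum(incomplete)
  if (n_dropped > 0) {
    message(n_dropped, " record(s) dropped due to missing covariate data")
    raw <- raw[!incomplete, , drop = FALSE]
  }
  out <- as_cohort(raw, spec)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: writing then re-reading with the same
#' specification reproduces the cohort exactly.
#'
#' @param cohort A `cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data
  for (nm in names(cohort$spec)) d[[nm]] <- as.character(d[[nm]])
  utils::write.csv(d, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write / read a covariate specification as YAML
#'
#' The specification is stored as a mapping from category name to the ordered
#' level list (reference level first).
#'
#' @param spec A `covariate_spec`.
#' @param path File path (YAML).
#' @return `path` invisibly, or the `covariate_spec` read back.
#' @export
write_covariate_spec <- function(spec, path) {
  stopifnot(inherits(spec, "covariate_spec"))
  yaml::write_yaml(lapply(unclass(spec), as.list), path)
  invisible(path)
}

#' @rdname write_covariate_spec
#' @export
read_covariate_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(covariate_spec, lapply(raw, function(x) unlist(x, use.names = FALSE)))
}

#' Build the dummy design matrix of a cohort
#'
#' One 0/1 column per non-reference covariate level, in deterministic order:
#' categories in specification order, then levels in level order. Reference
#' levels contribute no column, so a record at all-reference levels maps to an
#' all-zero row. Column names are `"<category>=<level>"`.
#'
#' @param cohort A `cohort`.
#' @return A numeric matrix with `n_records(cohort)` rows and
#'   `sum(levels - 1)` columns.
#' @export
build_design <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data
  if (nrow(d) == 0L) stop("empty cohort")
  cols <- list()
  for (nm in names(cohort$spec)) {
    lev <- cohort$spec[[nm]]
    for (lv in lev[-1L]) {
      cols[[paste0(nm, "=", lv)]] <- as.numeric(d[[nm]] == lv)
    }
  }
  if (length(cols) == 0L) {
    return(matrix(numeric(0), nrow = nrow(d), ncol = 0L))
  }
  do.call(cbind, cols)
}

#' Total person-time of a cohort in days
#' @param cohort A `cohort`.
#' @export
person_time <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  sum(cohort$data$exit_time - cohort$data$entry_time)
}
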