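#' Patient record of panel-observed eGFR stages
#'
#' One patient's irregular observation history: times (years since entry) and
#' observed living stages of each eGFR test, an exactly observed death time if
#' the patient died, and the administrative censoring time otherwise.
#'
#' @param patient_id scalar id (character or integer).
#' @param profile a [covariate_profile()].
#' @param times numeric, strictly increasing observation times in years,
#'   starting at or after 0.
#' @param stages character, observed living stage labels (same length).
#' @param death_time death time in years, or `NA` if alive at censoring.
#' @param censor_time administrative censor time (>= last observation).
#' @return Object of class `ckd_record`.
#' @export
patient_record <- function(patient_id, profile, times, stages,
                           death_time = NA_real_, censor_time = NA_real_) {
  stopifnot(inherits(profile, "ckd_profile"))
  times <- as.numeric(times)
  stages <- as.character(stages)
  if (length(times) != length(stages)) {
    stop("times and stages must have equal length")
  }
  if (length(times) && (any(diff(times) <= 0) || times[1] < 0)) {
    stop("observation times must be non-negative and strictly increasing")
  }
  if (any(stages == death_state())) {
    stop("DEATH is not an observed test result; use death_time")
  }
  stage_index(stages)  # validates labels
  died <- !is.na(death_time)
  if (died && length(times) && death_time <= times[length(times)]) {
    stop("death_time must follow the last eGFR observation")
  }
  if (is.na(censor_time)) {
    censor_time <- if (died) death_time else
      if (length(times)) times[length(times)] else 0
  }
  if (!died && length(times) && censor_time < times[length(times)] - 1e-12) {
    stop("censor_time must not precede the last observation")
  }
  structure(
    list(patient_id = patient_id, profile = profile, times = times,
         stages = stages, death_time = as.numeric(death_time),
         censor_time = as.numeric(censor_time)),
    class = "ckd_record"
  )
}

record_died <- function(record) !is.na(record$death_time)

#' @export
print.ckd_record <- function(x, ...) {
  cat("Patient", x$patient_id, "-", length(x$times), "eGFR tests over",
      round(max(c(x$times, 0)), 2), "years;",
      if (record_died(x)) paste("died at", round(x$death_time, 2))
      else paste("censored at", round(x$censor_time, 2)), "\n")
  invisible(x)
}

#' Cohort of patient records
#'
#' @param records list of [patient_record()] objects sharing one albuminuria
#'   stratum.
#' @param stratum albuminuria stratum label.
#' @param truth optional `ckd_params` that generated the cohort (kept for
#'   truth-known experiments).
#' @param dropped number of simulated patients removed by the minimum-test
#'   filter (bookkeeping from [generate_cohort()]).
#' @return Object of class `ckd_cohort`.
#' @export
ckd_cohort <- function(records, stratum = "unmeasured", truth = NULL,
                       dropped = 0L) {
  assert_stratum(stratum)
  if (!all(vapply(records, inherits, logical(1), "ckd_record"))) {
    stop("records must be a list of ckd_record objects")
  }
  ids <- vapply(records, function(r) as.character(r$patient_id), character(1))
  if (anyDuplicated(ids)) stop("patient ids must be unique")
  ok <- vapply(records, function(r) r$profile$stratum == stratum, logical(1))
  if (!all(ok)) stop("all records must share the cohort's stratum")
  structure(list(records = records, stratum = stratum, truth = truth,
                 dropped = as.integer(dropped)),
            class = "ckd_cohort")
}

#' @export
length.ckd_cohort <- function(x) length(x$records)

#' @export
print.ckd_cohort <- function(x, ...) {
  nobs <- sum(vapply(x$records, function(r) length(r$times), integer(1)))
  ndead <- sum(vapply(x$records, record_died, logical(1)))
  cat("eGFR panel cohort (", x$stratum, " albuminuria): ",
      length(x$records), " patients, ", nobs, " tests, ", ndead,
      " deaths\n", sep = "")
  if (x$dropped > 0) {
    cat("  (", x$dropped, " simulated patients dropped by the >=3-test rule)\n",
        sep = "")
  }
  invisible(x)
}

#' Long-format view of a cohort
#'
#' One row per eGFR observation plus, for patients who died, a final row with
#' `observed_stage = DEATH` at the death time. The layout matches the CSV
#' interchange schema of [write_cohort_csv()].
#'
#' @param x a `ckd_cohort`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return A `data.frame`.
#' @export
as.data.frame.ckd_cohort <- function(x, row.names = NULL, optional = FALSE, ...) {
  if (!length(x$records)) {
    return(data.frame(patient_id = character(), time_years = numeric(),
                      age_years = numeric(), observed_stage = character(),
                      sex = numeric(), heart_failure = numeric(),
                      cancer = numeric(), hypertension = numeric(),
                      diabetes = numeric(), age_at_entry = numeric(),
                      albuminuria_stratum = character(),
                      censor_time_years = numeric(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(x$records, function(r) {
    p <- r$profile
    n <- length(r$times) + record_died(r)
    data.frame(
      patient_id = rep(as.character(r$patient_id), n),
      time_years = c(r$times, if (record_died(r)) r$death_time),
      age_years = p$age_at_entry + c(r$times, if (record_died(r)) r$death_time),
      observed_stage = c(r$stages, if (record_died(r)) death_state()),
      sex = p$sex, heart_failure = p$heart_failure, cancer = p$cancer,
      hypertension = p$hypertension, diabetes = p$diabetes,
      age_at_entry = p$age_at_entry,
      albuminuria_stratum = p$stratum,
      censor_time_years = r$censor_time,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
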