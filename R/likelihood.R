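#' Likelihood evaluation options
#'
#' @param init initial-state convention at the first test: `"obs"` (default;
#'   the true state at the first observation is taken to equal the observed
#'   stage) or `"emission"` (the first observation is itself subject to
#'   misclassification; the hidden initial state has prior `init_probs`
#'   re-weighted by the emission row).
#' @param init_probs prior over living stages used by `init = "emission"`;
#'   `"uniform"`, `"empirical"` (frequencies of first observed stages in the
#'   cohort at hand) or a length-5 probability vector.
#' @param age_update `"interval_start"` (default; covariate value at the
#'   start of each observation interval, the standard panel-data convention)
#'   or `"annual"` (exact: intervals are split at integer age anniversaries,
#'   matching the simulator's annual age refresh).
#' @param use_censor include the survival factor from the last test to the
#'   administrative censor time for patients known alive at censoring
#'   (default `TRUE`; death times are exactly observed, so dropping this
#'   factor would overstate death rates).
#' @return A list of class `ckd_lik_options`.
#' @export
likelihood_options <- function(init = c("obs", "emission"),
                               init_probs = "uniform",
                               age_update = c("interval_start", "annual"),
                               use_censor = TRUE) {
  init <- match.arg(init)
  age_update <- match.arg(age_update)
  structure(list(init = init, init_probs = init_probs,
                 age_update = age_update, use_censor = isTRUE(use_censor)),
            class = "ckd_lik_options")
}

resolve_init_probs <- function(options, records) {
  ip <- options$init_probs
  if (is.character(ip)) {
    if (ip == "uniform") return(rep(1 / 5, 5))
    if (ip == "empirical") {
      first <- vapply(records, function(r) r$stages[1], character(1))
      tab <- table(factor(first, levels = stage_levels()))
      p <- as.numeric(tab) + 0.5  # smoothed
      return(p / sum(p))
    }
    stop("init_probs must be 'uniform', 'empirical' or a length-5 vector")
  }
  ip <- as.numeric(ip)
  if (length(ip) != 5L || any(ip < 0) || sum(ip) <= 0) {
    stop("init_probs must be a length-5 non-negative vector")
  }
  ip / sum(ip)
}

# Flatten records into the contiguous arrays the C++ engine consumes.
records_for_cpp <- function(records) {
  list(
    n_obs = vapply(records, function(r) length(r$times), integer(1)),
    t = unlist(lapply(records, `[[`, "times"), use.names = FALSE),
    s = unlist(lapply(records, function(r) stage_index(r$stages)),
               use.names = FALSE),
    died = vapply(records, function(r) as.integer(record_died(r)), integer(1)),
    tdeath = vapply(records, function(r)
      if (record_died(r)) r$death_time else -1, numeric(1)),
    censor = vapply(records, function(r) r$censor_time, numeric(1)),
    age_entry = vapply(records, function(r) r$profile$age_at_entry, numeric(1))
  )
}

record_multipliers <- function(params, records) {
  mp <- vapply(records, function(r) profile_multipliers(params, r$profile)["prog"],
               numeric(1))
  md <- vapply(records, function(r) profile_multipliers(params, r$profile)["death"],
               numeric(1))
  list(prog = mp, death = md)
}

cohort_loglik_engine <- function(records, params, options, want_grad = FALSE) {
  m <- record_multipliers(params, records)
  initp <- resolve_init_probs(options, records)
  fl <- records_for_cpp(records)
  cohort_loglik_cpp(
    n_obs = fl$n_obs, t_all = fl$t, s_all = fl$s, died = fl$died,
    tdeath = fl$tdeath, censor = fl$censor, age_entry = fl$age_entry,
    q_prog = unname(params$q_prog), q_death = unname(params$q_death),
    am_prog = unname(params$age_mult["prog"]),
    am_death = unname(params$age_mult["death"]),
    mult_prog = m$prog, mult_death = m$death,
    E5 = params$emission[1:5, 1:5],
    init_emission = options$init == "emission",
    initp = initp,
    annual_split = options$age_update == "annual",
    use_censor = options$use_censor,
    want_grad = want_grad
  )
}

#' Log-likelihood of one patient record
#'
#' Forward-algorithm likelihood of the observed stage sequence under the
#' hidden Markov model: between consecutive tests the hidden stage evolves by
#' `P(dt) = exp(dt Q)` with covariates evaluated per the age-updating
#' convention, each test contributes the emission probability of its observed
#' stage, an exactly observed death contributes the density
#' `sum_s P(dt)[., s] q_{s,death}`, and a patient known alive at censoring
#' contributes the probability of remaining in a living stage. Impossible
#' sequences (e.g. an observed regression under an identity emission matrix)
#' have likelihood zero and log-likelihood `-Inf`.
#'
#' @param record a [patient_record()].
#' @param params a [model_parameters()] object.
#' @param options a [likelihood_options()] list.
#' @return Scalar log-likelihood.
#' @export
record_log_likelihood <- function(record, params,
                                  options = likelihood_options()) {
  stopifnot(inherits(record, "ckd_record"))
  validate_parameters(params)
  if (!length(record$times)) stop("record has no observations")
  cohort_loglik_engine(list(record), params, options)$loglik
}

#' Log-likelihood of a cohort
#'
#' Sum of [record_log_likelihood()] over patients; independent of patient
#' order and of any partition of the cohort.
#'
#' @param cohort a [ckd_cohort()].
#' @inheritParams record_log_likelihood
#' @return Scalar log-likelihood (0, with a warning, for an empty cohort).
#' @export
cohort_log_likelihood <- function(cohort, params,
                                  options = likelihood_options()) {
  stopifnot(inherits(cohort, "ckd_cohort"))
  validate_parameters(params)
  if (!length(cohort$records)) {
    warning("empty cohort: log-likelihood 0")
    return(0)
  }
  cohort_loglik_engine(cohort$records, params, options)$loglik
}
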