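#' Generator presets per albuminuria cohort
#'
#' Default parameter sets and population mixes for the synthetic-cohort
#' generator, one per albuminuria stratum. Baseline intensities are specified
#' on the scale results are usually quoted on — one-year transition
#' probabilities for the reference profile (woman aged 60, no heart failure,
#' no cancer) — and converted to rates with [rates_from_annual_probs()]. The
#' progression probabilities lie inside the per-cohort ranges the model class
#' produces on primary-care data (0.75-1.3%, 1.5-2.5%, 3.4-5.4% and
#' 3.1-11.9%/year for unmeasured, normo-, micro- and macroalbuminuria);
#' baseline stage occupancy, covariate prevalences and the age mix follow the
#' published cohort description. Misclassification, death-probability and
#' covariate-multiplier values are stated generator assumptions (see the
#' methods vignette).
#'
#' @param stratum albuminuria stratum label.
#' @param n number of patients to simulate.
#' @return A `ckd_cohort_config` list, ready for [generate_cohort()].
#' @export
cohort_preset <- function(stratum = "unmeasured", n = 1000) {
  assert_stratum(stratum)
  p_next <- switch(stratum,
    unmeasured = c(1.10, 0.85, 1.00, 1.30),
    normo      = c(1.50, 1.70, 2.00, 2.50),
    micro      = c(3.40, 4.00, 4.60, 5.40),
    macro      = c(3.10, 5.00, 8.00, 11.90)) / 100
  p_death <- switch(stratum,
    unmeasured = c(0.70, 1.20, 2.00, 3.50, 13.0),
    normo      = c(1.00, 1.60, 2.60, 4.50, 15.0),
    micro      = c(1.50, 2.50, 4.00, 6.00, 18.0),
    macro      = c(2.00, 3.50, 6.00, 9.00, 16.0)) / 100
  rates <- rates_from_annual_probs(p_next, p_death)
  params <- model_parameters(
    q_prog = rates$q_prog, q_death = rates$q_death,
    age_mult = c(prog = 1.08, death = 1.09),
    cov_mult = rbind(sex = c(1.25, 1.40),
                     heart_failure = c(1.35, 2.00),
                     cancer = c(1.10, 2.20)),
    misclass = default_misclass(),
    stratum = stratum
  )
  init_probs <- switch(stratum,
    unmeasured = c(79.3, 15.4, 4.4, 0.8, 0.1),
    normo      = c(73.1, 18.1, 7.2, 1.6, 0.1),
    micro      = c(59.7, 21.0, 14.1, 5.1, 0.3),
    macro      = c(55.7, 19.5, 15.5, 8.4, 0.9))
  init_probs <- init_probs / sum(init_probs)
  names(init_probs) <- stage_levels()
  prevalence <- switch(stratum,
    unmeasured = c(sex = 0.449, heart_failure = 0.008, cancer = 0.020,
                   hypertension = 0.213, diabetes = 0.029),
    normo = c(sex = 0.517, heart_failure = 0.004, cancer = 0.007,
              hypertension = 0.095, diabetes = 0.055),
    micro = c(sex = 0.537, heart_failure = 0.004, cancer = 0.004,
              hypertension = 0.069, diabetes = 0.057),
    macro = c(sex = 0.538, heart_failure = 0.003, cancer = 0.004,
              hypertension = 0.060, diabetes = 0.039))
  age_band_probs <- switch(stratum,
    unmeasured = c(13.2, 16.9, 21.8, 21.9, 16.7, 8.1, 1.3),
    normo      = c(7.1, 12.7, 19.4, 26.2, 22.7, 10.4, 1.6),
    micro      = c(4.9, 9.1, 15.1, 21.4, 25.1, 19.6, 4.9),
    macro      = c(9.1, 12.0, 17.6, 21.8, 20.6, 15.2, 3.7))
  cohort_config(
    n = n, stratum = stratum, params = params, init_probs = init_probs,
    prevalence = prevalence,
    age_bands = data.frame(lower = c(18, 40, 50, 60, 70, 80, 90),
                           upper = c(40, 50, 60, 70, 80, 90, 100),
                           prob = age_band_probs / sum(age_band_probs)),
    follow_up = c(2, 9),
    scheme = observation_scheme("random", mean_gap = 1),
    min_obs = 3L
  )
}

# Stated generator assumption: neighbour-band misclassification with heavier
# one-step than two-step error, heavier under-grading of moderate stages.
default_misclass <- function() {
  list("G1_2->G3A" = 0.029, "G1_2->G3B" = 0.003,
       "G3A->G1_2" = 0.120, "G3A->G3B" = 0.060, "G3A->G4" = 0.005,
       "G3B->G1_2" = 0.005, "G3B->G3A" = 0.100, "G3B->G4" = 0.060,
       "G3B->G5" = 0.003,
       "G4->G3A" = 0.004, "G4->G3B" = 0.100, "G4->G5" = 0.030,
       "G5->G3B" = 0.003, "G5->G4" = 0.100)
}

#' Synthetic-cohort generator configuration
#'
#' @param n number of patients to simulate (before the minimum-test filter).
#' @param stratum albuminuria stratum label.
#' @param params generating `ckd_params`.
#' @param init_probs length-5 probability vector over living stages at entry.
#' @param prevalence named covariate prevalences in `[0,1]`
#'   (`sex` = proportion male).
#' @param age_bands data.frame `lower`/`upper`/`prob`; entry age is drawn by
#'   band, uniform within it.
#' @param follow_up length-2 range of administrative follow-up in years
#'   (uniform across patients; emulates an open cohort).
#' @param scheme an [observation_scheme()].
#' @param min_obs minimum number of eGFR tests for a patient to be retained.
#' @return A `ckd_cohort_config` list.
#' @export
cohort_config <- function(n, stratum, params, init_probs, prevalence,
                          age_bands, follow_up = c(2, 9),
                          scheme = observation_scheme("random", mean_gap = 1),
                          min_obs = 3L) {
  stopifnot(n >= 0, inherits(params, "ckd_params"),
            inherits(scheme, "ckd_scheme"))
  assert_stratum(stratum)
  if (length(init_probs) != 5L || any(init_probs < 0) ||
      abs(sum(init_probs) - 1) > 1e-8) {
    stop("init_probs must be a length-5 probability vector")
  }
  if (any(prevalence < 0 | prevalence > 1)) {
    stop("covariate prevalences must lie in [0, 1]")
  }
  if (!all(c("lower", "upper", "prob") %in% names(age_bands))) {
    stop("age_bands needs columns lower, upper, prob")
  }
  if (!(length(follow_up) == 2L && follow_up[1] > 0 &&
        follow_up[2] >= follow_up[1])) {
    stop("follow_up must be an increasing positive range")
  }
  structure(list(n = as.integer(n), stratum = stratum, params = params,
                 init_probs = init_probs, prevalence = prevalence,
                 age_bands = age_bands, follow_up = as.numeric(follow_up),
                 scheme = scheme, min_obs = as.integer(min_obs)),
            class = "ckd_cohort_config")
}

#' Generate a synthetic panel cohort
#'
#' Simulates `n` patients: entry age and covariates from the configured
#' population mix, a true trajectory from the generating parameters, test
#' times from the observation scheme, and observed stages through the
#' misclassification matrix. Death times are recorded exactly; survivors are
#' censored administratively at their follow-up end. Patients with fewer than
#' `min_obs` eGFR tests are dropped (their number is kept on the cohort).
#' A single master seed drives deterministic per-patient substreams, so the
#' same configuration and seed reproduce the cohort exactly.
#'
#' @param config a [cohort_config()] / [cohort_preset()].
#' @param seed integer master seed.
#' @return A [ckd_cohort()] carrying the generating truth.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_preset("unmeasured", n = 50), seed = 1)
#' coh
generate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "ckd_cohort_config"))
  set.seed(seed)
  n <- config$n
  if (n == 0L) {
    return(ckd_cohort(list(), stratum = config$stratum,
                      truth = config$params, dropped = 0L))
  }
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  E <- config$params$emission
  use_E_in_schedule <- config$scheme$kind == "doctors_care"
  records <- vector("list", n)
  kept <- logical(n)
  for (i in seq_len(n)) {
    set.seed(sub_seeds[i])
    band <- sample.int(nrow(config$age_bands), 1,
                       prob = config$age_bands$prob)
    age0 <- stats::runif(1, config$age_bands$lower[band],
                         config$age_bands$upper[band])
    cov <- lapply(config$prevalence, function(p) stats::rbinom(1, 1, p))
    profile <- covariate_profile(
      sex = cov$sex, heart_failure = cov$heart_failure, cancer = cov$cancer,
      hypertension = cov$hypertension, diabetes = cov$diabetes,
      age_at_entry = age0, stratum = config$stratum)
    horizon <- stats::runif(1, config$follow_up[1], config$follow_up[2])
    init_stage <- sample(stage_levels(), 1, prob = config$init_probs)
    path <- simulate_true_path(config$params, profile, horizon,
                               init_stage = init_stage)
    times <- schedule_observations(config$scheme, path, horizon,
                                   E = if (use_E_in_schedule) E else NULL)
    if (length(times) < config$min_obs) next
    stages <- attr(times, "emitted")
    if (is.null(stages)) {
      stages <- emit_observations(path, as.numeric(times), E)
    }
    records[[i]] <- patient_record(
      patient_id = sprintf("P%06d", i), profile = profile,
      times = as.numeric(times), stages = stages,
      death_time = path$death_time,
      censor_time = if (is.na(path$death_time)) horizon else NA_real_)
    kept[i] <- TRUE
  }
  ckd_cohort(records[kept], stratum = config$stratum, truth = config$params,
             dropped = sum(!kept))
}
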