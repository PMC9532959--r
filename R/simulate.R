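#' Simulate a true kidney-function trajectory
#'
#' Forward simulation of the uni-directional continuous-time process with
#' covariate-dependent intensities refreshed at each integer age anniversary
#' ("annually updated age"). The path starts in `init_stage` at time 0 and
#' ends at death or at the administrative horizon.
#'
#' @inheritParams build_intensity_matrix
#' @param horizon follow-up horizon in years (> 0).
#' @param init_stage starting living stage label.
#' @param seed optional integer seed (`NULL`: use the current RNG stream).
#' @return Object of class `ckd_path`: `jump_times` (starting at 0),
#'   `states` (stage labels at those times, possibly ending in `DEATH`),
#'   `death_time` (`NA` if alive at horizon) and `horizon`.
#' @export
simulate_true_path <- function(params, profile, horizon, init_stage = "G1_2",
                               seed = NULL) {
  validate_parameters(params)
  stopifnot(inherits(profile, "ckd_profile"), horizon > 0)
  if (!is.null(seed)) set.seed(seed)
  si <- stage_index(init_stage)
  if (si > n_living()) stop("init_stage must be a living stage")
  m <- profile_multipliers(params, profile)
  t <- 0; stage <- si
  jump_times <- 0; states <- si
  death_time <- NA_real_
  repeat {
    if (t >= horizon || stage > n_living()) break
    age <- profile$age_at_entry + t
    seg_end <- min(horizon, ceiling(age + 1e-9) - profile$age_at_entry)
    if (seg_end <= t + 1e-12) seg_end <- min(horizon, t + 1)
    qp <- if (stage < n_living())
      params$q_prog[stage] * m["prog"] * params$age_mult["prog"]^(age - 60)
    else 0
    qd <- params$q_death[stage] * m["death"] * params$age_mult["death"]^(age - 60)
    exit <- qp + qd
    if (exit <= 0) { t <- seg_end; next }
    wait <- stats::rexp(1, exit)
    if (t + wait > seg_end) { t <- seg_end; next }
    t <- t + wait
    if (stats::runif(1) < qd / exit) {
      stage <- n_states(); death_time <- t
    } else {
      stage <- stage + 1L
    }
    jump_times <- c(jump_times, t); states <- c(states, stage)
  }
  structure(list(jump_times = jump_times,
                 states = stage_levels(TRUE)[states],
                 death_time = death_time, horizon = horizon),
            class = "ckd_path")
}

#' True stage occupied at given times
#'
#' @param path a `ckd_path`.
#' @param times numeric vector of query times within `[0, horizon]`.
#' @return Character vector of stage labels (`DEATH` after the death time).
#' @export
stage_at <- function(path, times) {
  stopifnot(inherits(path, "ckd_path"))
  if (any(times < 0 | times > path$horizon + 1e-9)) {
    stop("query times must lie within [0, horizon]")
  }
  idx <- findInterval(times + 1e-12, path$jump_times)
  path$states[pmax(idx, 1L)]
}

#' Observation scheme for eGFR test times
#'
#' Two mechanisms for the timing of kidney-function tests: `random` tests at
#' renewal times unrelated to kidney function (exponential inter-test gaps
#' with the stated mean), and `doctors_care`, where the gap to the next test
#' is keyed by the last observed stage (test intensification as observed
#' kidney function worsens), jittered multiplicatively.
#'
#' @param kind `"random"` or `"doctors_care"`.
#' @param mean_gap mean inter-test gap in years (random scheme).
#' @param gap_map named numeric vector mapping each living stage to a gap in
#'   years; must be non-increasing in stage severity.
#' @param jitter half-width of the multiplicative uniform jitter applied to
#'   doctors-care gaps (gap is scaled by `U(1 - jitter, 1 + jitter)`).
#' @return Object of class `ckd_scheme`.
#' @export
observation_scheme <- function(kind = c("random", "doctors_care"),
                               mean_gap = 1,
                               gap_map = c(G1_2 = 1, G3A = 1, G3B = 0.5,
                                           G4 = 0.25, G5 = 0.25),
                               jitter = 0.2) {
  kind <- match.arg(kind)
  if (kind == "random") {
    if (!(mean_gap > 0)) stop("mean_gap must be > 0")
  } else {
    if (!all(stage_levels() %in% names(gap_map))) {
      stop("gap_map must name every living stage")
    }
    gap_map <- gap_map[stage_levels()]
    if (any(gap_map <= 0)) stop("gaps must be > 0")
    if (any(diff(gap_map) > 1e-12)) {
      stop("doctors_care gaps must be non-increasing in stage severity")
    }
    if (jitter < 0 || jitter >= 1) stop("jitter must lie in [0, 1)")
  }
  structure(list(kind = kind, mean_gap = mean_gap, gap_map = gap_map,
                 jitter = jitter),
            class = "ckd_scheme")
}

#' Schedule eGFR observation times along a true path
#'
#' The first test happens at entry (time 0). Under the random scheme,
#' subsequent gaps are exponential with the configured mean, independent of
#' the path. Under doctors' care, each gap is looked up from the last
#' *observed* stage (drawn through the emission matrix `E` when supplied,
#' otherwise the true stage is used) and jittered. Scheduling stops at the
#' horizon or at death, whichever is first.
#'
#' @param scheme an [observation_scheme()].
#' @param path a `ckd_path` (needed for doctors' care and to stop at death).
#' @param horizon scheduling horizon in years.
#' @param E optional emission matrix used to draw the observed stages that
#'   drive doctors-care gaps.
#' @param seed optional integer seed.
#' @param first_test_at_entry logical; if `TRUE` (default) the baseline test
#'   defining cohort membership happens at time 0, otherwise the first test
#'   only occurs after an initial gap (so a short horizon can yield an empty,
#'   flagged schedule).
#' @return Numeric vector of observation times; when `E` was used, the drawn
#'   observed stages are attached as attribute `"emitted"`; an empty schedule
#'   carries attribute `"empty" = TRUE`.
#' @export
schedule_observations <- function(scheme, path = NULL, horizon, E = NULL,
                                  seed = NULL, first_test_at_entry = TRUE) {
  stopifnot(inherits(scheme, "ckd_scheme"))
  if (!is.null(seed)) set.seed(seed)
  end <- horizon
  if (!is.null(path) && !is.na(path$death_time)) {
    end <- min(end, path$death_time)
  }
  draw_gap <- function(t_now, observed) {
    if (scheme$kind == "random") {
      stats::rexp(1, 1 / scheme$mean_gap)
    } else {
      scheme$gap_map[[observed]] *
        stats::runif(1, 1 - scheme$jitter, 1 + scheme$jitter)
    }
  }
  times <- numeric(0); emitted <- character(0)
  t <- 0
  if (!first_test_at_entry && end > 0) {
    t <- draw_gap(0, if (is.null(path)) "G1_2" else stage_at(path, 0))
  }
  while (t < end - 1e-12) {
    times <- c(times, t)
    obs <- NA_character_
    if (scheme$kind == "doctors_care") {
      true_stage <- stage_at(path, t)
      obs <- if (is.null(E)) true_stage else
        sample(stage_levels(TRUE), 1, prob = E[stage_index(true_stage), ])
      emitted <- c(emitted, obs)
    }
    t <- t + draw_gap(t, obs)
  }
  if (!length(times)) attr(times, "empty") <- TRUE
  if (length(emitted)) attr(times, "emitted") <- emitted
  times
}

#' Draw observed stages through the misclassification model
#'
#' Each eGFR test is classified into an observed stage by the emission row of
#' the true stage occupied at the test time. Tests cannot occur at or after
#' death.
#'
#' @param path a `ckd_path`.
#' @param times observation times within the path's living support.
#' @param E 6x6 emission matrix.
#' @param seed optional integer seed.
#' @return Character vector of observed living stage labels.
#' @export
emit_observations <- function(path, times, E, seed = NULL) {
  stopifnot(inherits(path, "ckd_path"))
  validate_emission_matrix(E)
  if (!is.null(seed)) set.seed(seed)
  if (!is.na(path$death_time) && length(times) &&
      any(times >= path$death_time - 1e-12)) {
    stop("cannot observe an eGFR test at or after the death time")
  }
  true_stages <- stage_at(path, times)
  vapply(true_stages, function(s) {
    sample(stage_levels(TRUE), 1, prob = E[stage_index(s), ])
  }, character(1), USE.NAMES = FALSE)
}
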