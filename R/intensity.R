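#' Build the transition intensity matrix for a covariate profile
#'
#' The 6x6 generator of the continuous-time progression process. Permitted
#' instantaneous transitions are stage k -> stage k+1 (progression) and any
#' living stage -> death; death is absorbing. Each permitted rate equals the
#' baseline rate times the product of the profile's covariate hazard ratios
#' times the age multiplier raised to `age - 60`.
#'
#' @param params a [model_parameters()] object.
#' @param profile a [covariate_profile()].
#' @param age current age in years (>= `profile$age_at_entry`).
#' @return 6x6 intensity matrix (rates/year) with zero row sums and a zero
#'   death row, stage dimnames attached.
#' @export
#' @examples
#' p <- model_parameters(q_prog = rep(0.01, 4), q_death = rep(0.005, 5),
#'                       age_mult = c(1.08, 1.09))
#' Q <- build_intensity_matrix(p, reference_profile(), age = 70)
build_intensity_matrix <- function(params, profile, age = profile$age_at_entry) {
  validate_parameters(params)
  stopifnot(inherits(profile, "ckd_profile"))
  if (!(is.numeric(age) && length(age) == 1L)) stop("age must be a scalar")
  if (age < profile$age_at_entry - 1e-9) {
    stop("age must not precede the profile's age at entry")
  }
  m <- profile_multipliers(params, profile)
  sp <- m["prog"] * params$age_mult["prog"]^(age - 60)
  sd <- m["death"] * params$age_mult["death"]^(age - 60)
  intensity_from_rates(params$q_prog * sp, params$q_death * sd)
}

# Assemble Q from already-scaled rate vectors.
intensity_from_rates <- function(q_prog, q_death) {
  k <- n_states()
  Q <- matrix(0, k, k, dimnames = list(stage_levels(TRUE), stage_levels(TRUE)))
  for (i in 1:4) Q[i, i + 1] <- q_prog[i]
  for (i in 1:5) Q[i, k] <- q_death[i]
  diag(Q) <- -rowSums(Q)
  Q
}

validate_intensity_matrix <- function(Q) {
  k <- n_states()
  if (!is.matrix(Q) || !all(dim(Q) == k)) stop("Q must be 6x6")
  off <- Q; diag(off) <- 0
  if (any(off < -1e-12)) stop("off-diagonal intensities must be >= 0")
  if (any(abs(rowSums(Q)) > 1e-10)) stop("intensity rows must sum to 0")
  allowed <- matrix(FALSE, k, k)
  for (i in 1:4) allowed[i, i + 1] <- TRUE
  allowed[1:5, k] <- TRUE
  diag(allowed) <- TRUE
  if (any(abs(Q[!allowed]) > 1e-12)) {
    stop("non-zero intensity on a forbidden transition")
  }
  if (any(abs(Q[k, ]) > 1e-12)) stop("death row must be zero (absorbing)")
  invisible(Q)
}

#' Interval transition probability matrix P(t) = exp(tQ)
#'
#' Solves the Kolmogorov forward equations for a time-homogeneous generator.
#' The computation uses a triangular eigendecomposition fast path with a
#' scaling-and-squaring fallback when exit rates are nearly confluent.
#'
#' @param Q 6x6 intensity matrix (see [build_intensity_matrix()]).
#' @param t elapsed time in years (>= 0).
#' @return 6x6 row-stochastic matrix of transition probabilities.
#' @export
transition_probability_matrix <- function(Q, t) {
  validate_intensity_matrix(Q)
  if (!(is.numeric(t) && length(t) == 1L && t >= 0)) {
    stop("t must be a single non-negative number")
  }
  P <- expm_ctmc(Q * t)
  # round tiny negative entries (triangular-recurrence rounding) back to 0
  P[P < 0] <- 0
  P[P > 1] <- 1
  dimnames(P) <- dimnames(Q)
  P
}

expm_ctmc <- function(A) {
  expm_tri_cpp(A)
}

# Age segments of an interval [t0, t1): the simulator and the exact likelihood
# refresh intensities at integer age anniversaries. Returns data.frame of
# segment start (time), length and age at segment start.
age_segments <- function(age_at_entry, t0, t1) {
  if (t1 < t0) stop("t1 must be >= t0")
  a0 <- age_at_entry + t0
  a1 <- age_at_entry + t1
  cut_lo <- floor(a0 + 1e-9) + 1
  cut_hi <- ceiling(a1 - 1e-9) - 1
  cuts <- if (cut_lo <= cut_hi) cut_lo:cut_hi else numeric(0)
  breaks <- unique(c(t0, cuts - age_at_entry, t1))
  data.frame(start = breaks[-length(breaks)],
             length = diff(breaks),
             age = age_at_entry + breaks[-length(breaks)])
}

#' Transition probabilities over an interval with annually updated age
#'
#' Product of matrix exponentials over the integer-age segments of
#' `[t0, t1]`, matching the simulator's annual age refresh. With
#' `age_update = "interval_start"` a single exponential with the age at `t0`
#' is used instead (the panel-likelihood default).
#'
#' @inheritParams build_intensity_matrix
#' @param t0,t1 interval endpoints in years since entry (`t1 >= t0 >= 0`).
#' @param age_update `"annual"` (default) or `"interval_start"`.
#' @return 6x6 row-stochastic matrix.
#' @export
interval_transition_matrix <- function(params, profile, t0, t1,
                                       age_update = c("annual", "interval_start")) {
  age_update <- match.arg(age_update)
  if (age_update == "interval_start") {
    Q <- build_intensity_matrix(params, profile, profile$age_at_entry + t0)
    return(transition_probability_matrix(Q, t1 - t0))
  }
  seg <- age_segments(profile$age_at_entry, t0, t1)
  P <- diag(n_states())
  for (i in seq_len(nrow(seg))) {
    Q <- build_intensity_matrix(params, profile, seg$age[i])
    P <- P %*% transition_probability_matrix(Q, seg$length[i])
  }
  dimnames(P) <- list(stage_levels(TRUE), stage_levels(TRUE))
  P
}

#' Presentation-level age scaling of an annual transition probability
#'
#' Reproduces the reporting convention in which an annual transition
#' probability for a reference 60-year-old is carried to other ages by
#' multiplying by the per-year age hazard ratio raised to the age difference
#' (e.g. 1.0% at 60 becomes 1.0 x 1.08^10 = 2.16% at 70). This is an
#' approximation valid for small probabilities: the model's exact age effect
#' acts on the intensity scale (see [build_intensity_matrix()]).
#'
#' @param annual_prob annual transition probability in `[0, 1]`.
#' @param multiplier per-year hazard-ratio multiplier (> 0).
#' @param years integer number of years of age difference (>= 0).
#' @return Scaled probability, capped at 1 (with a warning if capping occurs).
#' @export
#' @examples
#' apply_age_multiplier(0.010, 1.08, 10)  # 0.0216
apply_age_multiplier <- function(annual_prob, multiplier, years) {
  if (any(annual_prob < 0 | annual_prob > 1)) {
    stop("annual_prob must lie in [0, 1]")
  }
  if (any(multiplier <= 0)) stop("multiplier must be > 0")
  if (any(years < 0) || any(years != round(years))) {
    stop("years must be a non-negative integer")
  }
  p <- annual_prob * multiplier^years
  if (any(p > 1)) {
    warning("scaled probability exceeds 1; capped (the approximation has ",
            "broken down, use the intensity-scale age effect instead)")
    p <- pmin(p, 1)
  }
  p
}

#' Mean sojourn time in each living stage
#'
#' The expected time spent in a stage before any exit (progression or death)
#' is the reciprocal of the total exit rate, `-1 / q_rr`. Stages with zero
#' exit rate are reported as `Inf` (never left), not as an error.
#'
#' @param Q intensity matrix.
#' @return Named numeric vector of sojourn times in years per living stage.
#' @export
mean_sojourn <- function(Q) {
  validate_intensity_matrix(Q)
  exit <- -diag(Q)[seq_len(n_living())]
  s <- ifelse(exit > 0, 1 / exit, Inf)
  names(s) <- stage_levels()
  s
}

#' One-year transition and misclassification diagram
#'
#' The content of the annual state-model diagrams: for each living stage under
#' a given covariate profile, the one-year probabilities of remaining, moving
#' to each more severe living stage, and dying, together with the
#' misclassification distribution of a single eGFR test in that stage.
#'
#' @inheritParams build_intensity_matrix
#' @param age age at which the one-year interval starts (default entry age).
#' @return List with `transitions` (data.frame: stage, stay, next_stage,
#'   any_progression, death — each a one-year probability) and
#'   `misclassification` (the emission matrix rows for living stages).
#' @export
annual_transition_diagram <- function(params, profile = reference_profile(),
                                      age = profile$age_at_entry) {
  Q <- build_intensity_matrix(params, profile, age)
  P <- transition_probability_matrix(Q, 1)
  liv <- seq_len(n_living())
  tr <- data.frame(
    stage = stage_levels(),
    stay = diag(P)[liv],
    next_stage = c(P[1, 2], P[2, 3], P[3, 4], P[4, 5], 0),
    any_progression = vapply(liv, function(r) {
      if (r < n_living()) sum(P[r, (r + 1):n_living()]) else 0
    }, numeric(1)),
    death = P[liv, n_states()],
    stringsAsFactors = FALSE
  )
  rownames(tr) <- NULL
  list(transitions = tr,
       misclassification = params$emission[liv, liv, drop = FALSE])
}

#' Baseline rates from target one-year transition probabilities
#'
#' Inverts the relation between the intensity matrix and the one-year
#' transition probabilities of the reference profile: given, for each living
#' stage, the desired one-year probability of being found in the next stage
#' and of having died, solves for progression and death rates such that
#' `P(1)` reproduces them. Useful for specifying generator presets on the
#' probability scale on which results are usually quoted.
#'
#' @param p_next length-4: one-year probability of occupying stage k+1 having
#'   started in stage k (k = 1..4).
#' @param p_death length-5: one-year probability of death from each stage.
#' @return List with `q_prog` (length 4) and `q_death` (length 5) rates/year.
#' @export
rates_from_annual_probs <- function(p_next, p_death) {
  stopifnot(length(p_next) == 4L, length(p_death) == 5L,
            all(p_next >= 0), all(p_death > 0),
            all(p_next + p_death[1:4] < 1), p_death[5] < 1)
  q_prog <- numeric(4); q_death <- numeric(5)
  # Work backwards from G5 (death only). For stage k the one-year stay
  # probability is exp(-(qp+qd)) which pins the total exit rate; the death
  # split is then a 1-d root find given the already-solved downstream rates.
  q_death[5] <- -log(1 - p_death[5])
  for (k in 4:1) {
    g <- function(qd) {
      qp <- solve_qp(k, qd, p_next, q_prog, q_death)
      P <- probe_P1(k, qp, qd, q_prog, q_death)
      P[k, n_states()] - p_death[k]
    }
    qd <- stats::uniroot(g, lower = 1e-10, upper = 5, tol = 1e-12)$root
    qp <- solve_qp(k, qd, p_next, q_prog, q_death)
    q_death[k] <- qd; q_prog[k] <- qp
  }
  list(q_prog = q_prog, q_death = q_death)
}

# One-year probability of occupying stage k+1 from stage k as a function of
# q_prog[k]; monotone increasing, solved by uniroot.
solve_qp <- function(k, qd, p_next, q_prog, q_death) {
  h <- function(qp) probe_P1(k, qp, qd, q_prog, q_death)[k, k + 1] - p_next[k]
  stats::uniroot(h, lower = 1e-10, upper = 5, tol = 1e-12)$root
}

probe_P1 <- function(k, qp, qd, q_prog, q_death) {
  q_prog2 <- q_prog; q_death2 <- q_death
  q_prog2[k] <- qp; q_death2[k] <- qd
  Q <- intensity_from_rates(q_prog2, q_death2)
  expm_ctmc(Q)
}
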