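#' Probability of true stage progression within a horizon
#'
#' For a patient truly in a given living stage, the probability that the true
#' stage at the horizon is strictly more severe. By default death is reported
#' separately rather than counted as progression (monitoring a dead patient
#' is undefined); `include_death = TRUE` folds it in for sensitivity
#' analyses. Intensities follow the annually-updated-age convention over the
#' horizon.
#'
#' @inheritParams build_intensity_matrix
#' @param stage baseline true living stage label.
#' @param horizon horizon in years (> 0 unless exactly 0, which returns 0).
#' @param include_death count death within the horizon as progression.
#' @return Named vector: `progression`, `death`.
#' @export
progression_probability <- function(params, stage, profile, horizon,
                                    include_death = FALSE) {
  r <- stage_index(stage)
  if (r > n_living()) stop("baseline stage must be a living stage")
  if (horizon < 0) stop("horizon must be >= 0")
  P <- interval_transition_matrix(params, profile, 0, horizon, "annual")
  prog <- if (r < n_living()) sum(P[r, (r + 1):n_living()]) else 0
  death <- P[r, n_states()]
  c(progression = if (include_death) prog + death else prog, death = death)
}

#' True- and false-positive detection probabilities of a single test
#'
#' For a patient truly in `stage` at baseline, consider a single eGFR test
#' taken at the horizon. The true positive probability is that the test reads
#' a stage more severe than baseline given that true kidney function has
#' progressed (to a more severe living stage); the false positive probability
#' is that the test reads any stage other than baseline in a person whose
#' true function has not changed. Directional variants are also returned:
#' `tp_any_change` (test reads anything other than baseline, given
#' progression) and `fp_more_severe` (test reads a more severe stage, given
#' no change).
#'
#' @inheritParams progression_probability
#' @return Named vector: `true_positive`, `false_positive`, `tp_any_change`,
#'   `fp_more_severe`, `p_progressed`, `p_unchanged`, `p_death`.
#' @export
detection_probabilities <- function(params, stage, profile, horizon) {
  r <- stage_index(stage)
  if (r > n_living()) stop("baseline stage must be a living stage")
  P <- interval_transition_matrix(params, profile, 0, horizon, "annual")
  E <- params$emission
  liv <- seq_len(n_living())
  more <- liv[liv > r]
  p_prog <- sum(P[r, more])
  tp <- if (p_prog > 0) {
    sum(vapply(more, function(s) P[r, s] * sum(E[s, more]), numeric(1))) /
      p_prog
  } else NA_real_
  # tp_any: observed differs from the baseline stage, given progression
  tp_any <- if (p_prog > 0) {
    sum(vapply(more, function(s) P[r, s] * (1 - E[s, r]), numeric(1))) / p_prog
  } else NA_real_
  fp <- 1 - E[r, r]
  fp_up <- if (r < n_living()) sum(E[r, (r + 1):n_living()]) else 0
  c(true_positive = tp, false_positive = unname(fp),
    tp_any_change = tp_any, fp_more_severe = unname(fp_up),
    p_progressed = unname(p_prog), p_unchanged = unname(P[r, r]),
    p_death = unname(P[r, n_states()]))
}

#' Monitoring metrics table at standard horizons
#'
#' Progression, death, true-positive and false-positive probabilities for
#' baseline stages G3a and G3b at 6-, 12- and 36-month horizons — the
#' decision-relevant quantities for choosing a retest interval.
#'
#' @inheritParams progression_probability
#' @param stages baseline stages (default G3a and G3b).
#' @param horizons_months monitoring horizons in months.
#' @return Data frame, one row per stage x horizon.
#' @export
monitoring_report <- function(params, profile = reference_profile(),
                              stages = c("G3A", "G3B"),
                              horizons_months = c(6, 12, 36)) {
  rows <- list()
  for (st in stages) {
    for (hm in horizons_months) {
      h <- hm / 12
      pr <- progression_probability(params, st, profile, h)
      det <- detection_probabilities(params, st, profile, h)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = params$stratum, stage = st, horizon_months = hm,
        p_progression = unname(pr["progression"]),
        p_death = unname(pr["death"]),
        true_positive = unname(det["true_positive"]),
        false_positive = unname(det["false_positive"]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Forward filter: normalised distribution of the true living stage at the
# last used observation, conditional on the observations used.
forward_filter <- function(record, params, options = likelihood_options(),
                           upto = length(record$times)) {
  obs <- stage_index(record$stages)
  E <- params$emission
  initp <- resolve_init_probs(options, list(record))
  alpha <- numeric(5)
  if (options$init == "emission") {
    alpha <- initp * E[1:5, obs[1]]
  } else {
    alpha[obs[1]] <- 1
  }
  if (sum(alpha) <= 0) stop("impossible first observation")
  alpha <- alpha / sum(alpha)
  if (upto >= 2) for (k in 2:upto) {
    P <- interval_transition_matrix(
      params, record$profile, record$times[k - 1], record$times[k],
      age_update = if (options$age_update == "annual") "annual"
      else "interval_start")
    alpha <- as.numeric(alpha %*% P[1:5, 1:5]) * E[1:5, obs[k]]
    if (sum(alpha) <= 0) stop("impossible observation ", k)
    alpha <- alpha / sum(alpha)
  }
  alpha
}

#' Forecast the observed-stage distribution for a patient
#'
#' Filters the hidden stage distribution at the last observation of the
#' record prefix, propagates it forward through the transition kernel to
#' each query time, and maps it through the misclassification matrix to the
#' distribution a future eGFR test would be drawn from. The death state is
#' carried as a separate category.
#'
#' @param params a `ckd_params` (typically `fit$params`).
#' @param record a [patient_record()]; its first `upto` observations are
#'   conditioned on.
#' @param query_times times (years since entry), each at or after the last
#'   conditioning observation.
#' @param upto number of leading observations to condition on (default all).
#' @param options [likelihood_options()].
#' @return Matrix `length(query_times)` x 6: predicted probabilities of each
#'   observed category (5 living stages, then `DEATH`).
#' @export
occupancy_forecast <- function(params, record, query_times,
                               upto = length(record$times),
                               options = likelihood_options()) {
  stopifnot(inherits(record, "ckd_record"), upto >= 1)
  t0 <- record$times[upto]
  if (any(query_times < t0 - 1e-9)) {
    stop("query times must not precede the last conditioning observation")
  }
  alpha <- forward_filter(record, params, options, upto = upto)
  E <- params$emission
  out <- matrix(0, length(query_times), n_states(),
                dimnames = list(NULL, stage_levels(TRUE)))
  for (i in seq_along(query_times)) {
    P <- interval_transition_matrix(
      params, record$profile, t0, query_times[i],
      age_update = if (options$age_update == "annual") "annual"
      else "interval_start")
    v <- as.numeric(c(alpha, 0) %*% P)
    obs_liv <- as.numeric(v[1:5] %*% E[1:5, 1:5])
    out[i, ] <- c(obs_liv, v[n_states()])
  }
  out
}

#' Calibration of predicted against observed stage proportions
#'
#' For every held-out eGFR test beyond each patient's first, predicts the
#' observed-category distribution from the patient's earlier observations
#' ([occupancy_forecast()] conditioned on all prior tests by default, or on
#' the first test only), conditions on the patient being alive to be tested,
#' and aggregates predicted and observed proportions within time bins.
#'
#' @param params a `ckd_params` (typically from a fit on the training half).
#' @param cohort held-out test cohort.
#' @param bin_width_years calibration bin width (default 1 year).
#' @param conditioning `"all_prior"` (default) or `"first_only"`.
#' @param options [likelihood_options()].
#' @return Object of class `ckd_calibration`: data.frame with `bin`
#'   (interval start), `category`, `predicted`, `observed`, `n`. Within each
#'   non-empty bin both proportion columns sum to 1.
#' @export
calibration_table <- function(params, cohort, bin_width_years = 1,
                              conditioning = c("all_prior", "first_only"),
                              options = likelihood_options()) {
  stopifnot(inherits(cohort, "ckd_cohort"))
  conditioning <- match.arg(conditioning)
  preds <- list(); times <- numeric(0); obs <- character(0)
  for (r in cohort$records) {
    m <- length(r$times)
    if (m < 2) next
    for (k in 2:m) {
      upto <- if (conditioning == "all_prior") k - 1L else 1L
      p <- occupancy_forecast(params, r, r$times[k], upto = upto,
                              options = options)[1, ]
      pl <- p[1:5]
      if (sum(pl) <= 0) next
      preds[[length(preds) + 1L]] <- pl / sum(pl)  # condition on alive
      times <- c(times, r$times[k])
      obs <- c(obs, r$stages[k])
    }
  }
  if (!length(preds)) stop("no predictable observations in the cohort")
  PM <- do.call(rbind, preds)
  bins <- floor(times / bin_width_years) * bin_width_years
  ub <- sort(unique(bins))
  rows <- list()
  for (b in ub) {
    sel <- bins == b
    pbar <- colMeans(PM[sel, , drop = FALSE])
    otab <- table(factor(obs[sel], levels = stage_levels()))
    rows[[length(rows) + 1L]] <- data.frame(
      bin = b, category = stage_levels(),
      predicted = as.numeric(pbar),
      observed = as.numeric(otab) / sum(otab),
      n = as.integer(sum(sel)), stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows),
            class = c("ckd_calibration", "data.frame"),
            bin_width = bin_width_years)
}

#' Mean absolute calibration error
#'
#' @param calib a [calibration_table()] result.
#' @param weighted weight bin-category cells by bin counts (default TRUE).
#' @return Mean absolute predicted-minus-observed proportion per
#'   (bin, category) cell.
#' @export
calibration_mae <- function(calib, weighted = TRUE) {
  err <- abs(calib$predicted - calib$observed)
  if (weighted) sum(err * calib$n) / sum(calib$n) else mean(err)
}

#' Plot predicted against observed stage proportions over time
#'
#' One panel per observed category: lines for predicted, points for observed
#' proportions by time bin.
#'
#' @param calib a [calibration_table()] result.
#' @param file optional PNG path; when given, the plot is written there.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_calibration <- function(calib, file = NULL) {
  draw <- function() {
    op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    for (cat in stage_levels()) {
      d <- calib[calib$category == cat, ]
      ylim <- range(0, d$predicted, d$observed)
      plot(d$bin, d$predicted, type = "l", col = "steelblue", lwd = 2,
           xlab = "years since entry", ylab = "proportion of tests",
           main = cat, ylim = ylim)
      graphics::points(d$bin, d$observed, pch = 19, col = "firebrick")
    }
  }
  if (is.null(file)) {
    draw()
  } else {
    grDevices::png(file, width = 1200, height = 800, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  }
  invisible(file)
}
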