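#' Viterbi decoding of the most probable true stage sequence
#'
#' Dynamic programme over the living stages at each observation time,
#' maximising the joint probability of the hidden stage sequence and the
#' observed test results under the fitted HMM. Interval transition kernels
#' use the same covariate/age convention as the likelihood; an exactly
#' observed death (and, when enabled, survival to the censor time)
#' contributes its marginal weight to the terminal state. Ties are broken
#' toward the less severe stage.
#'
#' @param record a [patient_record()].
#' @param params a [model_parameters()] object (typically `fit$params`).
#' @param options [likelihood_options()]; the initial-state and age-updating
#'   conventions used in fitting should be reused here.
#' @return Object of class `ckd_decoded`: data.frame with `time_years`,
#'   `observed_stage`, `decoded_stage` and `grading`
#'   (`correct`/`under`/`over`: the observed stage is less/more severe than
#'   the decoded truth), plus the joint log-probability as attribute
#'   `"log_joint"`.
#' @export
viterbi_decode <- function(record, params, options = likelihood_options()) {
  stopifnot(inherits(record, "ckd_record"))
  validate_parameters(params)
  m <- length(record$times)
  if (!m) stop("record has no observations")
  obs <- stage_index(record$stages)
  E <- params$emission
  logE <- log(E[1:5, 1:5])
  initp <- resolve_init_probs(options, list(record))
  score <- matrix(-Inf, m, 5)
  back <- matrix(NA_integer_, m, 5)
  if (options$init == "emission") {
    score[1, ] <- log(initp) + logE[, obs[1]]
  } else {
    score[1, obs[1]] <- 0
  }
  if (all(!is.finite(score[1, ]))) {
    stop("no hidden stage can produce observation 1 (stage ",
         record$stages[1], ")")
  }
  Pk <- function(t0, t1) {
    interval_transition_matrix(params, record$profile, t0, t1,
                               age_update = if (options$age_update == "annual")
                                 "annual" else "interval_start")
  }
  for (k in seq_len(m)[-1]) {
    P <- Pk(record$times[k - 1], record$times[k])
    logP <- log(P[1:5, 1:5])
    for (s in 1:5) {
      best <- -Inf; arg <- NA_integer_
      for (r in 1:5) {           # increasing severity: ties keep less severe
        v <- score[k - 1, r] + logP[r, s]
        if (v > best) { best <- v; arg <- r }
      }
      score[k, s] <- best + logE[s, obs[k]]
      back[k, s] <- arg
    }
    if (all(!is.finite(score[k, ]))) {
      stop("no hidden path is consistent with observation ", k,
           " (stage ", record$stages[k], ")")
    }
  }
  term <- score[m, ]
  if (record_died(record)) {
    P <- Pk(record$times[m], record$death_time)
    seg <- age_segments(record$profile$age_at_entry, record$times[m],
                        record$death_time)
    age_d <- if (options$age_update == "annual")
      seg$age[nrow(seg)] else record$profile$age_at_entry + record$times[m]
    mm <- profile_multipliers(params, record$profile)
    qd <- params$q_death * mm["death"] * params$age_mult["death"]^(age_d - 60)
    w <- as.numeric(P[1:5, 1:5] %*% qd)
    term <- term + log(w)
  } else if (options$use_censor &&
             record$censor_time > record$times[m] + 1e-12) {
    P <- Pk(record$times[m], record$censor_time)
    term <- term + log(rowSums(P[1:5, 1:5]))
  }
  last <- which.max(replace(term, !is.finite(term), -Inf))
  path <- integer(m)
  path[m] <- last
  if (m > 1) for (k in m:2) path[k - 1] <- back[k, path[k]]
  decoded <- stage_levels()[path]
  grading <- ifelse(obs == path, "correct", ifelse(obs < path, "under", "over"))
  out <- data.frame(time_years = record$times,
                    observed_stage = record$stages,
                    decoded_stage = decoded,
                    grading = grading, stringsAsFactors = FALSE)
  structure(out, class = c("ckd_decoded", "data.frame"),
            patient_id = record$patient_id, log_joint = term[last])
}

#' Under-/over-grading rates of eGFR tests
#'
#' Decodes every record with [viterbi_decode()], takes the decoded sequence
#' as the truth, and reports the percentage of tests whose observed stage is
#' less severe (under-grading) or more severe (over-grading) than the decoded
#' stage, together with their total. Confidence intervals are Wilson score
#' intervals on the pooled test counts; a patient-level bootstrap is
#' available instead.
#'
#' @param cohort a [ckd_cohort()].
#' @inheritParams viterbi_decode
#' @param ci `"wilson"` (default) or `"bootstrap"` (patient-level, 200
#'   resamples).
#' @param boot_reps bootstrap resamples when `ci = "bootstrap"`.
#' @param seed seed for the bootstrap.
#' @return Object of class `ckd_grading`: data.frame with rows `under`,
#'   `over`, `total`; columns percent, lower, upper (95%), count and
#'   `n_tests`.
#' @export
grading_rates <- function(cohort, params, options = likelihood_options(),
                          ci = c("wilson", "bootstrap"), boot_reps = 200,
                          seed = 1) {
  stopifnot(inherits(cohort, "ckd_cohort"))
  if (!length(cohort$records)) stop("cohort is empty")
  ci <- match.arg(ci)
  per_rec <- lapply(cohort$records, function(r) {
    d <- viterbi_decode(r, params, options)
    c(under = sum(d$grading == "under"),
      over = sum(d$grading == "over"),
      n = nrow(d))
  })
  M <- do.call(rbind, per_rec)
  n <- sum(M[, "n"])
  counts <- c(under = sum(M[, "under"]), over = sum(M[, "over"]))
  counts["total"] <- counts["under"] + counts["over"]
  pct <- 100 * counts / n
  if (ci == "wilson") {
    cis <- t(vapply(counts, function(k) wilson_ci(k, n), numeric(2)))
  } else {
    set.seed(seed)
    reps <- replicate(boot_reps, {
      idx <- sample.int(nrow(M), replace = TRUE)
      cs <- colSums(M[idx, , drop = FALSE])
      100 * c(cs["under"], cs["over"], cs["under"] + cs["over"]) / cs["n"]
    })
    cis <- t(apply(reps, 1, stats::quantile, probs = c(0.025, 0.975)))
  }
  out <- data.frame(grading = c("under", "over", "total"),
                    percent = unname(pct),
                    lower = unname(cis[, 1]), upper = unname(cis[, 2]),
                    count = unname(counts), n_tests = n,
                    stringsAsFactors = FALSE)
  structure(out, class = c("ckd_grading", "data.frame"))
}

wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  100 * c(max(0, centre - half), min(1, centre + half))
}
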