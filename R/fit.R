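#' Maximum-likelihood fit of the progression HMM
#'
#' Maximises the cohort log-likelihood over unconstrained transforms of all
#' parameters: log baseline intensities (4 progression + 5 death rates), log
#' hazard-ratio multipliers for the selected covariates (one progression and
#' one death multiplier each) and for age, and multinomial-logit emission
#' probabilities over the permitted neighbour band. Optimisation is
#' quasi-Newton (BFGS) with analytic gradients from an adjoint
#' (forward-backward) recursion, started from deterministic crude estimates
#' (observed transition counts over person-time; emission off-diagonals
#' 0.05). Wald confidence intervals come from the numerically differentiated
#' observed information at the optimum and are only reported when that
#' Hessian is positive definite.
#'
#' @param cohort a [ckd_cohort()].
#' @param covariates character vector of covariate multipliers to fit
#'   (subset of `sex, heart_failure, cancer, hypertension, diabetes`).
#' @param fit_age fit the per-year age multipliers (default `TRUE`).
#' @param band emission band width (default 2).
#' @param fixed_emission optional 6x6 emission matrix to hold fixed (e.g.
#'   identity for a no-misclassification model); when supplied no emission
#'   parameters are estimated.
#' @param fixed_age_mult optional length-2 `c(prog, death)` age multipliers
#'   held fixed when `fit_age = FALSE` (default both 1).
#' @param options [likelihood_options()] controlling the initial-state
#'   convention, age-updating convention and censoring factor.
#' @param n_starts number of optimiser starts; starts beyond the first jitter
#'   the crude start by `N(0, jitter_sd)` on the transformed scale.
#' @param jitter_sd jitter standard deviation for extra starts.
#' @param start optional named start list (`params`-like) overriding the
#'   crude start.
#' @param compute_ci compute the observed-information Hessian and Wald CIs.
#' @param max_iter BFGS iteration cap.
#' @param seed seed for the (deterministic) start jitter.
#' @return Object of class `ckd_fit`: MLE `params`, the CI table
#'   (`fit$ci`), `loglik`, convergence and Hessian diagnostics.
#' @export
fit_ckd_hmm <- function(cohort,
                        covariates = c("sex", "heart_failure", "cancer"),
                        fit_age = TRUE,
                        band = 2L,
                        fixed_emission = NULL,
                        fixed_age_mult = c(1, 1),
                        options = likelihood_options(),
                        n_starts = 1L,
                        jitter_sd = 0.3,
                        start = NULL,
                        compute_ci = TRUE,
                        max_iter = 500L,
                        seed = 1L) {
  stopifnot(inherits(cohort, "ckd_cohort"))
  if (!length(cohort$records)) stop("cohort must be non-empty")
  if (length(covariates) &&
      !all(covariates %in% covariate_names())) {
    stop("unknown covariate(s): ",
         paste(setdiff(covariates, covariate_names()), collapse = ", "))
  }
  records <- cohort$records
  skel <- fit_skeleton(covariates, fit_age, band, fixed_emission,
                       fixed_age_mult, cohort$stratum)
  recs_cpp <- records_for_cpp(records)
  X <- do.call(rbind, lapply(records, function(r) {
    unlist(r$profile[covariate_names()])[covariates]
  }))
  if (length(covariates) == 0L) X <- matrix(0, length(records), 0)
  initp <- resolve_init_probs(options, records)

  eval_engine <- function(theta, want_grad) {
    pp <- unpack_theta(theta, skel)
    mult_prog <- as.numeric(exp(X %*% pp$log_m[, 1, drop = FALSE]))
    mult_death <- as.numeric(exp(X %*% pp$log_m[, 2, drop = FALSE]))
    if (!ncol(X)) mult_prog <- mult_death <- rep(1, length(records))
    cohort_loglik_cpp(
      n_obs = recs_cpp$n_obs, t_all = recs_cpp$t, s_all = recs_cpp$s,
      died = recs_cpp$died, tdeath = recs_cpp$tdeath,
      censor = recs_cpp$censor, age_entry = recs_cpp$age_entry,
      q_prog = pp$q_prog, q_death = pp$q_death,
      am_prog = pp$age_mult[1], am_death = pp$age_mult[2],
      mult_prog = mult_prog, mult_death = mult_death,
      E5 = pp$E[1:5, 1:5],
      init_emission = options$init == "emission", initp = initp,
      annual_split = options$age_update == "annual",
      use_censor = options$use_censor, want_grad = want_grad)
  }
  negll <- function(theta) {
    v <- eval_engine(theta, FALSE)$loglik
    if (!is.finite(v)) return(1e10)
    -v
  }
  neggr <- function(theta) {
    res <- eval_engine(theta, TRUE)
    if (!is.finite(res$loglik)) return(rep(0, length(theta)))
    -assemble_gradient(res, theta, skel, X)
  }

  theta0 <- if (is.null(start)) crude_start(records, skel) else
    pack_start(start, skel)
  set.seed(seed)
  starts <- list(theta0)
  if (n_starts > 1L) {
    for (k in seq_len(n_starts - 1L)) {
      starts[[k + 1L]] <- theta0 + stats::rnorm(length(theta0), 0, jitter_sd)
    }
  }
  best <- NULL
  for (th in starts) {
    opt <- stats::optim(th, negll, neggr, method = "BFGS",
                        control = list(maxit = max_iter, reltol = 1e-8))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  theta_hat <- best$par
  ll <- -best$value
  converged <- best$convergence == 0L

  hessian <- NULL; vcov <- NULL; hessian_pd <- FALSE
  if (compute_ci) {
    hessian <- gradient_fd_hessian(neggr, theta_hat)
    ch <- tryCatch(chol(hessian), error = function(e) NULL)
    if (!is.null(ch)) {
      hessian_pd <- TRUE
      vcov <- chol2inv(ch)
    }
  }
  pp <- unpack_theta(theta_hat, skel)
  params_hat <- params_from_unpacked(pp, skel)
  ci <- ci_table(theta_hat, vcov, skel, hessian_pd)
  structure(
    list(params = params_hat, theta = theta_hat, skeleton = skel,
         vcov = vcov, hessian = hessian, hessian_pd = hessian_pd,
         loglik = ll, converged = converged,
         iterations = best$counts[["function"]],
         ci = ci, covariates = covariates, options = options,
         n_patients = length(records),
         n_obs = sum(vapply(records, function(r) length(r$times), integer(1))),
         stratum = cohort$stratum),
    class = "ckd_fit")
}

# ---- parameter packing -----------------------------------------------------

# The skeleton records which blocks of the unconstrained vector exist and the
# support of the emission logits.
fit_skeleton <- function(covariates, fit_age, band, fixed_emission,
                         fixed_age_mult, stratum) {
  support <- emission_support(band)
  emis_idx <- NULL
  if (is.null(fixed_emission)) {
    emis_idx <- which(support[1:5, 1:5] & !diag(5) > 0, arr.ind = TRUE)
    emis_idx <- emis_idx[order(emis_idx[, 1], emis_idx[, 2]), , drop = FALSE]
  }
  n_rates <- 9L
  n_age <- if (fit_age) 2L else 0L
  n_cov <- 2L * length(covariates)
  n_emis <- if (is.null(emis_idx)) 0L else nrow(emis_idx)
  list(covariates = covariates, fit_age = fit_age, band = as.integer(band),
       fixed_emission = fixed_emission,
       fixed_age_mult = as.numeric(fixed_age_mult),
       emis_idx = emis_idx, stratum = stratum,
       npar = n_rates + n_age + n_cov + n_emis,
       i_rates = 1:9,
       i_age = if (fit_age) 9L + seq_len(2L) else integer(0),
       i_cov = 9L + n_age + seq_len(n_cov),
       i_emis = 9L + n_age + n_cov + seq_len(n_emis))
}

unpack_theta <- function(theta, skel) {
  q_prog <- exp(theta[1:4])
  q_death <- exp(theta[5:9])
  age_mult <- if (skel$fit_age) exp(theta[skel$i_age]) else skel$fixed_age_mult
  nm <- length(skel$covariates)
  log_m <- matrix(0, nm, 2,
                  dimnames = list(skel$covariates, c("prog", "death")))
  if (nm) log_m[] <- matrix(theta[skel$i_cov], nm, 2, byrow = TRUE)
  E <- if (is.null(skel$emis_idx)) skel$fixed_emission else {
    emission_from_logits(theta[skel$i_emis], skel)
  }
  list(q_prog = q_prog, q_death = q_death, age_mult = age_mult,
       log_m = log_m, E = E)
}

emission_from_logits <- function(logits, skel) {
  E <- diag(6)
  dimnames(E) <- list(stage_levels(TRUE), stage_levels(TRUE))
  idx <- skel$emis_idx
  for (r in 1:5) {
    rows <- which(idx[, 1] == r)
    if (!length(rows)) next
    ex <- exp(logits[rows])
    D <- 1 + sum(ex)
    E[r, idx[rows, 2]] <- ex / D
    E[r, r] <- 1 / D
  }
  E
}

params_from_unpacked <- function(pp, skel) {
  cov_mult <- NULL
  if (length(skel$covariates)) {
    cov_mult <- exp(pp$log_m)
  }
  model_parameters(q_prog = pp$q_prog, q_death = pp$q_death,
                   age_mult = pp$age_mult, cov_mult = cov_mult,
                   misclass = pp$E, band = skel$band,
                   stratum = skel$stratum)
}

pack_start <- function(start, skel) {
  theta <- numeric(skel$npar)
  theta[1:4] <- log(start$q_prog)
  theta[5:9] <- log(start$q_death)
  if (skel$fit_age) theta[skel$i_age] <- log(start$age_mult)
  if (length(skel$covariates)) {
    lm <- log(start$cov_mult[skel$covariates, , drop = FALSE])
    theta[skel$i_cov] <- as.numeric(t(lm))
  }
  if (!is.null(skel$emis_idx)) {
    E <- if (!is.null(start$emission)) start$emission else
      build_emission_matrix(default_start_misclass(skel), band = skel$band)
    idx <- skel$emis_idx
    theta[skel$i_emis] <- vapply(seq_len(nrow(idx)), function(k) {
      r <- idx[k, 1]; s <- idx[k, 2]
      log(max(E[r, s], 1e-8) / max(E[r, r], 1e-8))
    }, numeric(1))
  }
  theta
}

default_start_misclass <- function(skel) {
  idx <- skel$emis_idx
  lv <- stage_levels()
  out <- as.list(rep(0.05, nrow(idx)))
  names(out) <- paste0(lv[idx[, 1]], "->", lv[idx[, 2]])
  out
}

# Crude deterministic start: attribute person-time to the observed stage at
# each interval start; count one forward transition per observed step-up and
# one death per dying patient, with a half-count continuity floor.
crude_start <- function(records, skel) {
  pt <- numeric(5); nprog <- numeric(4); ndeath <- numeric(5)
  for (r in records) {
    s <- stage_index(r$stages)
    tt <- c(r$times, if (record_died(r)) r$death_time else r$censor_time)
    dt <- diff(tt)
    for (k in seq_along(dt)) pt[s[min(k, length(s))]] <- pt[s[min(k, length(s))]] + dt[k]
    if (length(s) > 1) {
      up <- which(diff(s) > 0)
      for (k in up) nprog[min(s[k], 4)] <- nprog[min(s[k], 4)] + 1
    }
    if (record_died(r)) ndeath[s[length(s)]] <- ndeath[s[length(s)]] + 1
  }
  pt <- pmax(pt, 0.5)
  q_prog <- pmax((nprog + 0.5) / pt[1:4], 1e-4)
  q_death <- pmax((ndeath + 0.5) / pt, 1e-4)
  start <- list(q_prog = pmin(q_prog, 2), q_death = pmin(q_death, 2),
                age_mult = c(1, 1), cov_mult = default_multipliers(),
                emission = NULL)
  pack_start(start, skel)
}

# Assemble d loglik / d theta from the engine's component gradients.
assemble_gradient <- function(res, theta, skel, X) {
  g <- numeric(skel$npar)
  g[1:4] <- res$gqp
  g[5:9] <- res$gqd
  if (skel$fit_age) g[skel$i_age] <- c(res$g_am_prog, res$g_am_death)
  nm <- length(skel$covariates)
  if (nm) {
    gc <- numeric(2 * nm)
    for (c in seq_len(nm)) {
      gc[2 * c - 1] <- sum(X[, c] * res$gp_rec)
      gc[2 * c] <- sum(X[, c] * res$gd_rec)
    }
    g[skel$i_cov] <- gc
  }
  if (!is.null(skel$emis_idx)) {
    pp <- unpack_theta(theta, skel)
    idx <- skel$emis_idx
    ge <- numeric(nrow(idx))
    for (r in 1:5) {
      rows <- which(idx[, 1] == r)
      if (!length(rows)) next
      cols <- idx[rows, 2]
      p_off <- pp$E[r, cols]
      p_diag <- pp$E[r, r]
      gErow <- res$gE[r, ]
      mean_g <- sum(p_off * gErow[cols]) + p_diag * gErow[r]
      ge[rows] <- p_off * (gErow[cols] - mean_g)
    }
    g[skel$i_emis] <- ge
  }
  g
}

# Finite differences of the analytic gradient: observed information.
# One-sided steps suffice (the O(h) truncation error is far below the
# statistical uncertainty the Hessian is used to quantify); symmetrised.
gradient_fd_hessian <- function(neggr, theta, h = 1e-4) {
  n <- length(theta)
  g0 <- neggr(theta)
  H <- matrix(0, n, n)
  for (j in seq_len(n)) {
    tp <- theta; tp[j] <- tp[j] + h
    H[, j] <- (neggr(tp) - g0) / h
  }
  (H + t(H)) / 2
}

# ---- reporting -------------------------------------------------------------

ci_table <- function(theta, vcov, skel, hessian_pd) {
  se <- if (hessian_pd) sqrt(pmax(diag(vcov), 0)) else rep(NA_real_, skel$npar)
  z <- stats::qnorm(0.975)
  lv <- stage_levels()
  name <- character(skel$npar); type <- character(skel$npar)
  name[1:4] <- paste0("rate:", lv[1:4], "->", lv[2:5])
  name[5:9] <- paste0("rate:", lv, "->DEATH")
  type[1:9] <- "rate"
  if (skel$fit_age) {
    name[skel$i_age] <- c("age_mult:prog", "age_mult:death")
    type[skel$i_age] <- "multiplier"
  }
  if (length(skel$covariates)) {
    name[skel$i_cov] <- as.vector(t(outer(skel$covariates,
                                          c(":prog", ":death"), paste0)))
    type[skel$i_cov] <- "multiplier"
  }
  est <- exp(theta); lower <- exp(theta - z * se); upper <- exp(theta + z * se)
  scale <- rep("log", skel$npar)
  if (!is.null(skel$emis_idx)) {
    idx <- skel$emis_idx
    pp <- unpack_theta(theta, skel)
    for (k in seq_len(nrow(idx))) {
      i <- skel$i_emis[k]
      r <- idx[k, 1]; s <- idx[k, 2]
      name[i] <- paste0("emission:", lv[r], "->", lv[s])
      type[i] <- "emission"
      p <- pp$E[r, s]
      est[i] <- p
      if (hessian_pd) {
        # delta method through the row softmax, then a logit-scale interval
        rows <- which(idx[, 1] == r)
        Jrow <- -p * pp$E[r, idx[rows, 2]]
        Jrow[rows == k] <- Jrow[rows == k] + p
        V <- vcov[skel$i_emis[rows], skel$i_emis[rows], drop = FALSE]
        se_p <- sqrt(max(drop(t(Jrow) %*% V %*% Jrow), 0))
        se[i] <- se_p
        if (p > 0 && p < 1 && se_p > 0) {
          se_l <- se_p / (p * (1 - p))
          lower[i] <- stats::plogis(stats::qlogis(p) - z * se_l)
          upper[i] <- stats::plogis(stats::qlogis(p) + z * se_l)
        } else {
          lower[i] <- NA_real_; upper[i] <- NA_real_
        }
      } else {
        lower[i] <- NA_real_; upper[i] <- NA_real_
      }
      scale[i] <- "probability"
    }
  }
  data.frame(parameter = name, type = type, estimate = est, se = se,
             lower = lower, upper = upper, scale = scale,
             stringsAsFactors = FALSE)
}

#' @export
print.ckd_fit <- function(x, ...) {
  cat("Kidney-function progression HMM fit (", x$stratum, " stratum)\n",
      sep = "")
  cat("  patients:", x$n_patients, " tests:", x$n_obs, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 10),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  observed-information Hessian positive definite:",
      x$hessian_pd, "\n")
  cat("\nParameter estimates (95% Wald CIs):\n")
  tab <- x$ci
  tab$estimate <- signif(tab$estimate, 4)
  tab$lower <- signif(tab$lower, 4); tab$upper <- signif(tab$upper, 4)
  print(tab[, c("parameter", "estimate", "lower", "upper")],
        row.names = FALSE)
  invisible(x)
}

#' Hazard-ratio multiplier display table
#'
#' Presentation rule for transition-rate multipliers: a covariate whose 95%
#' confidence interval overlaps "no effect" (1.0) is displayed as 1.00; the
#' underlying estimates are retained in the fit object.
#'
#' @param fit a `ckd_fit` with confidence intervals.
#' @return Data frame with one row per multiplier: estimate, CI bounds, the
#'   displayed value, and a flag when no CI is available.
#' @export
multiplier_table <- function(fit) {
  stopifnot(inherits(fit, "ckd_fit"))
  tab <- fit$ci[fit$ci$type == "multiplier", , drop = FALSE]
  if (!nrow(tab)) return(tab)
  no_ci <- !is.finite(tab$lower) | !is.finite(tab$upper)
  overlaps <- !no_ci & tab$lower <= 1 & tab$upper >= 1
  tab$display <- ifelse(no_ci, NA_real_,
                        ifelse(overlaps, 1.00, round(tab$estimate, 2)))
  tab$no_ci <- no_ci
  rownames(tab) <- NULL
  tab[, c("parameter", "estimate", "lower", "upper", "display", "no_ci")]
}

#' Mean sojourn times with confidence intervals from a fit
#'
#' Sojourn time in stage r is `1 / (progression rate + death rate)`; its CI
#' is obtained by the delta method on the log total exit rate.
#'
#' @param fit a `ckd_fit`.
#' @param profile covariate profile at which to evaluate (default reference).
#' @param age age at which to evaluate (default 60, the reference).
#' @return Data frame: stage, sojourn years, lower, upper.
#' @export
sojourn_table <- function(fit, profile = reference_profile(fit$stratum),
                          age = 60) {
  stopifnot(inherits(fit, "ckd_fit"))
  Q <- build_intensity_matrix(fit$params, profile, age)
  soj <- mean_sojourn(Q)
  lower <- upper <- rep(NA_real_, 5)
  if (fit$hessian_pd) {
    m <- profile_multipliers(fit$params, profile)
    for (r in 1:5) {
      # d log(exit) / d theta over the two (or one) contributing log rates
      qp <- if (r < 5) fit$params$q_prog[r] *
        m["prog"] * fit$params$age_mult["prog"]^(age - 60) else 0
      qd <- fit$params$q_death[r] *
        m["death"] * fit$params$age_mult["death"]^(age - 60)
      exit <- qp + qd
      g <- numeric(length(fit$theta))
      if (r < 5) g[r] <- qp / exit
      g[4 + r] <- qd / exit
      se_log <- sqrt(max(drop(t(g) %*% fit$vcov %*% g), 0))
      z <- stats::qnorm(0.975)
      lower[r] <- soj[r] * exp(-z * se_log)
      upper[r] <- soj[r] * exp(z * se_log)
    }
  }
  data.frame(stage = stage_levels(), sojourn_years = unname(soj),
             lower = lower, upper = upper, stringsAsFactors = FALSE)
}

#' Split a cohort into equal-size training and testing halves
#'
#' Pseudo-random partition by patient; the two halves differ in size by at
#' most one patient and are deterministic given the seed.
#'
#' @param cohort a [ckd_cohort()] with at least two patients.
#' @param seed integer seed.
#' @return List of class `ckd_split` with elements `train`, `test`, `seed`.
#' @export
split_sample <- function(cohort, seed = 1) {
  stopifnot(inherits(cohort, "ckd_cohort"))
  n <- length(cohort$records)
  if (n < 2L) stop("need at least 2 patients to split")
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- ceiling(n / 2)
  mk <- function(idx) ckd_cohort(cohort$records[sort(idx)],
                                 stratum = cohort$stratum,
                                 truth = cohort$truth)
  structure(list(train = mk(perm[seq_len(n_train)]),
                 test = mk(perm[(n_train + 1):n]), seed = seed),
            class = "ckd_split")
}

#' Uniform patient subsample
#'
#' Without-replacement sample of `n` patients, deterministic given the seed
#' (used to cap fitting cost on very large cohorts).
#'
#' @inheritParams split_sample
#' @param n subsample size (`<=` cohort size).
#' @return A [ckd_cohort()].
#' @export
subsample_patients <- function(cohort, n, seed = 1) {
  stopifnot(inherits(cohort, "ckd_cohort"))
  if (n > length(cohort$records)) {
    stop("subsample size exceeds the cohort size")
  }
  set.seed(seed)
  idx <- sort(sample.int(length(cohort$records), n))
  ckd_cohort(cohort$records[idx], stratum = cohort$stratum,
             truth = cohort$truth)
}

#' Fit with the published covariate-selection procedure
#'
#' Fits with hypertension and diabetes included; if no hypertension or
#' diabetes multiplier's 95% CI excludes 1 (they are "unable to predict"
#' progression or death), both are removed and the model refitted.
#'
#' @inheritParams fit_ckd_hmm
#' @param ... passed to [fit_ckd_hmm()].
#' @return A `ckd_fit`; attribute `"dropped_covariates"` lists any removals.
#' @export
fit_with_covariate_selection <- function(cohort, ...) {
  full <- fit_ckd_hmm(cohort, covariates = c("sex", "heart_failure", "cancer",
                                             "hypertension", "diabetes"), ...)
  tab <- full$ci
  cand <- tab[grepl("^(hypertension|diabetes):", tab$parameter), ]
  excl <- is.finite(cand$lower) & is.finite(cand$upper) &
    (cand$lower > 1 | cand$upper < 1)
  if (any(excl)) return(full)
  red <- fit_ckd_hmm(cohort, covariates = c("sex", "heart_failure", "cancer"),
                     ...)
  attr(red, "dropped_covariates") <- c("hypertension", "diabetes")
  red
}
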