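test_that("the assembled analytic gradient matches finite differences", {
  coh <- small_cohort("micro", n = 50, seed = 3, min_obs = 0)
  records <- coh$records
  covs <- c("sex", "heart_failure")
  skel <- ckdhmm:::fit_skeleton(covs, TRUE, 2L, NULL, c(1, 1), "micro")
  fl <- ckdhmm:::records_for_cpp(records)
  X <- do.call(rbind, lapply(records, function(r)
    unlist(r$profile[ckdhmm:::covariate_names()])[covs]))
  initp <- rep(0.2, 5)
  eval_ll <- function(theta, grad, annual, initE) {
    pp <- ckdhmm:::unpack_theta(theta, skel)
    mp <- as.numeric(exp(X %*% pp$log_m[, 1]))
    md <- as.numeric(exp(X %*% pp$log_m[, 2]))
    ckdhmm:::cohort_loglik_cpp(fl$n_obs, fl$t, fl$s, fl$died, fl$tdeath,
                               fl$censor, fl$age_entry, pp$q_prog,
                               pp$q_death, pp$age_mult[1], pp$age_mult[2],
                               mp, md, pp$E[1:5, 1:5], initE, initp,
                               annual, TRUE, grad)
  }
  set.seed(99)
  theta <- ckdhmm:::crude_start(records, skel) +
    rnorm(skel$npar, 0, 0.2)
  # keep the per-year age multipliers physiological: a log-jitter of 0.2 per
  # year compounds to overflow for the oldest patients
  theta[skel$i_age] <- log(c(1.08, 1.09)) + rnorm(2, 0, 0.01)
  for (annual in c(TRUE, FALSE)) for (initE in c(TRUE, FALSE)) {
    res <- eval_ll(theta, TRUE, annual, initE)
    g <- ckdhmm:::assemble_gradient(res, theta, skel, X)
    for (j in sample(skel$npar, 8)) {
      h <- 1e-6
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      num <- (eval_ll(tp, FALSE, annual, initE)$loglik -
                eval_ll(tm, FALSE, annual, initE)$loglik) / (2 * h)
      expect_equal(g[j], num, tolerance = 1e-5)
    }
  }
})

test_that("fitting a no-misclassification model recovers the generating rates", {
  cfg <- cohort_preset("micro", n = 700)
  cfg$min_obs <- 0L
  cfg$params$emission <- build_emission_matrix(NULL)   # identity: no error
  coh <- generate_cohort(cfg, seed = 61)
  opts <- likelihood_options(init = "emission", init_probs = cfg$init_probs,
                             age_update = "annual")
  fit <- fit_ckd_hmm(coh, fixed_emission = diag(6), options = opts)
  expect_true(fit$converged)
  expect_true(fit$hessian_pd)
  # the MLE cannot have lower likelihood than the generating truth
  expect_gte(fit$loglik, cohort_log_likelihood(coh, cfg$params, opts) - 1e-6)
  # rates with plenty of events sit close to truth
  truth <- c(cfg$params$q_prog, cfg$params$q_death)
  est <- fit$ci$estimate[1:9]
  expect_lt(max(abs(log(est[c(1, 2, 5, 6)] / truth[c(1, 2, 5, 6)]))), 0.5)
  # coverage: most of the 9 rate CIs contain the truth
  cov9 <- truth >= fit$ci$lower[1:9] & truth <= fit$ci$upper[1:9]
  expect_gte(sum(cov9), 7)

  # sojourn table: point estimates are inverse exit rates, CIs bracket them
  soj <- sojourn_table(fit)
  Q <- build_intensity_matrix(fit$params, reference_profile("micro"), 60)
  expect_equal(soj$sojourn_years, unname(mean_sojourn(Q)))
  ok <- is.finite(soj$lower)
  expect_true(all(soj$lower[ok] <= soj$sojourn_years[ok] &
                    soj$sojourn_years[ok] <= soj$upper[ok]))
})

test_that("a degenerate one-patient cohort does not crash the fitter", {
  pr <- covariate_profile(age_at_entry = 65, stratum = "micro")
  rec <- patient_record("solo", pr, times = c(0, 1, 2),
                        stages = rep("G3A", 3), censor_time = 2)
  coh <- ckd_cohort(list(rec), stratum = "micro")
  fit <- suppressWarnings(
    fit_ckd_hmm(coh, covariates = character(0), fit_age = FALSE,
                fixed_emission = diag(6), max_iter = 200))
  expect_s3_class(fit, "ckd_fit")
  # either very wide intervals or an honest non-PD flag; never an error
  if (fit$hessian_pd) {
    width <- with(fit$ci, upper / lower)
    expect_gt(max(width, na.rm = TRUE), 10)
  } else {
    expect_true(all(!is.finite(fit$ci$lower)))
  }
})

test_that("multiplier display table applies the no-effect rule", {
  tab <- data.frame(
    parameter = c("sex:prog", "sex:death", "cancer:prog"),
    type = "multiplier",
    estimate = c(1.08, 1.25, 1.40),
    se = 0.05,
    lower = c(0.95, 1.02, NA),
    upper = c(1.20, 1.53, NA),
    scale = "log", stringsAsFactors = FALSE)
  fake <- structure(list(ci = tab), class = "ckd_fit")
  out <- multiplier_table(fake)
  expect_equal(out$display[1], 1.00)   # CI overlaps 1 -> shown as no effect
  expect_equal(out$display[2], 1.25)   # CI excludes 1 -> shown as estimated
  expect_true(is.na(out$display[3]) && out$no_ci[3])  # no CI -> blank + flag
})

test_that("split_sample partitions patients into near-equal halves", {
  coh10 <- small_cohort("normo", n = 18, seed = 2, min_obs = 0)
  coh10$records <- coh10$records[1:10]
  sp <- split_sample(coh10, seed = 5)
  expect_length(sp$train, 5)
  expect_length(sp$test, 5)

  coh11 <- coh10; coh11$records <- coh10$records[1:9]
  sp2 <- split_sample(coh11, seed = 5)
  expect_equal(sort(c(length(sp2$train), length(sp2$test))), c(4, 5))

  ids <- function(x) sort(vapply(x$records, `[[`, character(1), "patient_id"))
  expect_identical(sort(c(ids(sp$train), ids(sp$test))), ids(coh10))
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)

  sp_again <- split_sample(coh10, seed = 5)
  expect_identical(ids(sp_again$train), ids(sp$train))

  one <- ckd_cohort(coh10$records[1], stratum = coh10$stratum)
  expect_error(split_sample(one), "at least 2")
})

test_that("patient subsampling is uniform and deterministic", {
  coh <- small_cohort("normo", n = 80, seed = 6, min_obs = 0)
  N <- length(coh)
  expect_identical(subsample_patients(coh, N, seed = 1)$records, coh$records)
  expect_length(subsample_patients(coh, 0, seed = 1), 0)
  expect_error(subsample_patients(coh, N + 1), "exceeds")

  ids <- function(x) vapply(x$records, `[[`, character(1), "patient_id")
  s1 <- ids(subsample_patients(coh, 30, seed = 1))
  s1b <- ids(subsample_patients(coh, 30, seed = 1))
  expect_identical(s1, s1b)
  # overlap of two independent draws concentrates near the hypergeometric
  # expectation n^2 / N
  overlaps <- vapply(1:40, function(k) {
    length(intersect(ids(subsample_patients(coh, 30, seed = 100 + k)),
                     ids(subsample_patients(coh, 30, seed = 500 + k))))
  }, numeric(1))
  n <- 30
  exp_overlap <- n * n / N
  var_overlap <- n * (n / N) * (1 - n / N) * (N - n) / (N - 1)
  se_mean <- sqrt(var_overlap / 40)
  expect_lt(abs(mean(overlaps) - exp_overlap), 4 * se_mean)
})

test_that("covariate selection drops hypertension and diabetes when uninformative", {
  # generated truth has no hypertension/diabetes effect
  cfg <- cohort_preset("micro", n = 250)
  cfg$min_obs <- 0L
  coh <- generate_cohort(cfg, seed = 44)
  opts <- likelihood_options(init = "emission", init_probs = cfg$init_probs,
                             age_update = "annual")
  fit <- fit_with_covariate_selection(coh, fixed_emission = cfg$params$emission,
                                      options = opts)
  expect_s3_class(fit, "ckd_fit")
  if (!is.null(attr(fit, "dropped_covariates"))) {
    expect_identical(attr(fit, "dropped_covariates"),
                     c("hypertension", "diabetes"))
    expect_false(any(grepl("hypertension", fit$ci$parameter)))
  }
})
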