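test_that("state space is five ordered living stages plus absorbing death", {
  expect_identical(stage_levels(), c("G1_2", "G3A", "G3B", "G4", "G5"))
  expect_identical(stage_levels(TRUE)[6], "DEATH")
  expect_equal(stage_index(c("G1_2", "G5", "DEATH")), c(1L, 5L, 6L))
  expect_error(stage_index("G6"), "unknown stage")
  rng <- stage_egfr_ranges()
  # eGFR ranges partition (0, Inf): each upper bound meets the next lower
  expect_equal(rng$egfr_lower[1:4], rng$egfr_upper[2:5] + 1)
  expect_equal(rng$egfr_lower[5], 0)
  expect_equal(rng$egfr_upper[1], Inf)
})

test_that("intensity matrix scales baselines by covariates and age", {
  p <- model_parameters(
    q_prog = c(0.010, 0.012, 0.010, 0.013),
    q_death = c(0.007, 0.010, 0.015, 0.030, 0.150),
    age_mult = c(prog = 1.08, death = 1.09),
    cov_mult = rbind(sex = c(1.25, 1.40), heart_failure = c(1.35, 2.0)))

  # reference profile at age 60 reproduces the baselines exactly
  Q <- build_intensity_matrix(p, reference_profile(), 60)
  expect_equal(unname(Q[cbind(1:4, 2:5)]), unname(p$q_prog))
  expect_equal(unname(Q[1:5, 6]), unname(p$q_death))
  expect_equal(rowSums(Q), rep(0, 6), ignore_attr = TRUE)

  # 0.010/yr at 60 with multiplier 1.08 becomes 0.010 * 1.08^10 at 70
  Q70 <- build_intensity_matrix(p, reference_profile(), 70)
  expect_equal(Q70["G1_2", "G3A"], 0.010 * 1.08^10, tolerance = 1e-12)
  expect_equal(unname(Q70["G1_2", "G3A"]), 0.021589, tolerance = 1e-4)

  # covariate multipliers act multiplicatively on the whole block
  prof <- covariate_profile(sex = 1, heart_failure = 1)
  Qm <- build_intensity_matrix(p, prof, 60)
  expect_equal(Qm["G3A", "G3B"], p$q_death[1] * 0 + 0.012 * 1.25 * 1.35,
               ignore_attr = TRUE)
  expect_equal(Qm["G4", "DEATH"], 0.030 * 1.40 * 2.0, ignore_attr = TRUE)

  # degenerate: all-zero rates give the zero generator
  p0 <- model_parameters(q_prog = rep(0, 4), q_death = rep(0, 5))
  expect_equal(build_intensity_matrix(p0, reference_profile(), 75),
               matrix(0, 6, 6), ignore_attr = TRUE)

  expect_error(build_intensity_matrix(p, reference_profile(), 59),
               "age")
  expect_error(model_parameters(q_prog = c(-0.1, 0, 0, 0),
                                q_death = rep(0.1, 5)), ">= 0")
  expect_error(covariate_profile(stratum = "nephrotic"), "stratum")
})

test_that("transition probabilities satisfy the CTMC closed forms", {
  p <- model_parameters(q_prog = c(0.02, 0.03, 0.04, 0.05),
                        q_death = c(0.01, 0.02, 0.03, 0.04, 0.2))
  Q <- build_intensity_matrix(p, reference_profile(), 60)

  expect_equal(transition_probability_matrix(Q, 0), diag(6),
               ignore_attr = TRUE, tolerance = 1e-14)

  # single exit rate: staying probability is exp(-q t)
  p2 <- model_parameters(q_prog = rep(0, 4), q_death = c(0.1, 0, 0, 0, 0))
  Q2 <- build_intensity_matrix(p2, reference_profile(), 60)
  expect_equal(transition_probability_matrix(Q2, 1)["G1_2", "G1_2"],
               exp(-0.1), tolerance = 1e-12)
  expect_equal(unname(transition_probability_matrix(Q2, 1)["G1_2", "G1_2"]),
               0.904837, tolerance = 1e-6)

  # Chapman-Kolmogorov: P(2) = P(1) P(1), P(s+t) = P(s) P(t)
  P1 <- transition_probability_matrix(Q, 1)
  expect_equal(transition_probability_matrix(Q, 2), P1 %*% P1,
               tolerance = 1e-10)
  expect_equal(transition_probability_matrix(Q, 1.7),
               transition_probability_matrix(Q, 0.4) %*%
                 transition_probability_matrix(Q, 1.3), tolerance = 1e-8)

  expect_error(transition_probability_matrix(Q, -1), "non-negative")
})

test_that("matrix exponential matches independent oracles on random generators", {
  skip_if_not_installed("Matrix")
  set.seed(101)
  for (i in 1:25) {
    Q <- ckdhmm:::intensity_from_rates(runif(4, 0, 0.8), runif(5, 0, 0.8))
    t <- runif(1, 0.05, 6)
    P <- transition_probability_matrix(Q, t)
    # scaling-and-squaring oracle from Matrix
    expect_equal(P, as.matrix(Matrix::expm(Matrix::Matrix(Q * t))),
                 ignore_attr = TRUE, tolerance = 1e-9)
    # truncated series oracle
    S <- diag(6); Tm <- diag(6)
    for (k in 1:40) { Tm <- Tm %*% (Q * t) / k; S <- S + Tm }
    expect_equal(P, S, ignore_attr = TRUE, tolerance = 1e-9)
    # structural invariants
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(all(P[lower.tri(P)] == 0))  # uni-directional
    expect_equal(unname(P[6, 6]), 1)        # death absorbing
  }
})

test_that("age multiplier on the probability scale approximates the rate-scale effect", {
  # identity at zero years, cap with warning
  expect_equal(apply_age_multiplier(0.42, 1.08, 0), 0.42)
  expect_warning(out <- apply_age_multiplier(0.5, 1.2, 10), "capped")
  expect_equal(out, 1)
  expect_error(apply_age_multiplier(1.2, 1.08, 5), "\\[0, 1\\]")
  expect_error(apply_age_multiplier(0.01, 1.08, 2.5), "integer")

  # agreement with the intensity-scale computation over the documented
  # validity region (p <= 2%, m <= 1.1, y <= 20): the discrepancy obeys the
  # second-order Taylor bound and stays within 6% of the exact probability
  for (p in c(0.005, 0.01, 0.02)) {
    for (m in c(1.05, 1.08, 1.1)) {
      for (y in c(5, 10, 20)) {
        q <- -log(1 - p)  # base rate giving one-year exit probability p
        approx <- apply_age_multiplier(p, m, y)
        exact <- 1 - exp(-q * m^y)
        M <- m^y
        expect_lt(abs(approx - exact), 0.5 * (p * M)^2 + M * p^2)
        expect_lt(abs(approx - exact) / exact, 0.06)
      }
    }
  }
})

test_that("mean sojourn time is the inverse total exit rate", {
  p <- model_parameters(q_prog = c(0.5, 0, 0.2, 0),
                        q_death = c(0.5, 0, 0.1, 0.25, 1 / 30.5))
  Q <- build_intensity_matrix(p, reference_profile(), 60)
  s <- mean_sojourn(Q)
  expect_equal(unname(s["G1_2"]), 1.0)          # unit total exit rate
  expect_equal(unname(s["G5"]), 30.5)           # exit rate 1/30.5 per year
  expect_identical(unname(s["G3A"]), Inf)       # zero exit: flagged, no error
  # monotone decreasing in the total exit rate
  exit <- -diag(Q)[1:5]
  expect_identical(order(s[exit > 0]), order(-exit[exit > 0]))
})

test_that("sojourn of 30.5 years corresponds to the fitted G1/2 exit rate read inversely", {
  r <- rates_from_annual_probs(c(0.011, 0.0085, 0.010, 0.013) * 2.42,
                               c(0.007, 0.012, 0.020, 0.035, 0.13))
  # direct inverse reading: total exit 1/30.5 -> 30.5 years
  Q <- ckdhmm:::intensity_from_rates(c(1 / 30.5 * 0.6, r$q_prog[2:4]),
                                     c(1 / 30.5 * 0.4, r$q_death[2:5]))
  expect_equal(unname(mean_sojourn(Q)["G1_2"]), 30.5, tolerance = 1e-12)
})

test_that("emission matrix respects the neighbour band and row stochasticity", {
  expect_equal(build_emission_matrix(NULL), diag(6), ignore_attr = TRUE)

  E <- build_emission_matrix(list("G1_2->G3A" = 0.029))
  expect_equal(unname(E["G1_2", "G1_2"]), 0.971)
  expect_equal(unname(E["G1_2", "G3A"]), 0.029)

  # a true G1/2 can read G3a or G3b but never G4 or G5
  expect_error(build_emission_matrix(list("G1_2->G4" = 0.01)),
               "neighbour")
  expect_error(build_emission_matrix(list("G1_2->G5" = 0.001)),
               "neighbour")
  # true G3b may read G1/2, G3a, G4 or G5
  E2 <- build_emission_matrix(list("G3B->G1_2" = 0.01, "G3B->G3A" = 0.1,
                                   "G3B->G4" = 0.05, "G3B->G5" = 0.01))
  expect_equal(unname(E2["G3B", "G3B"]), 1 - 0.17)
  # death is always classified correctly and never emitted by the living
  expect_error(build_emission_matrix(list("G3A->DEATH" = 0.01)), "neighbour")
  S <- emission_support()
  expect_true(all(!S[1:5, 6]))
  expect_identical(unname(S[6, ]), c(rep(FALSE, 5), TRUE))

  # row sums exceeding 1 rejected; full-matrix input validated
  expect_error(build_emission_matrix(list("G3A->G1_2" = 0.6, "G3A->G3B" = 0.5)),
               "> 1")
  M <- diag(6); M[1, 4] <- 0.1; M[1, 1] <- 0.9
  expect_error(build_emission_matrix(M), "violates")
  # band width 1 tightens the constraint
  expect_error(build_emission_matrix(list("G1_2->G3B" = 0.01), band = 1),
               "neighbour")
  E3 <- build_emission_matrix(ckdhmm:::default_misclass())
  expect_equal(rowSums(E3), rep(1, 6), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("one-year diagram agrees with the transition kernel and conserves mass", {
  p <- random_params(seed = 7)
  d <- annual_transition_diagram(p, reference_profile(), age = 65)
  Q <- build_intensity_matrix(p, reference_profile(), 65)
  P1 <- transition_probability_matrix(Q, 1)
  expect_equal(d$transitions$stay, unname(diag(P1)[1:5]))
  expect_equal(d$transitions$next_stage[1], unname(P1[1, 2]))
  expect_equal(d$transitions$death, unname(P1[1:5, 6]))
  # stay + progression-to-anywhere + death sums to one for every stage
  expect_equal(d$transitions$stay + d$transitions$any_progression +
                 d$transitions$death, rep(1, 5), tolerance = 1e-10)

  p0 <- model_parameters(q_prog = rep(0, 4), q_death = rep(0, 5))
  d0 <- annual_transition_diagram(p0)
  expect_equal(d0$transitions$stay, rep(1, 5))
})

test_that("annual probabilities invert to rates and back", {
  pn <- c(0.034, 0.040, 0.046, 0.054)
  pd <- c(0.015, 0.025, 0.040, 0.060, 0.18)
  r <- rates_from_annual_probs(pn, pd)
  P <- ckdhmm:::expm_ctmc(ckdhmm:::intensity_from_rates(r$q_prog, r$q_death))
  expect_equal(unname(P[cbind(1:4, 2:5)]), pn, tolerance = 1e-9)
  expect_equal(unname(P[1:5, 6]), pd, tolerance = 1e-9)
})

test_that("parameter config files round-trip exactly", {
  p <- cohort_preset("macro", 10)$params
  f <- tempfile(fileext = ".cfg")
  write_model_config(p, f)
  p2 <- read_model_config(f)
  expect_equal(p2$q_prog, p$q_prog, tolerance = 1e-15)
  expect_equal(p2$q_death, p$q_death, tolerance = 1e-15)
  expect_equal(p2$age_mult, p$age_mult)
  expect_equal(p2$cov_mult, p$cov_mult)
  expect_equal(p2$emission, p$emission, tolerance = 1e-15)
  expect_identical(p2$stratum, "macro")
})
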