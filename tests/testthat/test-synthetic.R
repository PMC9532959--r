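test_that("true paths are uni-directional, absorbing and seed-deterministic", {
  p <- cohort_preset("macro", 10)$params
  prof <- covariate_profile(age_at_entry = 70, stratum = "macro")

  path1 <- simulate_true_path(p, prof, horizon = 10, init_stage = "G3A",
                              seed = 42)
  path2 <- simulate_true_path(p, prof, horizon = 10, init_stage = "G3A",
                              seed = 42)
  expect_identical(path1, path2)

  set.seed(1)
  for (i in 1:200) {
    pa <- simulate_true_path(p, prof, horizon = 12,
                             init_stage = sample(stage_levels(), 1))
    idx <- stage_index(pa$states)
    expect_true(all(diff(idx) > 0))          # severity only increases
    expect_lte(length(pa$jump_times), 6)     # at most 5 jumps
    expect_true(all(diff(pa$jump_times) > 0))
    if (!is.na(pa$death_time)) {
      expect_identical(pa$states[length(pa$states)], "DEATH")
      expect_equal(pa$death_time, max(pa$jump_times))
    }
  }

  # zero rates: one segment in the initial stage for the whole horizon
  p0 <- model_parameters(q_prog = rep(0, 4), q_death = rep(0, 5))
  pz <- simulate_true_path(p0, prof, horizon = 5, init_stage = "G3B", seed = 1)
  expect_identical(pz$states, "G3B")
  expect_identical(pz$jump_times, 0)
  expect_true(is.na(pz$death_time))
})

test_that("simulated one-year state distribution matches the matrix exponential", {
  # fixed Q (no age effect): empirical occupancy at t = 1 within 3 binomial
  # standard errors of the corresponding P(1) row
  p <- model_parameters(q_prog = c(0.25, 0.3, 0.35, 0.4),
                        q_death = c(0.1, 0.15, 0.2, 0.25, 0.6))
  prof <- reference_profile()
  P1 <- transition_probability_matrix(
    build_intensity_matrix(p, prof, 60), 1)["G1_2", ]
  n <- 50000
  set.seed(2024)
  states <- vapply(seq_len(n), function(i) {
    stage_at(simulate_true_path(p, prof, horizon = 1.0001), 1)
  }, character(1))
  emp <- table(factor(states, levels = stage_levels(TRUE))) / n
  for (s in stage_levels(TRUE)) {
    se <- sqrt(P1[s] * (1 - P1[s]) / n)
    expect_lt(abs(emp[[s]] - P1[[s]]), 3 * se + 1e-12)
  }
  # conservation: the occupancy probabilities sum to one
  expect_equal(sum(emp), 1)
})

test_that("empirical sojourn times match the inverse exit rates", {
  p <- model_parameters(q_prog = c(0.5, 0.6, 0, 0), q_death = c(0.3, 0.4, 0, 0, 0))
  prof <- reference_profile()
  set.seed(77)
  n <- 4000
  holds <- vapply(seq_len(n), function(i) {
    pa <- simulate_true_path(p, prof, horizon = 200, init_stage = "G1_2")
    pa$jump_times[2]
  }, numeric(1))
  expect_true(all(is.finite(holds)))
  mu <- 1 / 0.8
  expect_lt(abs(mean(holds) - mu), 3 * stats::sd(holds) / sqrt(n))
})

test_that("observation schedules follow their mechanism", {
  p0 <- model_parameters(q_prog = rep(0, 4), q_death = rep(0, 5))
  prof <- reference_profile()
  still <- simulate_true_path(p0, prof, horizon = 10, init_stage = "G1_2",
                              seed = 1)

  # doctors' care with a deterministic mapping and a path stuck in G1/2:
  # equally spaced yearly tests
  sch <- observation_scheme("doctors_care",
                            gap_map = c(G1_2 = 1, G3A = 0.5, G3B = 0.5,
                                        G4 = 0.5, G5 = 0.5), jitter = 0)
  times <- schedule_observations(sch, still, horizon = 5.5, seed = 1)
  expect_equal(as.numeric(times), 0:5)

  # doctors-care gaps must intensify (not relax) with severity
  expect_error(observation_scheme("doctors_care",
                                  gap_map = c(G1_2 = 0.5, G3A = 1, G3B = 1,
                                              G4 = 1, G5 = 1)),
               "non-increasing")

  # random renewal: mean number of tests over 10 years with mean gap 1 year
  # is 1 + 10 within Monte-Carlo error (first test at entry)
  set.seed(3)
  rnd <- observation_scheme("random", mean_gap = 1)
  counts <- vapply(seq_len(4000), function(i) {
    length(schedule_observations(rnd, still, horizon = 10))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 11), 3 * stats::sd(counts) / sqrt(4000))

  # a horizon shorter than the first gap yields an empty, flagged schedule
  empty <- schedule_observations(sch, still, horizon = 0.1, seed = 1,
                                 first_test_at_entry = FALSE)
  expect_length(empty, 0)
  expect_true(attr(empty, "empty"))

  # scheduling stops at death
  p1 <- model_parameters(q_prog = rep(0, 4), q_death = c(2, 0, 0, 0, 0))
  dead <- simulate_true_path(p1, prof, horizon = 50, init_stage = "G1_2",
                             seed = 5)
  expect_false(is.na(dead$death_time))
  tms <- schedule_observations(rnd, dead, horizon = 50, seed = 5)
  expect_true(all(tms < dead$death_time))
})

test_that("emitted observations follow the misclassification rows", {
  p0 <- model_parameters(q_prog = rep(0, 4), q_death = rep(0, 5))
  prof <- reference_profile()
  path <- simulate_true_path(p0, prof, horizon = 10, init_stage = "G3A",
                             seed = 1)

  # identity emission reproduces the true stage
  expect_identical(emit_observations(path, c(0.5, 2, 7), diag(6), seed = 1),
                   rep("G3A", 3))

  # multinomial frequencies within 3 binomial SEs of the emission row
  E <- build_emission_matrix(list("G3A->G1_2" = 0.05, "G3A->G3B" = 0.04,
                                  "G3A->G4" = 0.01))
  n <- 100000
  obs <- emit_observations(path, seq(0.0001, 9.999, length.out = n), E,
                           seed = 9)
  freq <- table(factor(obs, levels = stage_levels(TRUE))) / n
  for (s in stage_levels(TRUE)) {
    pr <- E["G3A", s]
    expect_lt(abs(freq[[s]] - pr), 3 * sqrt(pr * (1 - pr) / n) + 1e-9)
  }

  # observing at or after death is a domain error
  p1 <- model_parameters(q_prog = rep(0, 4), q_death = c(5, 0, 0, 0, 0))
  dead <- simulate_true_path(p1, prof, horizon = 100, init_stage = "G1_2",
                             seed = 3)
  expect_error(emit_observations(dead, dead$death_time + 0.5, diag(6)),
               "death")
})

test_that("generate_cohort is reproducible and its filter is a pure subset", {
  cfg <- cohort_preset("normo", n = 120)
  c1 <- generate_cohort(cfg, seed = 31)
  c2 <- generate_cohort(cfg, seed = 31)
  f1 <- tempfile(); f2 <- tempfile()
  write_cohort_csv(c1, f1); write_cohort_csv(c2, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical

  # the >=3-test rule only removes patients, never alters retained records
  cfg0 <- cohort_preset("normo", n = 120)
  cfg0$min_obs <- 0L
  c0 <- generate_cohort(cfg0, seed = 31)
  expect_gte(length(c0), length(c1))
  expect_equal(length(c0) , length(c1) + c1$dropped)
  ids1 <- vapply(c1$records, `[[`, character(1), "patient_id")
  ids0 <- vapply(c0$records, `[[`, character(1), "patient_id")
  expect_true(all(ids1 %in% ids0))
  expect_identical(c1$records, c0$records[match(ids1, ids0)])

  # every retained patient has at least 3 tests; stratum is uniform
  expect_true(all(vapply(c1$records, function(r) length(r$times),
                         integer(1)) >= 3))
  expect_true(all(vapply(c1$records, function(r) r$profile$stratum,
                         character(1)) == "normo"))

  # n = 0: a valid empty cohort and a header-only CSV
  c_empty <- generate_cohort(cohort_preset("normo", n = 0), seed = 1)
  expect_length(c_empty, 0)
  fe <- tempfile()
  write_cohort_csv(c_empty, fe)
  expect_length(readLines(fe), 1L)

  expect_error(cohort_config(n = 10, stratum = "normo", params = cfg$params,
                             init_probs = cfg$init_probs,
                             prevalence = c(sex = 1.2),
                             age_bands = cfg$age_bands),
               "prevalences")
})

test_that("occupancy of death and advanced stages never decreases along a path", {
  p <- cohort_preset("macro", 10)$params
  prof <- covariate_profile(age_at_entry = 75, stratum = "macro")
  set.seed(11)
  grid <- seq(0, 8, by = 0.25)
  for (i in 1:100) {
    pa <- simulate_true_path(p, prof, horizon = 8)
    idx <- stage_index(stage_at(pa, grid))
    expect_true(all(diff(idx) >= 0))
    expect_true(all(diff(idx >= 2) >= 0))   # {>= G3a} absorbing as a set
    expect_true(all(diff(idx == 6) >= 0))   # death absorbing
  }
})
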