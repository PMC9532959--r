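# Brute-force oracles, independent of the package's forward/Viterbi C++ path.
# They enumerate every admissible hidden stage sequence at the observation
# times and accumulate transition x emission products directly, using only
# interval_transition_matrix() (itself cross-checked against Matrix::expm and
# a truncated series in test-core-model.R).

# All length-m sequences over living stages 1..5 that never decrease.
nondecreasing_sequences <- function(m) {
  grid <- as.matrix(expand.grid(rep(list(1:5), m)))
  grid[apply(grid, 1, function(x) all(diff(x) >= 0)), , drop = FALSE]
}

# Precomputed ingredients of the joint probability: initial weights, one
# kernel per observation interval, per-observation emission columns, and the
# terminal (death density / censor survival) weight vector.
oracle_ingredients <- function(record, params,
                               options = likelihood_options()) {
  E <- params$emission
  initp <- ckdhmm:::resolve_init_probs(options, list(record))
  m <- length(record$times)
  au <- if (options$age_update == "annual") "annual" else "interval_start"
  obs <- stage_index(record$stages)
  init_w <- if (options$init == "emission") {
    initp * E[1:5, obs[1]]
  } else {
    as.numeric(seq_len(5) == obs[1])
  }
  Ps <- vector("list", m)
  if (m > 1) for (k in 2:m) {
    Ps[[k]] <- interval_transition_matrix(params, record$profile,
                                          record$times[k - 1],
                                          record$times[k], au)
  }
  emis <- lapply(seq_len(m), function(k) E[1:5, obs[k]])
  term_w <- rep(1, 5)
  if (ckdhmm:::record_died(record)) {
    P <- interval_transition_matrix(params, record$profile,
                                    record$times[m], record$death_time, au)
    seg <- ckdhmm:::age_segments(record$profile$age_at_entry,
                                 record$times[m], record$death_time)
    age_d <- if (au == "annual") seg$age[nrow(seg)]
    else record$profile$age_at_entry + record$times[m]
    mm <- ckdhmm:::profile_multipliers(params, record$profile)
    qd <- params$q_death * mm["death"] *
      params$age_mult["death"]^(age_d - 60)
    term_w <- as.numeric(P[1:5, 1:5] %*% qd)
  } else if (options$use_censor &&
             record$censor_time > record$times[m] + 1e-12) {
    P <- interval_transition_matrix(params, record$profile,
                                    record$times[m], record$censor_time, au)
    term_w <- rowSums(P[1:5, 1:5])
  }
  list(m = m, init_w = init_w, Ps = Ps, emis = emis, term_w = term_w)
}

# Joint probability of one hidden sequence and the record's observations.
oracle_sequence_prob <- function(record, params, seq_states,
                                 options = likelihood_options(),
                                 ing = NULL) {
  if (is.null(ing)) ing <- oracle_ingredients(record, params, options)
  p <- ing$init_w[seq_states[1]]
  if (ing$m > 1) for (k in 2:ing$m) {
    p <- p * ing$Ps[[k]][seq_states[k - 1], seq_states[k]] *
      ing$emis[[k]][seq_states[k]]
  }
  p * ing$term_w[seq_states[ing$m]]
}

oracle_all_probs <- function(record, params, options) {
  ing <- oracle_ingredients(record, params, options)
  seqs <- nondecreasing_sequences(ing$m)
  probs <- apply(seqs, 1, function(s)
    oracle_sequence_prob(record, params, s, options, ing))
  list(seqs = seqs, probs = probs)
}

# Exhaustive-path-sum log-likelihood.
oracle_record_loglik <- function(record, params,
                                 options = likelihood_options()) {
  log(sum(oracle_all_probs(record, params, options)$probs))
}

# Exhaustive argmax over hidden sequences (Viterbi oracle). Among ties
# (within tol) prefers the lexicographically smallest = least severe.
oracle_viterbi <- function(record, params, options = likelihood_options()) {
  ap <- oracle_all_probs(record, params, options)
  best <- max(ap$probs)
  cand <- which(ap$probs >= best * (1 - 1e-12))
  ord <- cand[order(apply(ap$seqs[cand, , drop = FALSE], 1,
                          function(x) paste(x, collapse = "")))][1]
  list(states = stage_levels()[ap$seqs[ord, ]], prob = best)
}

# Posterior over the hidden stage at observation `upto`, then propagated and
# emitted: oracle for occupancy_forecast on short prefixes.
oracle_forecast <- function(params, record, query_time, upto,
                            options = likelihood_options()) {
  sub <- patient_record(record$patient_id, record$profile,
                        record$times[1:upto], record$stages[1:upto],
                        censor_time = record$times[upto])
  opts2 <- options; opts2$use_censor <- FALSE
  ap <- oracle_all_probs(sub, params, opts2)
  post <- vapply(1:5, function(s) sum(ap$probs[ap$seqs[, upto] == s]),
                 numeric(1))
  post <- post / sum(post)
  au <- if (options$age_update == "annual") "annual" else "interval_start"
  P <- interval_transition_matrix(params, record$profile,
                                  record$times[upto], query_time, au)
  v <- as.numeric(c(post, 0) %*% P)
  c(as.numeric(v[1:5] %*% params$emission[1:5, 1:5]), v[6])
}

# Small random parameter sets with full-band emission support.
random_params <- function(seed = NULL, stratum = "unmeasured") {
  if (!is.null(seed)) set.seed(seed)
  mis <- ckdhmm:::default_misclass()
  mis <- lapply(mis, function(p) p * stats::runif(1, 0.5, 1.5))
  model_parameters(
    q_prog = stats::runif(4, 0.01, 0.15),
    q_death = stats::runif(5, 0.005, 0.25),
    age_mult = c(prog = stats::runif(1, 1, 1.1),
                 death = stats::runif(1, 1, 1.1)),
    cov_mult = rbind(sex = stats::runif(2, 0.8, 1.6),
                     heart_failure = stats::runif(2, 0.8, 2.2)),
    misclass = mis, stratum = stratum)
}

# Random short records (some with death, some censored) for oracle checks.
random_record <- function(params, id = "R1", max_obs = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  profile <- covariate_profile(
    sex = stats::rbinom(1, 1, 0.5),
    heart_failure = stats::rbinom(1, 1, 0.2),
    age_at_entry = stats::runif(1, 40, 85),
    stratum = params$stratum)
  horizon <- stats::runif(1, 2, 8)
  init <- sample(1:4, 1)
  path <- simulate_true_path(params, profile, horizon,
                             init_stage = stage_levels()[init])
  m <- sample(2:max_obs, 1)
  end <- if (is.na(path$death_time)) horizon else path$death_time - 1e-3
  times <- sort(stats::runif(m, 0, end * 0.95))
  times[1] <- 0
  while (any(diff(times) < 1e-3)) times <- times + cumsum(c(0, rep(1e-3, m - 1)))
  stages <- emit_observations(path, times, params$emission)
  patient_record(id, profile, times, stages,
                 death_time = path$death_time,
                 censor_time = if (is.na(path$death_time)) horizon else NA)
}

# Convenience: a quick small test cohort.
small_cohort <- function(stratum = "micro", n = 60, seed = 1,
                         min_obs = 3L) {
  cfg <- cohort_preset(stratum, n)
  cfg$min_obs <- as.integer(min_obs)
  generate_cohort(cfg, seed = seed)
}
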