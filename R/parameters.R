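#' Covariate profile of a patient
#'
#' Fixed covariates entering the transition intensities multiplicatively, plus
#' age at cohort entry. The reference profile is a woman aged 60 with no heart
#' failure and no cancer history; hypertension and diabetes default to absent
#' and only act on the intensities when the parameter set carries multipliers
#' for them.
#'
#' @param sex 0 = female (reference), 1 = male.
#' @param heart_failure,cancer,hypertension,diabetes 0/1 indicators.
#' @param age_at_entry age in years at cohort entry (>= 18).
#' @param stratum albuminuria stratum label, one of
#'   `"unmeasured"`, `"normo"`, `"micro"`, `"macro"`.
#' @return An object of class `ckd_profile`.
#' @export
covariate_profile <- function(sex = 0, heart_failure = 0, cancer = 0,
                              hypertension = 0, diabetes = 0,
                              age_at_entry = 60, stratum = "unmeasured") {
  for (v in c(sex, heart_failure, cancer, hypertension, diabetes)) {
    if (!(length(v) == 1L && v %in% c(0, 1))) {
      stop("covariate indicators must be scalar 0/1")
    }
  }
  if (!(is.numeric(age_at_entry) && length(age_at_entry) == 1L &&
        age_at_entry >= 18)) {
    stop("age_at_entry must be a single number >= 18")
  }
  assert_stratum(stratum)
  structure(
    list(sex = as.numeric(sex), heart_failure = as.numeric(heart_failure),
         cancer = as.numeric(cancer), hypertension = as.numeric(hypertension),
         diabetes = as.numeric(diabetes),
         age_at_entry = as.numeric(age_at_entry), stratum = stratum),
    class = "ckd_profile"
  )
}

#' @rdname covariate_profile
#' @export
reference_profile <- function(stratum = "unmeasured") {
  covariate_profile(stratum = stratum)
}

#' @export
print.ckd_profile <- function(x, ...) {
  cat("Covariate profile:",
      if (x$sex == 1) "male," else "female,",
      "age at entry", x$age_at_entry, "\n")
  flags <- c(`heart failure` = x$heart_failure, cancer = x$cancer,
             hypertension = x$hypertension, diabetes = x$diabetes)
  cat("  comorbidity:", if (any(flags == 1))
    paste(names(flags)[flags == 1], collapse = ", ") else "none", "\n")
  cat("  albuminuria stratum:", x$stratum, "\n")
  invisible(x)
}

covariate_names <- function() {
  c("sex", "heart_failure", "cancer", "hypertension", "diabetes")
}

default_multipliers <- function() {
  m <- matrix(1, nrow = length(covariate_names()), ncol = 2,
              dimnames = list(covariate_names(), c("prog", "death")))
  m
}

#' Model parameter set for the progression HMM
#'
#' Bundles the baseline transition intensities (reference profile: woman aged
#' 60, no heart failure, no cancer), the covariate and age hazard-ratio
#' multipliers, and the misclassification (emission) probabilities.
#'
#' Baseline intensities are rates per year on the permitted arrows only:
#' four progression rates (stage k to k+1) and five death rates (each living
#' stage to death). Each covariate carries one multiplier shared across all
#' progression rates and one shared across all death rates; age acts
#' multiplicatively per year of age relative to 60 (e.g. 1.08 per year for
#' progression).
#'
#' @param q_prog length-4 numeric, rates/year for G1/2->G3a, G3a->G3b,
#'   G3b->G4, G4->G5.
#' @param q_death length-5 numeric, rates/year from each living stage to death.
#' @param age_mult length-2 numeric `c(prog, death)`: per-year-of-age hazard
#'   ratios (reference age 60).
#' @param cov_mult numeric matrix with rows among
#'   `sex, heart_failure, cancer, hypertension, diabetes` and columns
#'   `prog`, `death`; missing rows default to 1 (no effect).
#' @param misclass misclassification probabilities: a named list of
#'   `P(observed s | true r)` entries with names like `"G3A->G1_2"`
#'   (true -> observed), or a full 6x6 emission matrix. Entries outside the
#'   permitted band are rejected.
#' @param band misclassification band width in stages (default 2): an
#'   observation may fall at most `band` stages away from the true stage.
#' @param stratum albuminuria cohort label the parameters describe.
#' @return Object of class `ckd_params`.
#' @export
#' @examples
#' p <- model_parameters(
#'   q_prog = c(0.011, 0.012, 0.010, 0.013),
#'   q_death = c(0.007, 0.010, 0.015, 0.030, 0.150),
#'   age_mult = c(prog = 1.08, death = 1.09),
#'   misclass = list("G1_2->G3A" = 0.029)
#' )
#' p
model_parameters <- function(q_prog, q_death,
                             age_mult = c(prog = 1, death = 1),
                             cov_mult = NULL,
                             misclass = NULL,
                             band = 2L,
                             stratum = "unmeasured") {
  q_prog <- as.numeric(q_prog); q_death <- as.numeric(q_death)
  if (length(q_prog) != 4L || length(q_death) != 5L) {
    stop("q_prog must have length 4 and q_death length 5")
  }
  if (any(q_prog < 0) || any(q_death < 0)) stop("baseline rates must be >= 0")
  age_mult <- as.numeric(age_mult)
  if (length(age_mult) != 2L || any(age_mult <= 0)) {
    stop("age_mult must be two positive numbers c(prog, death)")
  }
  names(age_mult) <- c("prog", "death")
  cm <- default_multipliers()
  if (!is.null(cov_mult)) {
    cov_mult <- as.matrix(cov_mult)
    if (is.null(rownames(cov_mult)) ||
        !all(rownames(cov_mult) %in% covariate_names()) ||
        ncol(cov_mult) != 2L) {
      stop("cov_mult must have rows named after covariates and columns prog, death")
    }
    if (any(cov_mult <= 0)) stop("covariate multipliers must be > 0")
    cm[rownames(cov_mult), ] <- cov_mult
  }
  assert_stratum(stratum)
  band <- as.integer(band)
  if (band < 1L || band > 4L) stop("band must be an integer in 1..4")
  E <- build_emission_matrix(misclass, band = band)
  names(q_prog) <- paste0(stage_levels()[1:4], "->", stage_levels()[2:5])
  names(q_death) <- paste0(stage_levels(), "->DEATH")
  structure(
    list(q_prog = q_prog, q_death = q_death, age_mult = age_mult,
         cov_mult = cm, emission = E, band = band, stratum = stratum),
    class = "ckd_params"
  )
}

#' @export
print.ckd_params <- function(x, digits = 4, ...) {
  cat("Kidney-function progression HMM parameters (stratum:", x$stratum, ")\n")
  cat("Baseline intensities (/year, reference profile):\n")
  print(round(c(x$q_prog, x$q_death), digits))
  cat("Age multipliers per year (ref 60): progression",
      round(x$age_mult["prog"], digits), ", death",
      round(x$age_mult["death"], digits), "\n")
  active <- x$cov_mult[apply(x$cov_mult != 1, 1, any), , drop = FALSE]
  if (nrow(active)) {
    cat("Covariate multipliers:\n"); print(round(active, digits))
  } else cat("Covariate multipliers: all 1 (no effect)\n")
  cat("Misclassification matrix (rows = true stage):\n")
  print(round(x$emission, digits))
  invisible(x)
}

#' Validate a parameter set
#'
#' @param params a `ckd_params` object.
#' @return `params`, invisibly; stops on an invalid set.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "ckd_params"))
  if (any(params$q_prog < 0) || any(params$q_death < 0)) {
    stop("baseline rates must be >= 0")
  }
  if (any(params$cov_mult <= 0) || any(params$age_mult <= 0)) {
    stop("multipliers must be > 0")
  }
  validate_emission_matrix(params$emission, band = params$band)
  invisible(params)
}

# Product of covariate hazard ratios for a profile (excluding age), for the
# progression and death columns respectively.
profile_multipliers <- function(params, profile) {
  stopifnot(inherits(profile, "ckd_profile"))
  x <- unlist(profile[covariate_names()])
  prog <- prod(params$cov_mult[, "prog"]^x)
  death <- prod(params$cov_mult[, "death"]^x)
  c(prog = prog, death = death)
}
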