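#' Stage labels of the kidney-function state space
#'
#' The model operates on five living eGFR stages plus an absorbing death state.
#' Stages G1 and G2 are combined (eGFR > 60 ml/min/1.73m2 carries little
#' information about progression risk on its own), giving the ordered living
#' stages G1/2 < G3a < G3b < G4 < G5. Labels use an underscore (`G1_2`) so that
#' they are file-system and CSV safe.
#'
#' @param include_death logical; append the `DEATH` label.
#' @return Character vector of stage labels in increasing severity.
#' @export
#' @examples
#' stage_levels()
#' stage_levels(include_death = TRUE)
stage_levels <- function(include_death = FALSE) {
  s <- c("G1_2", "G3A", "G3B", "G4", "G5")
  if (include_death) s <- c(s, "DEATH")
  s
}

#' @rdname stage_levels
#' @export
death_state <- function() "DEATH"

#' eGFR ranges associated with each living stage
#'
#' @return Data frame with stage label, lower and upper eGFR bound
#'   (ml/min/1.73m2); the ranges partition (0, Inf).
#' @export
stage_egfr_ranges <- function() {
  data.frame(
    stage = stage_levels(),
    egfr_lower = c(60, 45, 30, 15, 0),
    egfr_upper = c(Inf, 59, 44, 29, 14),
    stringsAsFactors = FALSE
  )
}

#' Integer index of a stage label
#'
#' Severity is encoded by position: G1/2 = 1 up to G5 = 5, DEATH = 6.
#'
#' @param stage character vector of stage labels.
#' @return Integer vector of indices.
#' @export
stage_index <- function(stage) {
  idx <- match(stage, stage_levels(include_death = TRUE))
  if (anyNA(idx)) {
    stop("unknown stage label(s): ",
         paste(unique(stage[is.na(idx)]), collapse = ", "))
  }
  idx
}

n_living <- function() 5L
n_states <- function() 6L

#' Albuminuria cohort labels
#' @return The four albuminuria strata used to define cohorts.
#' @export
albuminuria_strata <- function() c("unmeasured", "normo", "micro", "macro")

assert_stratum <- function(stratum) {
  if (!(is.character(stratum) && length(stratum) == 1L &&
        stratum %in% albuminuria_strata())) {
    stop("albuminuria stratum must be one of: ",
         paste(albuminuria_strata(), collapse = ", "))
  }
  invisible(stratum)
}
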