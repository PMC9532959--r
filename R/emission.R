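#' Permitted misclassification support
#'
#' An observed eGFR stage may differ from the true stage by at most `band`
#' stages among the living stages: measurement error and biological variation
#' move a single eGFR reading into nearby categories, but a true G1/2 cannot
#' read as G4 or G5. Death is always classified correctly, is never emitted by
#' a living stage, and emits nothing else.
#'
#' @param band band width in stages (default 2).
#' @return 6x6 logical matrix: `TRUE` where `P(observed | true)` may be > 0.
#' @export
emission_support <- function(band = 2L) {
  k <- n_states()
  S <- matrix(FALSE, k, k,
              dimnames = list(stage_levels(TRUE), stage_levels(TRUE)))
  for (r in seq_len(n_living())) {
    for (s in seq_len(n_living())) {
      if (abs(r - s) <= band) S[r, s] <- TRUE
    }
  }
  S[k, k] <- TRUE
  S
}

#' Build the misclassification (emission) matrix
#'
#' Rows index the true stage, columns the observed stage; each row is a
#' probability distribution. Off-diagonal mass is restricted to the
#' neighbour band (see [emission_support()]); the diagonal receives the
#' complement so each row sums to 1.
#'
#' @param misclass `NULL` (identity: no misclassification), a named list/vector
#'   of off-diagonal probabilities with names `"TRUE->OBSERVED"`
#'   (e.g. `"G1_2->G3A" = 0.029`), or a full 6x6 row-stochastic matrix
#'   already satisfying the support constraint.
#' @param band permitted band width (default 2).
#' @return 6x6 emission matrix with stage dimnames.
#' @export
#' @examples
#' E <- build_emission_matrix(list("G1_2->G3A" = 0.029))
#' E["G1_2", "G1_2"]  # 0.971
build_emission_matrix <- function(misclass = NULL, band = 2L) {
  k <- n_states()
  lv <- stage_levels(TRUE)
  if (is.matrix(misclass)) {
    E <- misclass
    dimnames(E) <- list(lv, lv)
    validate_emission_matrix(E, band = band)
    return(E)
  }
  E <- diag(k)
  dimnames(E) <- list(lv, lv)
  if (!is.null(misclass) && length(misclass)) {
    pr <- unlist(misclass)
    nm <- names(pr)
    if (is.null(nm) || any(nm == "")) {
      stop("misclassification entries must be named \"TRUE->OBSERVED\"")
    }
    parts <- strsplit(nm, "->", fixed = TRUE)
    for (i in seq_along(pr)) {
      if (length(parts[[i]]) != 2L) {
        stop("malformed misclassification name: ", nm[i])
      }
      r <- stage_index(parts[[i]][1]); s <- stage_index(parts[[i]][2])
      if (r == s) stop("specify only off-diagonal entries (", nm[i], ")")
      if (pr[i] < 0 || pr[i] > 1) {
        stop("misclassification probability out of [0,1]: ", nm[i])
      }
      if (!emission_support(band)[r, s]) {
        stop("misclassification ", nm[i],
             " violates the ", band, "-stage neighbour constraint")
      }
      E[r, s] <- pr[i]
    }
    for (r in seq_len(n_living())) {
      off <- sum(E[r, -r])
      if (off > 1) {
        stop("misclassification probabilities for true stage ", lv[r],
             " sum to ", signif(off, 4), " > 1")
      }
      E[r, r] <- 1 - off
    }
  }
  validate_emission_matrix(E, band = band)
  E
}

#' @rdname build_emission_matrix
#' @param E candidate emission matrix.
#' @export
validate_emission_matrix <- function(E, band = 2L) {
  k <- n_states()
  if (!is.matrix(E) || !all(dim(E) == k)) stop("emission matrix must be 6x6")
  if (any(E < -1e-12) || any(E > 1 + 1e-12)) {
    stop("emission probabilities must lie in [0,1]")
  }
  if (any(abs(rowSums(E) - 1) > 1e-10)) {
    stop("emission matrix rows must sum to 1")
  }
  S <- emission_support(band)
  if (any(E[!S] > 1e-12)) {
    bad <- which(!S & E > 1e-12, arr.ind = TRUE)[1, ]
    stop("emission entry ", stage_levels(TRUE)[bad[1]], "->",
         stage_levels(TRUE)[bad[2]],
         " violates the neighbour-band / death constraints")
  }
  invisible(E)
}
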