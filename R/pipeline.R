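#' Write a cohort to CSV (long format)
#'
#' One row per eGFR observation; a patient who died gets a final row with
#' `observed_stage = DEATH` at the death time. Stage labels use `G1_2`
#' (underscore) so the combined G1/G2 stage is file-system safe. The
#' `censor_time_years` column preserves the administrative censoring time of
#' survivors.
#'
#' @param cohort a [ckd_cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#'
#' Validates the schema row by row (known stage labels, strictly increasing
#' times within each patient, `DEATH` only as a patient's final row) and
#' reconstructs the [ckd_cohort()]. Errors name the offending row.
#'
#' @param path CSV path written by [write_cohort_csv()] (or matching its
#'   schema).
#' @param stratum optional stratum override; defaults to the file's
#'   `albuminuria_stratum` column (which must be constant).
#' @return A [ckd_cohort()].
#' @export
read_cohort_csv <- function(path, stratum = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_years", "observed_stage", "sex",
            "heart_failure", "cancer", "hypertension", "diabetes",
            "age_at_entry", "albuminuria_stratum", "censor_time_years")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("cohort CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!nrow(df)) {
    return(ckd_cohort(list(),
                      stratum = if (is.null(stratum)) "unmeasured" else stratum))
  }
  ok <- df$observed_stage %in% stage_levels(TRUE)
  if (!all(ok)) {
    stop("row ", which(!ok)[1], ": unknown observed_stage '",
         df$observed_stage[which(!ok)[1]], "'")
  }
  if (is.null(stratum)) {
    us <- unique(df$albuminuria_stratum)
    if (length(us) != 1L) stop("albuminuria_stratum must be constant")
    stratum <- us
  }
  df$.row <- seq_len(nrow(df))
  records <- lapply(split(df, df$patient_id), function(d) {
    d <- d[order(d$time_years), ]
    dpos <- which(d$observed_stage == death_state())
    if (length(dpos) > 1L || (length(dpos) == 1L && dpos != nrow(d))) {
      stop("row ", d$.row[dpos[1]], ": DEATH must be the single final row ",
           "for patient ", d$patient_id[1])
    }
    if (any(diff(d$time_years) <= 0)) {
      bad <- which(diff(d$time_years) <= 0)[1] + 1L
      stop("row ", d$.row[bad], ": non-increasing time for patient ",
           d$patient_id[1])
    }
    died <- length(dpos) == 1L
    liv <- if (died) d[-nrow(d), ] else d
    profile <- covariate_profile(
      sex = d$sex[1], heart_failure = d$heart_failure[1],
      cancer = d$cancer[1], hypertension = d$hypertension[1],
      diabetes = d$diabetes[1], age_at_entry = d$age_at_entry[1],
      stratum = stratum)
    patient_record(
      patient_id = d$patient_id[1], profile = profile,
      times = liv$time_years, stages = liv$observed_stage,
      death_time = if (died) d$time_years[nrow(d)] else NA_real_,
      censor_time = d$censor_time_years[1])
  })
  ids <- vapply(records, function(r) as.character(r$patient_id), character(1))
  ckd_cohort(unname(records[order(ids)]), stratum = stratum)
}

#' Write / read model parameters as a flat key-value file
#'
#' Plain-text UTF-8 serialisation, one `key = value` pair per line: baseline
#' rates per transition, multipliers per covariate, misclassification entries
#' per (true, observed) pair, cohort label and band width.
#'
#' @param params a [model_parameters()] object.
#' @param path file path.
#' @return `path` invisibly (write) or a `ckd_params` (read).
#' @export
write_model_config <- function(params, path) {
  validate_parameters(params)
  lv <- stage_levels()
  lines <- c(
    paste0("stratum = ", params$stratum),
    paste0("band = ", params$band),
    paste0("rate.", names(params$q_prog), " = ",
           format(params$q_prog, digits = 17)),
    paste0("rate.", names(params$q_death), " = ",
           format(params$q_death, digits = 17)),
    paste0("age_mult.prog = ", format(params$age_mult["prog"], digits = 17)),
    paste0("age_mult.death = ", format(params$age_mult["death"], digits = 17))
  )
  for (cv in rownames(params$cov_mult)) {
    lines <- c(lines,
               paste0("mult.", cv, ".prog = ",
                      format(params$cov_mult[cv, "prog"], digits = 17)),
               paste0("mult.", cv, ".death = ",
                      format(params$cov_mult[cv, "death"], digits = 17)))
  }
  E <- params$emission
  for (r in 1:5) for (s in 1:5) {
    if (r != s && E[r, s] > 0) {
      lines <- c(lines, paste0("emission.", lv[r], "->", lv[s], " = ",
                               format(E[r, s], digits = 17)))
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw)) & !grepl("^\\s*#", raw)]
  kv <- regmatches(raw, regexec("^\\s*([^=]+?)\\s*=\\s*(.+?)\\s*$", raw))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad)) stop("malformed config line ", bad[1], ": ", raw[bad[1]])
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  get1 <- function(k, default = NULL) {
    i <- which(keys == k)
    if (!length(i)) {
      if (is.null(default)) stop("config is missing key: ", k)
      return(default)
    }
    vals[i[1]]
  }
  lv <- stage_levels()
  q_prog <- as.numeric(vapply(paste0("rate.", lv[1:4], "->", lv[2:5]),
                              get1, character(1)))
  q_death <- as.numeric(vapply(paste0("rate.", lv, "->DEATH"),
                               get1, character(1)))
  age_mult <- c(prog = as.numeric(get1("age_mult.prog", "1")),
                death = as.numeric(get1("age_mult.death", "1")))
  cm <- NULL
  cov_keys <- grepl("^mult\\.", keys)
  if (any(cov_keys)) {
    covs <- unique(sub("^mult\\.([^.]+)\\..*$", "\\1", keys[cov_keys]))
    cm <- matrix(1, length(covs), 2, dimnames = list(covs, c("prog", "death")))
    for (cv in covs) {
      cm[cv, "prog"] <- as.numeric(get1(paste0("mult.", cv, ".prog"), "1"))
      cm[cv, "death"] <- as.numeric(get1(paste0("mult.", cv, ".death"), "1"))
    }
  }
  em_keys <- which(grepl("^emission\\.", keys))
  mis <- NULL
  if (length(em_keys)) {
    mis <- as.list(as.numeric(vals[em_keys]))
    names(mis) <- sub("^emission\\.", "", keys[em_keys])
  }
  model_parameters(q_prog = q_prog, q_death = q_death, age_mult = age_mult,
                   cov_mult = cm, misclass = mis,
                   band = as.integer(get1("band", "2")),
                   stratum = get1("stratum", "unmeasured"))
}

#' Pipeline configuration
#'
#' @param out_dir output directory for artifacts.
#' @param seed master seed; all stage-level randomness is derived from it
#'   through named substreams.
#' @param cohort_csv optional path to an existing cohort CSV; when `NULL`
#'   the simulate stage must be enabled.
#' @param n,stratum generator size and stratum for the simulate stage.
#' @param stages character vector of stages to run, in dependency order,
#'   from `simulate`, `fit`, `decode`, `evaluate`, `calibrate`.
#' @param covariates covariates fitted (see [fit_ckd_hmm()]).
#' @param band emission band width.
#' @param age_update likelihood age-updating convention.
#' @param subsample optional cap on the number of patients used for fitting.
#' @param overwrite allow overwriting existing artifacts.
#' @return A `ckd_pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1, cohort_csv = NULL,
                            n = 500, stratum = "unmeasured",
                            stages = c("simulate", "fit", "decode",
                                       "evaluate", "calibrate"),
                            covariates = c("sex", "heart_failure", "cancer"),
                            band = 2L, age_update = "interval_start",
                            subsample = NULL, overwrite = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!(is.numeric(seed) && length(seed) == 1L && seed >= 0 &&
        seed == round(seed))) {
    stop("seed must be a non-negative integer")
  }
  needs_fit <- intersect(c("decode", "evaluate", "calibrate"), stages)
  if (length(needs_fit) && !("fit" %in% stages)) {
    stop("stage(s) ", paste(needs_fit, collapse = ", "),
         " require the fit stage (missing fit artifact)")
  }
  if (!("simulate" %in% stages) && is.null(cohort_csv)) {
    stop("either enable the simulate stage or supply cohort_csv")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 cohort_csv = cohort_csv, n = as.integer(n),
                 stratum = stratum, stages = stages,
                 covariates = covariates, band = as.integer(band),
                 age_update = age_update, subsample = subsample,
                 overwrite = isTRUE(overwrite)),
            class = "ckd_pipeline_config")
}

substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) * 1009L + as.integer(h %% 100003L)) %% 2147483587L + 1L
}

#' Run the end-to-end analysis pipeline
#'
#' Generate or load a cohort, split it into training and testing halves, fit
#' the HMM on the training half, decode and grade the testing half, compute
#' monitoring metrics, and calibrate predicted against observed stage
#' occupancy on the testing half. Every artifact is written under
#' `config$out_dir` and listed in a manifest together with the seed, a
#' configuration hash and each file's MD5 checksum. Runs are reproducible
#' given the seed.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the manifest data frame (also written to
#'   `manifest.txt`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ckd_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- proc.time()[["elapsed"]]
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  art <- character(0)
  emit <- function(file, class) {
    path <- file.path(config$out_dir, file)
    if (file.exists(path) && !config$overwrite &&
        !path %in% names(art)) {
      stop("artifact ", file, " exists; set overwrite = TRUE to replace it")
    }
    art[path] <<- class
    path
  }
  cfg_hash <- unname(tools::md5sum({
    tf <- tempfile(); writeLines(deparse(config[setdiff(names(config),
                                                        "out_dir")]), tf); tf
  }))

  # --- simulate / load ------------------------------------------------------
  if ("simulate" %in% config$stages) {
    say("simulate: ", config$n, " patients (", config$stratum, ")")
    cohort <- generate_cohort(cohort_preset(config$stratum, n = config$n),
                              seed = substream_seed(config$seed, "cohort"))
    write_cohort_csv(cohort, emit("cohort.csv", "cohort"))
  } else {
    say("load cohort: ", config$cohort_csv)
    cohort <- read_cohort_csv(config$cohort_csv)
    art[config$cohort_csv] <- "cohort"
  }

  opts <- likelihood_options(age_update = config$age_update)
  fit <- NULL; sp <- NULL
  if ("fit" %in% config$stages) {
    sp <- split_sample(cohort, seed = substream_seed(config$seed, "split"))
    train <- sp$train
    if (!is.null(config$subsample) &&
        config$subsample < length(train$records)) {
      train <- subsample_patients(train, config$subsample,
                                  seed = substream_seed(config$seed, "subsample"))
    }
    say("fit: ", length(train$records), " training patients")
    fit <- fit_ckd_hmm(train, covariates = config$covariates,
                       band = config$band, options = opts,
                       seed = substream_seed(config$seed, "optim"))
    rpt <- emit("fit_report.txt", "fit_report")
    writeLines(utils::capture.output(print(fit)), rpt)
    utils::write.csv(fit$ci, emit("fit_parameters.csv", "fit_report"),
                     row.names = FALSE)
    utils::write.csv(multiplier_table(fit),
                     emit("multiplier_table.csv", "multiplier_table"),
                     row.names = FALSE)
  }

  if ("decode" %in% config$stages) {
    say("decode: grading the testing half")
    gr <- grading_rates(sp$test, fit$params, options = opts)
    utils::write.csv(as.data.frame(gr),
                     emit("grading_report.csv", "grading_report"),
                     row.names = FALSE)
  }

  if ("evaluate" %in% config$stages) {
    say("evaluate: monitoring metrics")
    mr <- monitoring_report(fit$params)
    utils::write.csv(mr, emit("monitoring_report.csv", "monitoring_report"),
                     row.names = FALSE)
  }

  if ("calibrate" %in% config$stages) {
    say("calibrate: testing half")
    cal <- calibration_table(fit$params, sp$test, options = opts)
    utils::write.csv(as.data.frame(cal),
                     emit("calibration_table.csv", "calibration_table"),
                     row.names = FALSE)
    plot_calibration(cal, emit("calibration_plot.png", "figure"))
  }

  say("done in ", round(proc.time()[["elapsed"]] - t_start, 2), "s")
  writeLines(log_lines, file.path(config$out_dir, "pipeline_log.txt"))
  manifest <- data.frame(
    file = basename(names(art)), class = unname(art),
    bytes = file.size(names(art)),
    md5 = unname(tools::md5sum(names(art))),
    seed = config$seed, config_hash = cfg_hash,
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.txt"),
                   row.names = FALSE)
  invisible(manifest)
}
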