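#' Read a survival table
#'
#' Reads the package's delimited patient-record format: a CSV with header
#' columns `patient_id`, `enroll_time_months`, `followup_months`, `event`,
#' optional extra columns (preserved), and optional comment lines starting
#' with `#`. Rows violating the record invariants are reported with their
#' line numbers.
#'
#' @param path File path.
#' @param horizon Optional trial horizon in months; inferred as
#'   `max(enroll_time_months + followup_months)` when absent.
#' @return A tibble of validated records with a `horizon` attribute.
#' @export
read_survival_table <- function(path, horizon = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  if (nrow(d) == 0) abort(paste0("Empty survival table: ", path))
  needed <- c("patient_id", "enroll_time_months", "followup_months", "event")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols) > 0)
    abort(paste0("Missing column(s) in ", path, ": ",
                 paste(missing_cols, collapse = ", ")))
  problems <- character(0)
  bad <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx) > 0)
      problems <<- c(problems, paste0("row ", idx, ": ", msg))
  }
  bad(!is.finite(d$followup_months) | d$followup_months <= 0,
      "followup_months must be positive")
  bad(!is.finite(d$enroll_time_months) | d$enroll_time_months < 0,
      "enroll_time_months must be nonnegative")
  bad(!(d$event %in% c(0, 1)), "event must be 0 or 1")
  if (length(problems) > 0)
    abort(paste0("Invalid records in ", path, ":\n  ",
                 paste(head(problems, 10), collapse = "\n  ")))
  d$event <- as.integer(d$event)
  horizon <- horizon %||% max(d$enroll_time_months + d$followup_months)
  if (any(d$enroll_time_months + d$followup_months > horizon + 1e-9))
    abort("Some records extend beyond the stated horizon.")
  attr(d, "horizon") <- horizon
  d
}

#' Write a survival table
#'
#' Writes patient records in the CSV dialect read by
#' [read_survival_table()], with a comment header recording units and
#' provenance.
#'
#' @param data A patient-record data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(data, path) {
  data <- as_trial_frame(data, require_enroll = TRUE)
  hdr <- c(
    "# single-arm trial survival table",
    "# times in months (enroll_time_months, followup_months); event: 1 = observed, 0 = censored",
    if (!is.null(attr(data, "config_fingerprint")))
      paste0("# source: ", attr(data, "config_fingerprint")),
    if (!is.null(attr(data, "horizon")))
      paste0("# horizon_months: ", attr(data, "horizon"))
  )
  writeLines(hdr, path)
  readr::write_csv(tibble::as_tibble(data), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a run configuration
#'
#' Reads a YAML run configuration with sections `prior` (either
#' `mean`/`sd` or `jeffreys: true`), `design` (`efs0`, `tau_years`,
#' `alpha`, `analysis_times`, `rule`, `decision_scale`,
#' `futility_threshold`), `simulation` ([sim_config()] fields), `oc`
#' (`reps`, `sample_sizes`, `decision_prob`, `power_target`), and a
#' top-level `seed`. Unknown keys anywhere are rejected.
#'
#' @param path File path.
#' @return A list with elements `prior` (an `efs_prior` or `NULL`),
#'   `plan_args`, `sim` (a `sim_config` or `NULL`), `oc`, `seed`, and
#'   `resolved` (the raw key-value document, for provenance echoing).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- yaml::read_yaml(path)
  known_top <- c("prior", "design", "simulation", "oc", "seed")
  check_keys(raw, known_top, "top level")

  prior <- NULL
  if (!is.null(raw$prior)) {
    check_keys(raw$prior, c("mean", "sd", "shape", "rate", "jeffreys"), "prior")
    prior <- if (isTRUE(raw$prior$jeffreys)) jeffreys_prior()
      else if (!is.null(raw$prior$shape)) gamma_prior(raw$prior$shape, raw$prior$rate)
      else gamma_prior_mean_sd(raw$prior$mean, raw$prior$sd)
  }

  plan_args <- NULL
  if (!is.null(raw$design)) {
    check_keys(raw$design, c("efs0", "tau_years", "alpha", "analysis_times",
                             "rule", "decision_scale", "futility_threshold"),
               "design")
    plan_args <- list(
      efs0 = raw$design$efs0,
      tau = raw$design$tau_years %||% 2,
      alpha = raw$design$alpha %||% 0.05,
      analysis_times = unlist(raw$design$analysis_times) %||% c(18, 24, 30, 36, 42, 48),
      rule = raw$design$rule %||% "linear",
      decision_scale = raw$design$decision_scale %||% "z",
      futility_threshold = raw$design$futility_threshold
    )
  }

  sim <- NULL
  if (!is.null(raw$simulation)) {
    sim_fields <- c("n_groups", "enroll_interval", "accrual_mean",
                    "min_group_size", "fixed_group_size", "hazard_range",
                    "event_rate_range", "horizon", "censor_fraction", "seed")
    check_keys(raw$simulation, sim_fields, "simulation")
    args <- raw$simulation
    args$hazard_range <- unlist(args$hazard_range)
    args$event_rate_range <- unlist(args$event_rate_range)
    sim <- do.call(sim_config, args)
  }

  oc <- NULL
  if (!is.null(raw$oc)) {
    check_keys(raw$oc, c("reps", "sample_sizes", "decision_prob", "power_target"),
               "oc")
    oc <- raw$oc
    oc$sample_sizes <- unlist(oc$sample_sizes)
  }

  list(prior = prior, plan_args = plan_args, sim = sim, oc = oc,
       seed = raw$seed, resolved = raw)
}

check_keys <- function(x, known, where) {
  if (is.null(x)) return(invisible(TRUE))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0)
    abort(paste0("Unknown key(s) in ", where, ": ",
                 paste(unknown, collapse = ", "),
                 ". Known keys: ", paste(known, collapse = ", "), "."))
  invisible(TRUE)
}

#' Write a run configuration
#'
#' @param config A list in the shape produced by [read_run_config()]'s
#'   `resolved` element (plain nested key-value lists).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
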