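#' Configuration of the trial data-generating process
#'
#' Describes a single-arm trial with staggered group accrual: enrollment
#' opens every `enroll_interval` months for `n_groups` periods, each period
#' accruing `max(Poisson(accrual_mean), min_group_size)` patients (or exactly
#' `fixed_group_size` when set). Each group draws a hazard
#' \eqn{\lambda_j \sim U(hazard\_range)} (per year) and an event rate
#' \eqn{p_j \sim U(event\_rate\_range)}; the group's event count is
#' \eqn{Binom(n_j, p_j)}, event times are exponential conditioned to fall
#' inside the patient's administrative window (from enrollment to the trial
#' horizon), and event-free patients are administratively censored at the
#' horizon, with a fraction `censor_fraction` of them re-censored at a
#' uniform earlier time.
#'
#' Defaults correspond to a 6-year trial enrolling every 4 months for
#' 3 years with Poisson(10) accrual, a minimum of 6 patients per period, and
#' 10\% random censoring.
#'
#' @param n_groups Number of enrollment periods (default 9).
#' @param enroll_interval Months between period starts (default 4).
#' @param accrual_mean Poisson mean per period (default 10).
#' @param min_group_size Lower clip on period accrual (default 6).
#' @param fixed_group_size Optional integer; when set, every period enrolls
#'   exactly this many patients (used for equal-group-size sweeps).
#' @param hazard_range Length-2 range for the per-year hazard uniform draw.
#' @param event_rate_range Length-2 range for the event-rate uniform draw.
#' @param horizon Trial horizon, months (default 72).
#' @param censor_fraction Fraction of event-free patients randomly censored
#'   before the horizon (default 0.10).
#' @param seed Optional integer seed stored with the configuration and used
#'   by [simulate_trial()] when no explicit seed is given.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(hazard_range = c(0.02, 0.03), event_rate_range = c(0.05, 0.10))
#' @export
sim_config <- function(n_groups = 9, enroll_interval = 4, accrual_mean = 10,
                       min_group_size = 6, fixed_group_size = NULL,
                       hazard_range = c(0.02, 0.03),
                       event_rate_range = c(0.05, 0.10),
                       horizon = 72, censor_fraction = 0.10, seed = NULL) {
  cfg <- structure(
    list(n_groups = as.integer(n_groups), enroll_interval = enroll_interval,
         accrual_mean = accrual_mean, min_group_size = as.integer(min_group_size),
         fixed_group_size = if (!is.null(fixed_group_size)) as.integer(fixed_group_size),
         hazard_range = as.numeric(hazard_range),
         event_rate_range = as.numeric(event_rate_range),
         horizon = horizon, censor_fraction = censor_fraction,
         seed = if (!is.null(seed)) as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!inherits(cfg, "sim_config")) abort("Expected a `sim_config` object.")
  with(cfg, {
    if (n_groups < 1) abort("`n_groups` must be at least 1.")
    if (enroll_interval <= 0) abort("`enroll_interval` must be positive (months).")
    if (n_groups * enroll_interval > horizon)
      abort("All groups must enroll before the horizon: n_groups * enroll_interval <= horizon.")
    if (length(hazard_range) != 2 || any(hazard_range <= 0) ||
        hazard_range[1] > hazard_range[2] || hazard_range[2] >= 1)
      abort("`hazard_range` must be (low, high) inside (0, 1) per year with low <= high.")
    if (length(event_rate_range) != 2 || any(event_rate_range < 0) ||
        event_rate_range[1] > event_rate_range[2] || event_rate_range[2] >= 1)
      abort("`event_rate_range` must be (low, high) inside [0, 1) with low <= high.")
    if (censor_fraction < 0 || censor_fraction >= 1)
      abort("`censor_fraction` must lie in [0, 1).")
    if (!is.null(fixed_group_size) && fixed_group_size < 1)
      abort("`fixed_group_size` must be a positive integer.")
    if (accrual_mean <= 0) abort("`accrual_mean` must be positive.")
  })
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  acc <- if (is.null(x$fixed_group_size))
    sprintf("max(Pois(%g), %d)", x$accrual_mean, x$min_group_size)
  else sprintf("fixed %d", x$fixed_group_size)
  cat(sprintf(
    "<sim_config> %d groups every %g mo, accrual %s, horizon %g mo\n  hazard U(%g, %g) /yr, event rate U(%g, %g), censor fraction %g\n",
    x$n_groups, x$enroll_interval, acc, x$horizon,
    x$hazard_range[1], x$hazard_range[2],
    x$event_rate_range[1], x$event_rate_range[2], x$censor_fraction))
  invisible(x)
}

#' Draw per-period accrual counts
#'
#' Poisson accrual clipped from below at `min_group_size`, or the fixed
#' override when `fixed_group_size` is set. Uses the current RNG stream.
#'
#' @param config A `sim_config`.
#' @return Integer vector of length `n_groups`.
#' @export
draw_group_sizes <- function(config) {
  validate_sim_config(config)
  if (!is.null(config$fixed_group_size))
    return(rep(config$fixed_group_size, config$n_groups))
  pmax(rpois(config$n_groups, config$accrual_mean), config$min_group_size)
}

#' Simulate one single-arm trial dataset
#'
#' Generates a full trial under the configured data-generating process. The
#' RNG stream order is fixed: (1) group sizes, (2) group hazards, (3) group
#' event rates, then per group (4) the binomial event count and (5) the
#' truncated-exponential event times, and finally (6) the random-censoring
#' selection and (7) the replacement censoring times. Identical
#' configuration and seed therefore reproduce the dataset exactly.
#'
#' @param config A `sim_config`.
#' @param seed Optional integer seed; falls back to `config$seed`; if both
#'   are `NULL` the current RNG stream is used (so callers can manage
#'   common-random-number schemes themselves).
#' @return A tibble of patient records with columns `patient_id`,
#'   `group`, `enroll_time_months`, `followup_months`, `event`, carrying the
#'   horizon and a configuration fingerprint as attributes `horizon` and
#'   `config_fingerprint`.
#' @examples
#' d <- simulate_trial(sim_config(seed = 1))
#' survival_stats(d)
#' @export
simulate_trial <- function(config, seed = NULL) {
  validate_sim_config(config)
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)

  G <- config$n_groups
  enroll <- (seq_len(G) - 1) * config$enroll_interval
  n_j <- draw_group_sizes(config)
  lambda_j <- runif(G, config$hazard_range[1], config$hazard_range[2])
  p_j <- runif(G, config$event_rate_range[1], config$event_rate_range[2])

  n_total <- sum(n_j)
  group <- rep.int(seq_len(G), n_j)
  enroll_all <- rep.int(enroll, n_j)
  followup <- numeric(n_total)
  event <- integer(n_total)

  offset <- 0L
  for (j in seq_len(G)) {
    window_months <- config$horizon - enroll[j]
    window_years <- window_months / 12
    m <- rbinom(1L, n_j[j], p_j[j])
    if (m > 0) {
      # inverse-CDF draw from Exp(lambda_j) conditioned on (0, window)
      u <- runif(m)
      t_event <- -log(1 - u * (1 - exp(-lambda_j[j] * window_years))) / lambda_j[j]
      followup[offset + seq_len(m)] <- t_event * 12
      event[offset + seq_len(m)] <- 1L
    }
    if (m < n_j[j]) followup[offset + (m + 1L):n_j[j]] <- window_months
    offset <- offset + n_j[j]
  }

  # random censoring among event-free patients
  free <- which(event == 0L)
  k <- round(config$censor_fraction * length(free))
  if (k > 0) {
    pick <- free[sample.int(length(free), k)]
    followup[pick] <- runif(k, 0, followup[pick])
  }

  out <- tibble::new_tibble(
    list(
      patient_id = sprintf("P%04d", seq_len(n_total)),
      group = group,
      enroll_time_months = enroll_all,
      followup_months = followup,
      event = event
    ),
    nrow = n_total
  )
  attr(out, "horizon") <- config$horizon
  attr(out, "config_fingerprint") <- fingerprint_config(config, seed)
  out
}

fingerprint_config <- function(config, seed) {
  vals <- unlist(config[!vapply(config, is.null, logical(1))])
  paste0("sim_config{", paste(names(vals), vals, sep = "=", collapse = ";"),
         if (!is.null(seed)) paste0(";run_seed=", seed), "}")
}

#' Administrative snapshot of a trial at a calendar time
#'
#' Restricts a dataset to what would be observable at an interim analysis:
#' only patients enrolled before `analysis_time` are included; records whose
#' event or censoring falls after the analysis time are administratively
#' censored at `analysis_time - enroll_time`.
#'
#' @param data A patient-record data frame.
#' @param analysis_time Calendar months from trial start (positive).
#' @return A tibble of the same shape (possibly empty).
#' @export
snapshot <- function(data, analysis_time) {
  if (!is.numeric(analysis_time) || length(analysis_time) != 1L || analysis_time <= 0)
    abort("`analysis_time` must be a single positive calendar time in months.")
  data <- as_trial_frame(data, require_enroll = TRUE)
  keep <- data$enroll_time_months < analysis_time
  out <- data[keep, , drop = FALSE]
  over <- out$enroll_time_months + out$followup_months > analysis_time
  if (any(over)) {
    out$followup_months[over] <- analysis_time - out$enroll_time_months[over]
    out$event[over] <- 0L
  }
  tibble::as_tibble(out)
}

#' Exact mean of the clipped-Poisson accrual
#'
#' `E[max(Poisson(mu), m)]` by direct summation of the Poisson pmf; used to
#' reason about expected enrollment (9 periods of clipped Poisson(10) accrue
#' about 90 patients on average).
#'
#' @param mu Poisson mean.
#' @param min_size Lower clip.
#' @return The exact expectation.
#' @export
expected_group_size <- function(mu, min_size) {
  k <- 0:max(ceiling(mu + 12 * sqrt(mu) + min_size), 50)
  sum(pmax(k, min_size) * stats::dpois(k, mu))
}
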