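#' Interim-analysis plan
#'
#' Fixes the monitoring schedule and decision rule of a K-stage adaptive
#' analysis: calendar analysis times, the historical-control EFS, the EFS
#' horizon, the one-sided significance level, the boundary family, the
#' decision scale, an optional futility floor, and the prior.
#'
#' Two decision scales are supported. On the `"z"` scale (default, the form
#' used for the simulation-study reproduction) the stage statistic
#' \eqn{\hat{z}_k} is compared with the z-scale boundary of the chosen
#' family. On the `"posterior"` scale the posterior probability
#' \eqn{P(EFS \ge EFS_0)} is compared with the probability image
#' \eqn{\Phi(c_k)} of the same boundary — for the `"linear"` family this is
#' exactly the stage threshold \eqn{\beta_k = 1 - \alpha k/K}.
#'
#' @param analysis_times Increasing calendar months (default
#'   `c(18, 24, 30, 36, 42, 48)`: first look at month 18, then every
#'   6 months to 48).
#' @param efs0 Historical-control EFS in (0, 1).
#' @param tau EFS horizon in years (default 2).
#' @param alpha One-sided significance level (default 0.05).
#' @param rule Boundary family passed to [z_boundaries()]; `"linear"`
#'   (default), `"obrien-fleming"`, or `"pocock"` (spec-style long names are
#'   accepted).
#' @param decision_scale `"z"` or `"posterior"`.
#' @param futility_threshold Optional posterior-probability floor
#'   \eqn{\gamma_f}; when set, a stage with
#'   \eqn{P(EFS \ge EFS_0) < \gamma_f} stops for futility. Default `NULL`
#'   (futility monitoring off).
#' @param prior An `efs_prior` (default [jeffreys_prior()]).
#' @return An object of class `interim_plan`.
#' @export
interim_plan <- function(analysis_times = c(18, 24, 30, 36, 42, 48),
                         efs0, tau = 2, alpha = 0.05,
                         rule = "linear",
                         decision_scale = c("z", "posterior"),
                         futility_threshold = NULL,
                         prior = jeffreys_prior()) {
  if (length(analysis_times) < 1 || any(diff(analysis_times) <= 0) ||
      any(analysis_times <= 0))
    abort("`analysis_times` must be positive, strictly increasing calendar months.")
  if (!is.numeric(efs0) || length(efs0) != 1L || efs0 <= 0 || efs0 >= 1)
    abort("`efs0` must lie strictly between 0 and 1.")
  if (tau <= 0) abort("`tau` must be a positive horizon in years.")
  check_k_alpha(length(analysis_times), alpha)
  rule <- normalize_rule(rule)
  decision_scale <- match.arg(decision_scale)
  if (!is.null(futility_threshold) &&
      (futility_threshold <= 0 || futility_threshold >= 1))
    abort("`futility_threshold` must lie strictly between 0 and 1 (or be NULL).")
  if (!inherits(prior, "efs_prior")) abort("`prior` must be an `efs_prior`.")
  K <- length(analysis_times)
  structure(
    list(analysis_times = analysis_times, efs0 = efs0, tau = tau,
         alpha = alpha, rule = rule, decision_scale = decision_scale,
         futility_threshold = futility_threshold, prior = prior,
         K = K,
         z_bounds = z_boundaries(K, alpha, rule),
         prob_thresholds = pnorm(z_boundaries(K, alpha, rule))),
    class = "interim_plan"
  )
}

#' @export
print.interim_plan <- function(x, ...) {
  cat(sprintf("<interim_plan> %d analyses at months %s\n", x$K,
              paste(x$analysis_times, collapse = ", ")))
  cat(sprintf("  EFS0 %.3f at tau = %g yr, one-sided alpha %.3f, rule '%s' (%s scale)\n",
              x$efs0, x$tau, x$alpha, x$rule, x$decision_scale))
  cat("  z boundaries:", paste(sprintf("%.3f", x$z_bounds), collapse = ", "), "\n")
  if (!is.null(x$futility_threshold))
    cat(sprintf("  futility floor: P(EFS >= EFS0) < %.3f\n", x$futility_threshold))
  invisible(x)
}

#' Run the K-stage interim analysis on a trial dataset
#'
#' At each scheduled analysis the dataset is snapshotted at the calendar
#' time, the posterior is updated, the predictive EFS, its posterior SD, the
#' z statistic and the posterior probability of meeting the target are
#' computed, and the stage decision is taken. Stage posteriors are computed
#' both by one-shot update of the plan prior with the cumulative snapshot
#' statistics and by chaining the previous stage's posterior with the
#' increment in sufficient statistics; conjugacy makes the two identical and
#' the function verifies that at every stage.
#'
#' A stage whose snapshot contains no observed events is recorded as not
#' evaluable (`decision = "continue"`, `note = "insufficient data"`): with
#' no events the posterior either is improper (Jeffreys) or is the prior
#' essentially unchanged, and the first analysis is meant to wait for
#' sufficient follow-up.
#'
#' Processing stops after the first efficacy or futility stop; later stages
#' are not evaluated.
#'
#' @param data A patient-record data frame (see [simulate_trial()],
#'   [read_survival_table()]).
#' @param plan An [interim_plan()].
#' @return An object of class `trial_monitor`; `tidy()` gives the per-stage
#'   table, `glance()` the stopping summary, `autoplot()` the z path against
#'   the boundaries.
#' @export
run_trial <- function(data, plan) {
  if (!inherits(plan, "interim_plan")) abort("`plan` must be an `interim_plan`.")
  data <- as_trial_frame(data, require_enroll = TRUE)
  if (nrow(data) == 0) abort("`data` contains no patient records.")

  K <- plan$K
  rows <- vector("list", K)
  prev_post <- plan$prior
  prev_stats <- list(n_events = 0, exposure_years = 0)
  stopped <- FALSE

  for (k in seq_len(K)) {
    tm <- plan$analysis_times[k]
    snap <- snapshot(data, tm)
    st <- if (nrow(snap) > 0) survival_stats(snap) else
      tibble::tibble(n_events = 0L, exposure_years = 0)

    evaluable <- st$n_events >= 1 && st$exposure_years > 0
    if (evaluable) {
      post_pooled <- update_posterior(plan$prior, st)
      inc <- list(n_events = st$n_events - prev_stats$n_events,
                  exposure_years = st$exposure_years - prev_stats$exposure_years)
      post_chained <- update_posterior(prev_post, inc)
      if (abs(post_pooled$shape - post_chained$shape) > 1e-9 ||
          abs(post_pooled$rate - post_chained$rate) > 1e-9)
        abort("Internal error: chained and pooled posteriors disagree.")
      post <- post_pooled
      efs_hat <- predictive_survival(post, plan$tau)
      efs_sd <- predictive_survival_sd(post, plan$tau)
      z <- z_statistic(efs_hat, plan$efs0, efs_sd)
      p_meet <- prob_efs_meets_target(post, plan$efs0, plan$tau)
      efficacy <- switch(plan$decision_scale,
        z = z >= plan$z_bounds[k],
        posterior = p_meet >= plan$prob_thresholds[k])
      futility <- !is.null(plan$futility_threshold) &&
        p_meet < plan$futility_threshold
      decision <- if (efficacy) "stop-efficacy"
                  else if (futility) "stop-futility"
                  else "continue"
      note <- NA_character_
      prev_post <- post
      prev_stats <- as.list(st)
    } else {
      post <- NULL
      efs_hat <- efs_sd <- z <- p_meet <- NA_real_
      decision <- "continue"
      note <- "insufficient data"
      # the prior chain is unchanged; zero-increment update would be improper
    }

    rows[[k]] <- tibble::tibble(
      stage = k, analysis_time = tm,
      n_enrolled = nrow(snap), n_events = st$n_events,
      exposure_years = st$exposure_years,
      shape = if (evaluable) post$shape else NA_real_,
      rate = if (evaluable) post$rate else NA_real_,
      efs_hat = efs_hat, efs_sd = efs_sd, z = z,
      z_boundary = plan$z_bounds[k],
      prob_threshold = plan$prob_thresholds[k],
      prob_meets_target = p_meet,
      decision = decision, note = note
    )
    if (decision != "continue") { stopped <- TRUE; break }
  }

  stages <- dplyr::bind_rows(rows)
  structure(list(stages = stages, plan = plan, stopped = stopped),
            class = "trial_monitor")
}

#' @export
print.trial_monitor <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<trial_monitor> %d stage(s) evaluated; decision: %s%s\n",
              nrow(x$stages), g$final_decision,
              if (!is.na(g$stop_month)) sprintf(" at month %g", g$stop_month) else ""))
  print(x$stages[, c("stage", "analysis_time", "n_enrolled", "n_events",
                     "efs_hat", "z", "z_boundary", "decision")])
  invisible(x)
}

#' Per-stage table of an interim run
#'
#' @param x A `trial_monitor`.
#' @param ... Unused.
#' @return A tibble with one row per evaluated stage: enrollment, events,
#'   posterior shape/rate, EFS estimate and SD, z, boundary, posterior
#'   probability and decision.
#' @method tidy trial_monitor
#' @export
tidy.trial_monitor <- function(x, ...) x$stages

#' One-row summary of an interim run
#'
#' @inheritParams tidy.trial_monitor
#' @return A one-row tibble: final decision, stopping stage and month (NA if
#'   the trial ran to the last look without stopping), and enrollment and
#'   event count at the last evaluated stage.
#' @method glance trial_monitor
#' @export
glance.trial_monitor <- function(x, ...) {
  last <- x$stages[nrow(x$stages), ]
  stopped <- last$decision != "continue"
  tibble::tibble(
    final_decision = last$decision,
    stop_stage = if (stopped) last$stage else NA_integer_,
    stop_month = if (stopped) last$analysis_time else NA_real_,
    n_enrolled = last$n_enrolled,
    n_events = last$n_events,
    efs_hat = last$efs_hat
  )
}

#' Plot the interim z path against its boundaries
#'
#' @param object A `trial_monitor`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trial_monitor
#' @export
autoplot.trial_monitor <- function(object, ...) {
  st <- object$stages
  ggplot2::ggplot(st, ggplot2::aes(x = .data$analysis_time)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$z_boundary, linetype = "boundary")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$z, linetype = "z statistic"),
                       na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$z), na.rm = TRUE) +
    ggplot2::labs(x = "Calendar month", y = "z", linetype = NULL,
                  title = "Interim z path vs efficacy boundary") +
    ggplot2::theme_minimal()
}

#' Distribution of adaptive sample size and stopping time
#'
#' Simulates `reps` trials under `config`, monitors each with `plan`, and
#' summarizes the realized enrollment at stopping and the stopping month.
#' Trials that never cross a boundary contribute their full accrual and a
#' missing stopping month.
#'
#' @param config A [sim_config()].
#' @param plan An [interim_plan()].
#' @param reps Number of simulated trials.
#' @param seed Master seed; replicate `i` uses `seed + i`.
#' @return An object of class `adaptive_n` with elements `draws` (one row
#'   per replicate) and `summary` (means, medians and quartiles).
#' @export
adaptive_sample_size <- function(config, plan, reps = 200, seed = 1) {
  validate_sim_config(config)
  if (reps < 1) abort("`reps` must be at least 1.")
  draws <- purrr::map_dfr(seq_len(reps), function(i) {
    set.seed(seed + i)
    d <- simulate_trial(config)
    res <- glance(run_trial(d, plan))
    tibble::tibble(
      rep = i,
      stop_month = res$stop_month,
      stopped = !is.na(res$stop_month),
      n_at_stop = if (!is.na(res$stop_month)) res$n_enrolled else nrow(d),
      n_full = nrow(d)
    )
  })
  summary <- tibble::tibble(
    reps = reps,
    prop_stopped = mean(draws$stopped),
    mean_n = mean(draws$n_at_stop),
    median_n = median(draws$n_at_stop),
    q25_n = quantile(draws$n_at_stop, 0.25),
    q75_n = quantile(draws$n_at_stop, 0.75),
    median_stop_month = median(draws$stop_month[draws$stopped]),
    mean_stop_month = mean(draws$stop_month[draws$stopped])
  )
  structure(list(draws = draws, summary = summary), class = "adaptive_n")
}

#' @export
print.adaptive_n <- function(x, ...) {
  cat("<adaptive_n> realized enrollment under the adaptive rule\n")
  print(x$summary)
  invisible(x)
}

#' @method tidy adaptive_n
#' @export
tidy.adaptive_n <- function(x, ...) x$draws

#' @method glance adaptive_n
#' @export
glance.adaptive_n <- function(x, ...) x$summary
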