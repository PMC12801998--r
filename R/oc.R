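#' Single-look posterior-probability test
#'
#' Rejects (returns 1) when the posterior probability that the predictive
#' EFS meets the historical control reaches `decision_prob`:
#' \eqn{P(\hat{EFS} \ge EFS_0 \mid data) \ge 0.95} by default. A dataset
#' with no events under a Jeffreys prior leaves the posterior improper; the
#' test then returns 0 (no rejection) with a warning.
#'
#' @param data A patient-record data frame.
#' @param prior An `efs_prior`.
#' @param efs0 Historical-control EFS in (0, 1).
#' @param tau EFS horizon in years.
#' @param decision_prob Posterior-probability cutoff (default 0.95).
#' @return Integer 0 or 1.
#' @export
single_look_test <- function(data, prior, efs0, tau = 2, decision_prob = 0.95) {
  stats <- survival_stats(data)
  r <- single_look_from_stats(stats$n_events, stats$exposure_years,
                              prior, efs0, tau, decision_prob)
  if (is.na(r)) {
    warn("Improper posterior (no events under a Jeffreys prior); treating as no rejection.")
    return(0L)
  }
  r
}

# Hot path shared by the sweeps: NA marks an improper posterior.
single_look_from_stats <- function(n_events, exposure_years, prior, efs0, tau,
                                   decision_prob) {
  shape <- prior$shape + n_events
  rate <- prior$rate + exposure_years
  if (shape <= 0 || rate <= 0) return(NA_integer_)
  p <- pgamma(-log(efs0) / tau, shape = shape, rate = rate)
  as.integer(p >= decision_prob)
}

#' Empirical type-I error of the single-look test
#'
#' Monte-Carlo rejection rates of [single_look_test()] across a sample-size
#' grid, for data generated under a null scenario (`config` should describe
#' hazards at or above the null boundary). See [oc_sweep()] for mechanics.
#'
#' @inheritParams oc_sweep
#' @return An `oc_result`; see [tidy.oc_result()].
#' @export
empirical_type1 <- function(config, priors, efs0, n_grid = seq(80, 225, by = 5),
                            reps = 1000, tau = 2, decision_prob = 0.95, seed = 1) {
  oc_sweep(config, priors, efs0, n_grid, reps, tau, decision_prob, seed,
           metric = "type1")
}

#' Empirical power of the single-look test
#'
#' Same sweep as [empirical_type1()] under an alternative scenario; the
#' result additionally carries, per prior, the smallest grid `n` whose
#' rejection rate reaches `power_target`.
#'
#' @inheritParams oc_sweep
#' @param power_target Target power for the minimal-n summary (default 0.80).
#' @return An `oc_result`.
#' @export
empirical_power <- function(config, priors, efs0, n_grid = seq(80, 225, by = 5),
                            reps = 1000, tau = 2, decision_prob = 0.95, seed = 1,
                            power_target = 0.80) {
  oc_sweep(config, priors, efs0, n_grid, reps, tau, decision_prob, seed,
           metric = "power", power_target = power_target)
}

#' Monte-Carlo sweep of the single-look test over sample sizes
#'
#' For each replicate `i` the RNG is seeded with `seed + i`; one stream then
#' generates a dataset for every `n` in increasing order (equal group sizes,
#' `fixed_group_size = round(n / n_groups)`), and every prior is evaluated
#' on the same dataset — common random numbers across priors and across `n`
#' within a replicate, which stabilizes ordering comparisons. Improper
#' posteriors (Jeffreys with zero events) count as non-rejections.
#'
#' @param config A [sim_config()] scenario; its `fixed_group_size` is
#'   overridden by the sweep.
#' @param priors Named list of `efs_prior` objects.
#' @param efs0 Historical-control EFS.
#' @param n_grid Nominal total sample sizes to sweep.
#' @param reps Monte-Carlo replicates per `n` (default 1000).
#' @param tau EFS horizon in years.
#' @param decision_prob Posterior-probability cutoff.
#' @param seed Master seed.
#' @param metric Label stored on the result (`"power"` or `"type1"`).
#' @param power_target Target rate for the minimal-n summary.
#' @return An `oc_result` object: a tibble of rates (one row per prior and
#'   `n`, with Monte-Carlo SE and mean realized enrollment) plus a
#'   `minimal_n` attribute table.
#' @export
oc_sweep <- function(config, priors, efs0, n_grid = seq(80, 225, by = 5),
                     reps = 1000, tau = 2, decision_prob = 0.95, seed = 1,
                     metric = c("power", "type1"), power_target = 0.80) {
  validate_sim_config(config)
  metric <- match.arg(metric)
  if (!is.list(priors) || is.null(names(priors)) || any(names(priors) == ""))
    abort("`priors` must be a named list of `efs_prior` objects.")
  purrr::walk(priors, function(p)
    if (!inherits(p, "efs_prior")) abort("Every element of `priors` must be an `efs_prior`."))
  n_grid <- sort(unique(as.integer(n_grid)))
  P <- length(priors); N <- length(n_grid)

  rej <- array(0L, dim = c(P, N))
  realized <- numeric(N)
  for (i in seq_len(reps)) {
    set.seed(seed + i)
    for (jn in seq_len(N)) {
      cfg_n <- config
      cfg_n$fixed_group_size <- max(1L, as.integer(round(n_grid[jn] / config$n_groups)))
      cfg_n$seed <- NULL
      d <- simulate_trial(cfg_n)
      st <- survival_stats(d)
      realized[jn] <- realized[jn] + nrow(d)
      for (jp in seq_len(P)) {
        r <- single_look_from_stats(st$n_events, st$exposure_years,
                                    priors[[jp]], efs0, tau, decision_prob)
        if (!is.na(r) && r == 1L) rej[jp, jn] <- rej[jp, jn] + 1L
      }
    }
  }

  rate <- as.vector(t(rej)) / reps
  out <- tidyr::expand_grid(prior = names(priors), n = n_grid) |>
    dplyr::mutate(
      rate = rate,
      se = sqrt(rate * (1 - rate) / .env$reps),
      reps = .env$reps,
      n_realized = rep(realized / .env$reps, times = P),
      metric = .env$metric
    )
  min_n <- out |>
    dplyr::group_by(.data$prior) |>
    dplyr::summarise(
      minimal_n = if (any(.data$rate >= power_target))
        min(.data$n[.data$rate >= power_target]) else NA_integer_,
      .groups = "drop"
    )
  structure(
    list(rates = out, minimal_n = min_n, metric = metric,
         power_target = power_target, efs0 = efs0, tau = tau,
         decision_prob = decision_prob, seed = seed),
    class = "oc_result"
  )
}

#' @export
print.oc_result <- function(x, ...) {
  cat(sprintf("<oc_result> %s sweep: %d priors x %d sample sizes, %d reps\n",
              x$metric, length(unique(x$rates$prior)),
              length(unique(x$rates$n)), unique(x$rates$reps)))
  if (x$metric == "power") {
    cat(sprintf("  minimal n for %.0f%% power:\n", 100 * x$power_target))
    print(x$minimal_n)
  } else {
    worst <- x$rates |> dplyr::group_by(.data$prior) |>
      dplyr::summarise(max_rate = max(.data$rate), .groups = "drop")
    print(worst)
  }
  invisible(x)
}

#' Rates table of an operating-characteristics sweep
#'
#' @param x An `oc_result`.
#' @param ... Unused.
#' @return A tibble with one row per prior and sample size: rejection
#'   `rate`, Monte-Carlo `se`, `reps`, and mean realized enrollment
#'   `n_realized` (group sizes are rounded, so the realized total can differ
#'   from nominal `n`).
#' @method tidy oc_result
#' @export
tidy.oc_result <- function(x, ...) x$rates

#' Minimal-n summary of a sweep
#'
#' @inheritParams tidy.oc_result
#' @return One row per prior with the smallest grid `n` reaching the target
#'   rate (power sweeps), or the maximum rate over the grid (type-I sweeps).
#' @method glance oc_result
#' @export
glance.oc_result <- function(x, ...) {
  if (x$metric == "power") return(x$minimal_n)
  x$rates |>
    dplyr::group_by(.data$prior) |>
    dplyr::summarise(max_rate = max(.data$rate), .groups = "drop")
}

#' Plot an operating-characteristics sweep
#'
#' Rejection rate against nominal sample size, one line per prior, with the
#' nominal 5\% line (type-I sweeps) or the power target (power sweeps).
#'
#' @param object An `oc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oc_result
#' @export
autoplot.oc_result <- function(object, ...) {
  ref <- if (object$metric == "type1") 1 - object$decision_prob else object$power_target
  ggplot2::ggplot(object$rates,
                  ggplot2::aes(x = .data$n, y = .data$rate, colour = .data$prior)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = ref, linetype = 2) +
    ggplot2::labs(x = "Nominal sample size", colour = "Prior",
                  y = if (object$metric == "type1") "Empirical type I error"
                      else "Empirical power") +
    ggplot2::theme_minimal()
}

#' Operating characteristics of the K-stage interim design
#'
#' Simulates `reps` trials under `config` and monitors each with `plan`
#' under every prior in `priors` (common random numbers: all priors see the
#' same datasets). Reports the median z per stage and the distribution of
#' the first efficacy-stop month per prior.
#'
#' @inheritParams oc_sweep
#' @param plan An [interim_plan()]; its prior is replaced by each element of
#'   `priors` in turn.
#' @return An `interim_oc` object with elements `stage_z` (median z per
#'   stage and prior), `stops` (per replicate and prior: first-stop month,
#'   `Inf` when no boundary is crossed), and `summary` (per prior: median
#'   stop month, proportion stopping).
#' @export
interim_oc <- function(config, priors, plan, reps = 1000, seed = 1) {
  validate_sim_config(config)
  if (!inherits(plan, "interim_plan")) abort("`plan` must be an `interim_plan`.")
  if (!is.list(priors) || is.null(names(priors)) || any(names(priors) == ""))
    abort("`priors` must be a named list of `efs_prior` objects.")
  P <- length(priors); K <- plan$K
  plans <- purrr::map(priors, function(p) { pl <- plan; pl$prior <- p; pl })

  z_store <- array(NA_real_, dim = c(reps, K, P))
  stop_month <- matrix(Inf, nrow = reps, ncol = P,
                       dimnames = list(NULL, names(priors)))
  for (i in seq_len(reps)) {
    set.seed(seed + i)
    d <- simulate_trial(config)
    for (jp in seq_len(P)) {
      res <- run_trial_zpath(d, plans[[jp]])
      z_store[i, , jp] <- res$z
      stop_month[i, jp] <- res$stop
    }
  }

  stage_z <- tidyr::expand_grid(prior = names(priors), stage = seq_len(K)) |>
    dplyr::mutate(
      analysis_time = plan$analysis_times[.data$stage],
      median_z = purrr::map2_dbl(.data$prior, .data$stage, function(pr, k)
        median(z_store[, k, match(pr, names(priors))], na.rm = TRUE)),
      z_boundary = plan$z_bounds[.data$stage]
    )
  stops <- tidyr::expand_grid(rep = seq_len(reps), prior = names(priors)) |>
    dplyr::mutate(stop_month = purrr::map2_dbl(.data$rep, .data$prior,
      function(i, pr) stop_month[i, pr]))
  summary <- stops |>
    dplyr::group_by(.data$prior) |>
    dplyr::summarise(
      prop_stopped = mean(is.finite(.data$stop_month)),
      median_stop_month = {
        m <- median(.data$stop_month)
        if (is.finite(m)) m else NA_real_
      },
      .groups = "drop"
    )
  structure(list(stage_z = stage_z, stops = stops, summary = summary,
                 plan = plan, reps = reps, seed = seed),
            class = "interim_oc")
}

# Lean interim pass used by interim_oc: full-stage z path (no early exit for
# the path itself) plus the first boundary-crossing month.
run_trial_zpath <- function(data, plan) {
  K <- plan$K
  z <- rep(NA_real_, K)
  stop_at <- Inf
  for (k in seq_len(K)) {
    snap <- snapshot(data, plan$analysis_times[k])
    nev <- sum(snap$event)
    ex <- sum(snap$followup_months) / 12
    shape <- plan$prior$shape + nev
    rate <- plan$prior$rate + ex
    if (nev < 1 || shape <= 0 || rate <= 0) next
    efs <- (rate / (rate + plan$tau))^shape
    v <- (rate / (rate + 2 * plan$tau))^shape - efs^2
    z[k] <- (efs - plan$efs0) / sqrt(v)
    crossed <- switch(plan$decision_scale,
      z = z[k] >= plan$z_bounds[k],
      posterior = pgamma(-log(plan$efs0) / plan$tau, shape, rate = rate) >=
        plan$prob_thresholds[k])
    if (is.infinite(stop_at) && crossed) stop_at <- plan$analysis_times[k]
  }
  list(z = z, stop = stop_at)
}

#' @export
print.interim_oc <- function(x, ...) {
  cat(sprintf("<interim_oc> %d replicates, %d stages\n", x$reps, x$plan$K))
  print(x$summary)
  invisible(x)
}

#' Per-stage median z of an interim operating-characteristics run
#'
#' @param x An `interim_oc`.
#' @param ... Unused.
#' @return A tibble: prior, stage, analysis month, median z, boundary.
#' @method tidy interim_oc
#' @export
tidy.interim_oc <- function(x, ...) x$stage_z

#' Stopping summary of an interim operating-characteristics run
#'
#' @inheritParams tidy.interim_oc
#' @return One row per prior: proportion of replicates stopping for
#'   efficacy and the median first-stop month (NA when fewer than half the
#'   replicates stop).
#' @method glance interim_oc
#' @export
glance.interim_oc <- function(x, ...) x$summary

#' Plot median interim z paths against the boundary
#'
#' @param object An `interim_oc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot interim_oc
#' @export
autoplot.interim_oc <- function(object, ...) {
  ggplot2::ggplot(object$stage_z,
                  ggplot2::aes(x = .data$analysis_time)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$z_boundary, linetype = "boundary")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median_z, colour = .data$prior),
                       na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median_z, colour = .data$prior),
                        na.rm = TRUE) +
    ggplot2::labs(x = "Calendar month", y = "Median z across replicates",
                  colour = "Prior", linetype = NULL) +
    ggplot2::theme_minimal()
}
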