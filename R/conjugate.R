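#' Sufficient statistics of the exponential survival model
#'
#' The exponential likelihood
#' \eqn{\prod_i f(t_i|\lambda)^{\delta_i} S(t_i|\lambda)^{1-\delta_i}}
#' depends on the data only through the event count \eqn{\sum_i \delta_i}
#' and the total exposure \eqn{\sum_i t_i}. Follow-up is recorded in months
#' and converted to years here, the single point where units change.
#'
#' @param data A data frame of patient records with columns
#'   `followup_months` (positive) and `event` (0/1). Extra columns
#'   (e.g. `patient_id`, `enroll_time_months`) are ignored.
#' @param months_per_year Months-to-years conversion constant (default 12).
#' @return A one-row tibble with `n_events` and `exposure_years`.
#' @examples
#' d <- tibble::tibble(followup_months = c(12, 24), event = c(1L, 0L))
#' survival_stats(d) # 1 event, 3 exposure-years
#' @export
survival_stats <- function(data, months_per_year = 12) {
  data <- as_trial_frame(data, require_enroll = FALSE)
  tibble::tibble(
    n_events = sum(data$event),
    exposure_years = sum(data$followup_months) / months_per_year
  )
}

# Validate patient-record columns shared by several entry points.
as_trial_frame <- function(data, require_enroll = TRUE) {
  if (!is.data.frame(data)) abort("`data` must be a data frame of patient records.")
  needed <- c(if (require_enroll) "enroll_time_months", "followup_months", "event")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0)
    abort(paste0("`data` is missing column(s): ", paste(missing_cols, collapse = ", "), "."))
  if (nrow(data) == 0) return(data)
  if (any(!is.finite(data$followup_months)) || any(data$followup_months <= 0))
    abort("`followup_months` must be positive and finite for every record.")
  if (!all(data$event %in% c(0, 1)))
    abort("`event` must be 0 (censored) or 1 (event observed) for every record.")
  if (require_enroll && (any(!is.finite(data$enroll_time_months)) ||
                         any(data$enroll_time_months < 0)))
    abort("`enroll_time_months` must be nonnegative and finite.")
  data$event <- as.integer(data$event)
  data
}

#' Conjugate posterior update
#'
#' With an exponential likelihood and a Gamma(shape, rate) prior, the
#' posterior is Gamma(shape + events, rate + exposure). A Jeffreys prior
#' needs at least one event and positive exposure before the posterior is
#' proper.
#'
#' @param prior An `efs_prior` object.
#' @param stats A one-row data frame with `n_events` and `exposure_years`
#'   (as returned by [survival_stats()]).
#' @return The posterior as an `efs_prior` object (always proper).
#' @examples
#' update_posterior(gamma_prior(1, 1),
#'                  tibble::tibble(n_events = 3, exposure_years = 20))
#' @export
update_posterior <- function(prior, stats) {
  if (!inherits(prior, "efs_prior"))
    abort("`prior` must be an `efs_prior` object.")
  stats <- check_stats(stats)
  shape <- prior$shape + stats$n_events
  rate <- prior$rate + stats$exposure_years
  if (shape <= 0 || rate <= 0)
    abort(paste0("The posterior is improper: a Jeffreys prior needs at least one ",
                 "observed event and positive exposure. Wait for more data."))
  new_efs_prior(shape, rate, improper = FALSE)
}

check_stats <- function(stats) {
  if (is.data.frame(stats)) {
    if (nrow(stats) != 1L) abort("`stats` must have exactly one row.")
    stats <- as.list(stats)
  }
  if (!is.list(stats) || !all(c("n_events", "exposure_years") %in% names(stats)))
    abort("`stats` must contain `n_events` and `exposure_years`.")
  if (stats$n_events < 0 || stats$exposure_years < 0)
    abort("Sufficient statistics must be nonnegative.")
  if (stats$exposure_years == 0 && stats$n_events > 0)
    abort("Zero exposure with positive events is not a valid statistic.")
  stats
}

#' Posterior from patient records in one step
#'
#' Convenience composition of [survival_stats()] and [update_posterior()].
#'
#' @inheritParams survival_stats
#' @inheritParams update_posterior
#' @return The posterior as an `efs_prior` object.
#' @export
posterior_from_data <- function(data, prior, months_per_year = 12) {
  update_posterior(prior, survival_stats(data, months_per_year))
}

#' Posterior-predictive event-free survival
#'
#' The probability that a future patient is event-free at `horizon` years,
#' averaging the exponential survival function over the Gamma posterior.
#' The Gamma mixture has the closed form
#' \deqn{\hat{EFS}(\tau) = E[e^{-\tau\lambda}] = (rate/(rate+\tau))^{shape}.}
#'
#' @param p A proper `efs_prior` (posterior).
#' @param horizon Horizon \eqn{\tau} in years (e.g. 2 for 2-year EFS).
#' @return A probability in (0, 1].
#' @export
predictive_survival <- function(p, horizon) {
  check_proper(p, "predictive survival")
  if (!is.numeric(horizon) || length(horizon) != 1L || !is.finite(horizon) || horizon < 0)
    abort("`horizon` must be a single nonnegative number of years.")
  (p$rate / (p$rate + horizon))^p$shape
}

#' Posterior standard deviation of event-free survival
#'
#' The posterior SD of \eqn{e^{-\tau\lambda}}, available exactly through the
#' Gamma Laplace transform:
#' \deqn{Var = (rate/(rate+2\tau))^{shape} - (rate/(rate+\tau))^{2\,shape}.}
#' This is the \eqn{\hat{\sigma}(EFS)} used by the interim z statistic.
#'
#' @inheritParams predictive_survival
#' @return A nonnegative standard deviation on the probability scale.
#' @export
predictive_survival_sd <- function(p, horizon) {
  check_proper(p, "the predictive-survival SD")
  if (!is.numeric(horizon) || length(horizon) != 1L || !is.finite(horizon) || horizon < 0)
    abort("`horizon` must be a single nonnegative number of years.")
  second <- (p$rate / (p$rate + 2 * horizon))^p$shape
  first <- (p$rate / (p$rate + horizon))^p$shape
  sqrt(max(second - first^2, 0))
}

#' Posterior tail probability of the hazard
#'
#' \eqn{P(\lambda \ge r \mid data)} (direction `"at-or-above"`) or its
#' complement (`"below"`), from the Gamma posterior CDF.
#'
#' @inheritParams predictive_survival
#' @param r Hazard threshold, per year (nonnegative).
#' @param direction `"at-or-above"` or `"below"`.
#' @return A probability.
#' @export
posterior_tail_prob <- function(p, r, direction = c("at-or-above", "below")) {
  check_proper(p, "a tail probability")
  direction <- match.arg(direction)
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0)
    abort("`r` must be a single nonnegative hazard (per year).")
  upper <- pgamma(r, shape = p$shape, rate = p$rate, lower.tail = FALSE)
  if (direction == "at-or-above") upper else 1 - upper
}

#' Posterior probability that EFS meets the historical-control target
#'
#' The event \eqn{\{e^{-\tau\lambda} \ge EFS_0\}} equals
#' \eqn{\{\lambda \le -\log(EFS_0)/\tau\}}, so this is a Gamma CDF
#' evaluation at the null-boundary hazard.
#'
#' @inheritParams predictive_survival
#' @param efs0 Historical-control EFS in (0, 1).
#' @return \eqn{P(EFS(\tau) \ge EFS_0 \mid data)}.
#' @export
prob_efs_meets_target <- function(p, efs0, horizon) {
  check_proper(p, "the target probability")
  if (!is.numeric(efs0) || length(efs0) != 1L || efs0 <= 0 || efs0 >= 1)
    abort("`efs0` must lie strictly between 0 and 1.")
  if (!is.numeric(horizon) || length(horizon) != 1L || !is.finite(horizon) || horizon <= 0)
    abort("`horizon` must be a single positive number of years.")
  posterior_tail_prob(p, -log(efs0) / horizon, direction = "below")
}

#' Single-look Bayesian analysis of a trial dataset
#'
#' Fits the conjugate model to the full dataset and summarizes the posterior:
#' hazard mean/SD, predictive EFS at the horizon with its posterior SD, the
#' posterior probability that EFS meets the historical control, and one-sided
#' plus central credible intervals for the hazard and for EFS.
#'
#' @param data A data frame of patient records (see [survival_stats()]).
#' @param prior An `efs_prior`.
#' @param efs0 Historical-control EFS in (0, 1).
#' @param tau EFS horizon in years (default 2).
#' @param conf Credible level (default 0.95).
#' @return An object of class `efs_fit`; see [tidy.efs_fit()].
#' @examples
#' d <- tibble::tibble(followup_months = rep(24, 50), event = rep(0:1, c(48, 2)))
#' fit <- analyze_trial(d, gamma_prior_mean_sd(0.025, 0.01), efs0 = 0.92)
#' tidy(fit)
#' @export
analyze_trial <- function(data, prior, efs0, tau = 2, conf = 0.95) {
  stats <- survival_stats(data)
  post <- update_posterior(prior, stats)
  mv <- posterior_mean_var(post)
  alpha <- 1 - conf
  # one-sided (r, Inf) region with posterior mass `conf`, plus a central interval
  lambda_lower_1s <- qgamma(alpha, post$shape, rate = post$rate)
  lambda_ci <- qgamma(c(alpha / 2, 1 - alpha / 2), post$shape, rate = post$rate)
  structure(
    list(
      prior = prior, posterior = post, stats = stats,
      efs0 = efs0, tau = tau, conf = conf,
      hazard_mean = mv$mean, hazard_sd = mv$sd,
      efs_hat = predictive_survival(post, tau),
      efs_sd = predictive_survival_sd(post, tau),
      prob_meets_target = prob_efs_meets_target(post, efs0, tau),
      lambda_one_sided_lower = lambda_lower_1s,
      lambda_central = lambda_ci,
      efs_central = rev(exp(-tau * lambda_ci))
    ),
    class = "efs_fit"
  )
}

#' @export
print.efs_fit <- function(x, ...) {
  cat(sprintf("<efs_fit> %d events over %.1f patient-years\n",
              x$stats$n_events, x$stats$exposure_years))
  cat(sprintf("  posterior Gamma(%.4g, %.4g /yr); hazard %.4g /yr (sd %.4g)\n",
              x$posterior$shape, x$posterior$rate, x$hazard_mean, x$hazard_sd))
  cat(sprintf("  %g-year EFS %.4f (posterior sd %.4f)\n", x$tau, x$efs_hat, x$efs_sd))
  cat(sprintf("  P(EFS >= %.3f) = %.4f\n", x$efs0, x$prob_meets_target))
  invisible(x)
}

#' Tidy a single-look fit
#'
#' @param x An `efs_fit` object.
#' @param ... Unused.
#' @return A one-row tibble of posterior summaries.
#' @method tidy efs_fit
#' @export
tidy.efs_fit <- function(x, ...) {
  tibble::tibble(
    n_events = x$stats$n_events,
    exposure_years = x$stats$exposure_years,
    shape = x$posterior$shape,
    rate = x$posterior$rate,
    hazard_mean = x$hazard_mean,
    hazard_sd = x$hazard_sd,
    efs_hat = x$efs_hat,
    efs_sd = x$efs_sd,
    prob_meets_target = x$prob_meets_target,
    efs_ci_lower = x$efs_central[1],
    efs_ci_upper = x$efs_central[2]
  )
}

#' Glance at a single-look fit
#'
#' @inheritParams tidy.efs_fit
#' @return A one-row tibble: the decision-relevant summary.
#' @method glance efs_fit
#' @export
glance.efs_fit <- function(x, ...) {
  tibble::tibble(
    efs_hat = x$efs_hat,
    efs0 = x$efs0,
    tau = x$tau,
    prob_meets_target = x$prob_meets_target,
    conf = x$conf
  )
}
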