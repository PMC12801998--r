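#' Stage-wise posterior-probability thresholds
#'
#' The linear stage criterion: at analysis \eqn{k} of \eqn{K} the trial
#' stops for efficacy when the posterior probability of meeting the target
#' reaches \eqn{\beta_k = 1 - \alpha k / K}. The thresholds relax linearly
#' from near 1 down to \eqn{1 - \alpha} at the final look.
#'
#' @param K Number of analyses (at least 1).
#' @param alpha One-sided significance level in (0, 1).
#' @return Numeric vector of length `K`, strictly decreasing.
#' @examples
#' linear_posterior_thresholds(6, 0.05)
#' @export
linear_posterior_thresholds <- function(K, alpha) {
  check_k_alpha(K, alpha)
  1 - alpha * seq_len(K) / K
}

check_k_alpha <- function(K, alpha) {
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K))
    abort("`K` must be a positive integer number of analyses.")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    abort("`alpha` must lie strictly between 0 and 1.")
  invisible(TRUE)
}

#' One-sided z-scale efficacy boundaries
#'
#' Critical values for the standardized stage statistic at equally spaced
#' information fractions \eqn{k/K}. Three families are available:
#'
#' * `"linear"`: the normal-quantile image of the linear posterior
#'   thresholds, \eqn{c_k = \Phi^{-1}(1 - \alpha k/K)}. This is the package
#'   default for reproducing the simulation study.
#' * `"obrien-fleming"`: error-spending boundaries with the
#'   O'Brien-Fleming-type spending function
#'   \eqn{f(t) = 2\{1 - \Phi(z_{\alpha/2}/\sqrt{t})\}}.
#' * `"pocock"`: error-spending boundaries with the Pocock-type spending
#'   function \eqn{f(t) = \alpha \log\{1 + (e - 1)t\}}.
#'
#' Spending boundaries are computed by the standard recursion for the joint
#' normal law of the sequential statistic (independent Brownian increments),
#' integrating the continuation sub-density on a fine grid so that exactly
#' \eqn{f(t_k) - f(t_{k-1})} type-I probability is spent at look \eqn{k};
#' the total spend across all `K` looks is `alpha`. Note the two spending
#' families control the *overall* crossing probability at `alpha`, whereas
#' the linear family fixes each stage's nominal level at \eqn{\alpha k / K}.
#'
#' @inheritParams linear_posterior_thresholds
#' @param rule Boundary family: `"linear"`, `"obrien-fleming"`, `"pocock"`.
#' @return Numeric vector of `K` one-sided z-scale critical values.
#' @examples
#' z_boundaries(6, 0.05) # linear stage thresholds
#' z_boundaries(6, 0.05, rule = "obrien-fleming")
#' @export
z_boundaries <- function(K, alpha, rule = c("linear", "obrien-fleming", "pocock")) {
  check_k_alpha(K, alpha)
  rule <- normalize_rule(rule)
  if (rule == "linear") return(qnorm(1 - alpha * seq_len(K) / K))
  spend <- switch(rule,
    "obrien-fleming" = function(t) 2 * pnorm(qnorm(1 - alpha / 2) / sqrt(t), lower.tail = FALSE),
    "pocock" = function(t) alpha * log(1 + (exp(1) - 1) * t)
  )
  spending_boundaries(K, spend)
}

normalize_rule <- function(rule) {
  if (length(rule) > 1) rule <- rule[1]
  canon <- c(
    "linear" = "linear",
    "linear-posterior-threshold" = "linear",
    "obrien-fleming" = "obrien-fleming",
    "obrien-fleming-spending" = "obrien-fleming",
    "pocock" = "pocock",
    "pocock-spending" = "pocock"
  )
  if (!rule %in% names(canon))
    abort(paste0("Unknown boundary rule '", rule, "'. Supported: ",
                 paste(unique(names(canon)), collapse = ", "), "."))
  unname(canon[rule])
}

# Error-spending critical values via recursive sub-density integration.
# Works on the Brownian (score) scale B_k = Z_k * sqrt(t_k), t_k = k/K, with
# independent increments of variance 1/K. psi holds the continuation
# sub-density of B_{k-1} on a trapezoid grid.
spending_boundaries <- function(K, spend, grid_pts = 4001L, lower_sd = 8.5) {
  t_k <- seq_len(K) / K
  pi_k <- diff(c(0, spend(t_k)))
  pi_k <- pmax(pi_k, 0) # guard tiny negative spends from rounding
  crit <- numeric(K)

  crit[1] <- qnorm(pi_k[1], lower.tail = FALSE)
  if (K == 1L) return(crit)

  # stage-1 continuation sub-density of B_1 ~ N(0, t_1) below crit*sqrt(t_1)
  b_hi <- crit[1] * sqrt(t_k[1])
  grid <- seq(-lower_sd * sqrt(t_k[1]), b_hi, length.out = grid_pts)
  psi <- dnorm(grid, sd = sqrt(t_k[1]))

  for (k in 2:K) {
    sd_inc <- sqrt(t_k[k] - t_k[k - 1])
    h <- grid[2] - grid[1]
    w <- trapezoid_weights(length(grid), h)
    # tail probability of crossing at look k as a function of the z-scale cut
    tail_at <- function(z) {
      sum(w * psi * pnorm((z * sqrt(t_k[k]) - grid) / sd_inc, lower.tail = FALSE))
    }
    crit[k] <- uniroot(function(z) tail_at(z) - pi_k[k],
                       lower = -lower_sd, upper = lower_sd, tol = 1e-10)$root
    if (k < K) {
      b_hi_new <- crit[k] * sqrt(t_k[k])
      grid_new <- seq(-lower_sd * sqrt(t_k[k]), b_hi_new, length.out = grid_pts)
      psi <- vapply(grid_new, function(b) {
        sum(w * psi * dnorm(b - grid, sd = sd_inc))
      }, numeric(1))
      grid <- grid_new
    }
  }
  crit
}

trapezoid_weights <- function(n, h) {
  w <- rep(h, n)
  w[c(1, n)] <- h / 2
  w
}

#' Interim z statistic against the historical control
#'
#' \eqn{\hat{z}_k = (\hat{EFS}_k - EFS_0) / \hat{\sigma}(EFS_k)}, where
#' \eqn{\hat{\sigma}} is the posterior SD of EFS.
#'
#' @param efs_hat Predictive EFS at the horizon.
#' @param efs0 Historical-control EFS.
#' @param efs_sd Posterior SD of EFS (positive).
#' @return The standardized statistic.
#' @export
z_statistic <- function(efs_hat, efs0, efs_sd) {
  if (!is.numeric(efs_sd) || any(efs_sd <= 0))
    abort("`efs_sd` must be positive (degenerate posterior).")
  (efs_hat - efs0) / efs_sd
}
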