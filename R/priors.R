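#' Gamma prior (or posterior) for the event hazard
#'
#' The hazard \eqn{\lambda} of the exponential survival model carries a
#' conjugate Gamma prior, rate-parameterized: density proportional to
#' \eqn{\lambda^{shape-1} e^{-rate\,\lambda}}. `rate` has units of exposure
#' time in years, so the prior acts like `shape` pseudo-events observed over
#' `rate` pseudo-years.
#'
#' @param shape Positive shape parameter (pseudo-event count).
#' @param rate Positive rate parameter (pseudo-exposure, years).
#' @return An object of class `efs_prior`.
#' @seealso [gamma_prior_mean_sd()], [jeffreys_prior()], [update_posterior()]
#' @examples
#' gamma_prior(6.25, 250)
#' @export
gamma_prior <- function(shape, rate) {
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) || shape <= 0)
    abort("`shape` must be a single positive number.")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    abort("`rate` must be a single positive number.")
  new_efs_prior(shape, rate, improper = FALSE)
}

#' Gamma prior from a hazard mean and standard deviation
#'
#' Trial priors are usually elicited as a plausible hazard (per year) plus an
#' uncertainty, not as shape/rate. Moment matching gives
#' `shape = (mean/sd)^2`, `rate = mean/sd^2`, so the returned prior has
#' exactly the requested mean and variance.
#'
#' @param mean Prior mean hazard, per year.
#' @param sd Prior standard deviation of the hazard, per year.
#' @return An object of class `efs_prior`.
#' @examples
#' gamma_prior_mean_sd(0.025, 0.01) # shape 6.25, rate 250
#' @export
gamma_prior_mean_sd <- function(mean, sd) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0)
    abort("`mean` must be a single positive number (hazard per year).")
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    abort("`sd` must be a single positive number (hazard per year).")
  gamma_prior(shape = (mean / sd)^2, rate = mean / sd^2)
}

#' Jeffreys (non-informative) prior for the hazard
#'
#' The Jeffreys prior for the exponential hazard, \eqn{\pi(\lambda) \propto
#' 1/\lambda}, is the improper Gamma(0, 0) limit. The posterior is proper as
#' soon as at least one event and positive exposure have been observed.
#'
#' @return An object of class `efs_prior` with `improper = TRUE`.
#' @export
jeffreys_prior <- function() {
  new_efs_prior(0, 0, improper = TRUE)
}

new_efs_prior <- function(shape, rate, improper) {
  structure(
    list(shape = as.numeric(shape), rate = as.numeric(rate),
         improper = isTRUE(improper)),
    class = "efs_prior"
  )
}

is_improper <- function(p) isTRUE(p$improper) || p$shape <= 0 || p$rate <= 0

check_proper <- function(p, what = "this quantity") {
  if (!inherits(p, "efs_prior"))
    abort("Expected an `efs_prior` object (see `gamma_prior()`).")
  if (is_improper(p))
    abort(paste0("The Gamma parameters are improper (Jeffreys, no events yet); ",
                 what, " requires a proper posterior. Update with data first."))
  invisible(p)
}

#' @export
print.efs_prior <- function(x, ...) {
  if (is_improper(x)) {
    cat("<efs_prior> Jeffreys (improper), pi(lambda) ~ 1/lambda\n")
  } else {
    mv <- posterior_mean_var(x)
    cat(sprintf(
      "<efs_prior> Gamma(shape = %g, rate = %g /yr)\n  hazard mean %.5g /yr, sd %.5g /yr\n",
      x$shape, x$rate, mv$mean, sqrt(mv$variance)))
  }
  invisible(x)
}

#' Posterior (or prior) mean and variance of the hazard
#'
#' For a proper Gamma(shape, rate), the hazard mean is `shape/rate` and the
#' variance `shape/rate^2` (per year and per year squared).
#'
#' @param p An `efs_prior` object (prior or posterior).
#' @return A one-row tibble with columns `mean`, `variance`, `sd`.
#' @export
posterior_mean_var <- function(p) {
  check_proper(p, "the posterior mean/variance")
  tibble::tibble(mean = p$shape / p$rate,
                 variance = p$shape / p$rate^2,
                 sd = sqrt(p$shape) / p$rate)
}
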