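test_that("sufficient statistics reduce records to events and exposure-years", {
  d <- make_records(c(12, 24), c(1, 0))
  expect_equal(survival_stats(d),
               tibble::tibble(n_events = 1L, exposure_years = 3))

  empty <- make_records(numeric(0), integer(0))
  expect_equal(survival_stats(empty)$n_events, 0L)
  expect_equal(survival_stats(empty)$exposure_years, 0)

  many <- make_records(rep(6, 100), rep(1, 100))
  expect_equal(survival_stats(many),
               tibble::tibble(n_events = 100L, exposure_years = 50))

  expect_error(survival_stats(make_records(c(5, -1), c(0, 0))), "positive")
})

test_that("conjugate update adds events to shape and exposure to rate", {
  post <- update_posterior(gamma_prior(1, 1),
                           tibble::tibble(n_events = 3, exposure_years = 20))
  expect_equal(post$shape, 4)
  expect_equal(post$rate, 21)

  unchanged <- update_posterior(gamma_prior(2, 10),
                                tibble::tibble(n_events = 0, exposure_years = 0))
  expect_equal(unchanged$shape, 2)
  expect_equal(unchanged$rate, 10)

  expect_error(
    update_posterior(jeffreys_prior(),
                     tibble::tibble(n_events = 0, exposure_years = 30)),
    "improper")
})

test_that("Jeffreys posterior mean equals the exponential MLE", {
  post <- update_posterior(jeffreys_prior(),
                           tibble::tibble(n_events = 5, exposure_years = 40))
  expect_equal(posterior_mean_var(post)$mean, 0.125)

  # independent oracle: maximize the likelihood numerically on records
  set.seed(41)
  d <- make_records(round(rexp(40, 1 / 30), 3) + 0.5, rbinom(40, 1, 0.6))
  mle <- optimize(loglik_exp, c(1e-6, 5), data = d, maximum = TRUE)$maximum
  post2 <- posterior_from_data(d, jeffreys_prior())
  expect_equal(posterior_mean_var(post2)$mean, mle, tolerance = 1e-4)
})

test_that("closed-form posterior equals quadrature of likelihood times prior", {
  # sup-norm comparison on a hazard grid, for several priors and datasets
  set.seed(7)
  priors <- list(gamma_prior(2, 10), gamma_prior(6.25, 250), gamma_prior(0.5, 1))
  for (pr in priors) {
    d <- make_records(round(runif(30, 1, 60), 2), rbinom(30, 1, 0.3))
    post <- posterior_from_data(d, pr)
    unnorm <- function(l)
      dgamma(l, pr$shape, rate = pr$rate) * exp(loglik_exp(l, d))
    # normalize on a wide interval covering all posterior mass
    hi <- qgamma(1 - 1e-12, post$shape, rate = post$rate)
    Z <- integrate(Vectorize(unnorm), 0, hi, rel.tol = 1e-10)$value
    grid <- seq(qgamma(1e-9, post$shape, rate = post$rate), hi, length.out = 400)
    expect_lt(
      max(abs(vapply(grid, unnorm, 0) / Z -
                dgamma(grid, post$shape, rate = post$rate))),
      1e-6)
  }
})

test_that("sufficient statistics are additive across disjoint record sets", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    d <- make_records(runif(n, 1, 70), rbinom(n, 1, 0.4))
    split_at <- sample(seq_len(n - 1), 1)
    a <- d[seq_len(split_at), ]
    b <- d[(split_at + 1):n, ]
    prior <- gamma_prior(runif(1, 0.5, 10), runif(1, 1, 300))
    chained <- update_posterior(update_posterior(prior, survival_stats(a)),
                                survival_stats(b))
    pooled <- update_posterior(prior, survival_stats(d))
    expect_equal(chained$shape, pooled$shape)
    expect_equal(chained$rate, pooled$rate)
  }
})

test_that("predictive survival matches its Gamma-mixture Monte-Carlo value", {
  expect_equal(predictive_survival(gamma_prior(1, 1), 0), 1)
  expect_equal(predictive_survival(gamma_prior(1, 1), 1), 0.5)

  set.seed(5)
  p <- gamma_prior(4, 21)
  draws <- exp(-2 * rgamma(1e6, p$shape, rate = p$rate))
  mc_se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(predictive_survival(p, 2) - mean(draws)), 3 * mc_se)
})

test_that("predictive-survival SD has the Laplace-transform closed form", {
  expect_equal(predictive_survival_sd(gamma_prior(1, 1), 1), sqrt(1 / 12))
  expect_equal(predictive_survival_sd(gamma_prior(3, 7), 0), 0)

  set.seed(6)
  p <- gamma_prior(6.25, 250)
  draws <- exp(-2 * rgamma(1e6, p$shape, rate = p$rate))
  # MC error of a sample SD: sd/sqrt(2(n-1)) under approximate normality;
  # use a generous 3x bound
  sd_se <- sd(draws) / sqrt(2 * (length(draws) - 1))
  expect_lt(abs(predictive_survival_sd(p, 2) - sd(draws)), 3 * sd_se + 1e-6)
})

test_that("predictive survival is monotone in horizon and in rate", {
  taus <- seq(0.5, 6, by = 0.5)
  vals <- vapply(taus, function(t) predictive_survival(gamma_prior(4, 21), t), 0)
  expect_true(all(diff(vals) < 0))
  rates <- seq(10, 300, by = 10)
  vals_r <- vapply(rates, function(r) predictive_survival(gamma_prior(4, r), 2), 0)
  expect_true(all(diff(vals_r) > 0))
})

test_that("posterior tail probabilities integrate the Gamma density", {
  p <- gamma_prior(4, 21)
  expect_equal(posterior_tail_prob(p, 0, "at-or-above"), 1)
  expect_equal(posterior_tail_prob(gamma_prior(1, 1), log(2), "at-or-above"), 0.5)

  quad <- integrate(function(l) dgamma(l, 4, rate = 21), 0.19, Inf,
                    rel.tol = 1e-12)$value
  expect_lt(abs(posterior_tail_prob(p, 0.19, "at-or-above") - quad), 1e-8)

  for (r in c(0.01, 0.1, 0.19, 1)) {
    expect_equal(posterior_tail_prob(p, r, "at-or-above") +
                   posterior_tail_prob(p, r, "below"), 1)
  }
})

test_that("P(EFS meets target) thresholds the hazard at -log(efs0)/tau", {
  expect_equal(prob_efs_meets_target(gamma_prior(1, 1), exp(-2 * log(2)), 2), 0.5)

  set.seed(8)
  p <- gamma_prior(6.25 + 2, 250 + 180)
  draws <- exp(-2 * rgamma(1e6, p$shape, rate = p$rate))
  freq <- mean(draws >= 0.92)
  mc_se <- sqrt(freq * (1 - freq) / length(draws))
  expect_lt(abs(prob_efs_meets_target(p, 0.92, 2) - freq), 3 * mc_se)

  expect_error(prob_efs_meets_target(gamma_prior(1, 1), 1.2, 2), "between 0 and 1")
})

test_that("analyze_trial summarizes the posterior coherently", {
  d <- make_records(rep(24, 50), rep(c(1L, 0L), c(2, 48)))
  fit <- analyze_trial(d, gamma_prior_mean_sd(0.025, 0.01), efs0 = 0.92)
  td <- tidy(fit)
  expect_equal(td$shape, 6.25 + 2)
  expect_equal(td$rate, 250 + 100)
  expect_equal(td$efs_hat, predictive_survival(gamma_prior(8.25, 350), 2))
  expect_true(td$efs_ci_lower < td$efs_hat & td$efs_hat < td$efs_ci_upper)
  expect_equal(glance(fit)$prob_meets_target,
               prob_efs_meets_target(gamma_prior(8.25, 350), 0.92, 2))
})
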