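test_that("stage posteriors equal one-shot cumulative updates (chaining = pooling)", {
  # the engine cross-checks internally and aborts on disagreement; verify
  # externally against snapshots as well, on several seeded trials
  plan <- interim_plan(efs0 = 0.92, prior = gamma_prior_mean_sd(0.025, 0.02))
  for (seed in c(101, 202, 303)) {
    d <- simulate_trial(table2_case1(), seed = seed)
    res <- tidy(run_trial(d, plan))
    for (k in seq_len(nrow(res))) {
      st <- survival_stats(snapshot(d, res$analysis_time[k]))
      if (is.na(res$shape[k])) next
      expect_identical(res$shape[k], plan$prior$shape + st$n_events)
      expect_identical(res$rate[k], plan$prior$rate + st$exposure_years)
    }
  }
})

test_that("overwhelming favourable data stop for efficacy at the first look", {
  # one event over an enormous exposure, strongly informative optimistic prior
  d <- make_records(c(6, rep(70, 400)), c(1L, rep(0L, 400)), enroll = 0)
  plan <- interim_plan(analysis_times = c(18, 24), efs0 = 0.92,
                       prior = gamma_prior_mean_sd(0.01, 0.002))
  res <- glance(run_trial(d, plan))
  expect_equal(res$final_decision, "stop-efficacy")
  expect_equal(res$stop_stage, 1L)
})

test_that("uniformly early events stop for futility at the first evaluable look", {
  d <- make_records(rep(3, 60), rep(1L, 60), enroll = 0)
  plan <- interim_plan(analysis_times = c(18, 24), efs0 = 0.92,
                       prior = gamma_prior_mean_sd(0.025, 0.05),
                       futility_threshold = 0.10)
  res <- glance(run_trial(d, plan))
  expect_equal(res$final_decision, "stop-futility")
  expect_equal(res$stop_stage, 1L)
})

test_that("zero-event stages are recorded as not evaluable and do not stop", {
  d <- make_records(rep(70, 50), rep(0L, 50), enroll = 0)
  plan <- interim_plan(efs0 = 0.92, prior = jeffreys_prior())
  res <- tidy(run_trial(d, plan))
  expect_equal(nrow(res), 6L)
  expect_true(all(res$decision == "continue"))
  expect_true(all(res$note == "insufficient data"))

  # same guard for a proper but weak prior: no prior-driven stop without events
  plan_w <- interim_plan(efs0 = 0.92, prior = gamma_prior_mean_sd(0.025, 0.05))
  res_w <- tidy(run_trial(d, plan_w))
  expect_true(all(res_w$decision == "continue"))
})

test_that("adding events at fixed exposure never creates an efficacy stop", {
  plan <- interim_plan(analysis_times = 24, efs0 = 0.92,
                       prior = gamma_prior_mean_sd(0.025, 0.02))
  z_of <- function(n_events) {
    post <- update_posterior(plan$prior,
                             list(n_events = n_events, exposure_years = 150))
    z_statistic(predictive_survival(post, 2), 0.92,
                predictive_survival_sd(post, 2))
  }
  zs <- vapply(0:30, z_of, 0)
  expect_true(all(diff(zs) < 0))
})

test_that("a stricter historical control never stops earlier", {
  for (seed in c(11, 22, 33, 44)) {
    d <- simulate_trial(table2_case1(), seed = seed)
    stop_of <- function(efs0) {
      g <- glance(run_trial(d, interim_plan(
        efs0 = efs0, prior = gamma_prior_mean_sd(0.025, 0.01))))
      if (is.na(g$stop_month)) Inf else g$stop_month
    }
    expect_gte(stop_of(0.95), stop_of(0.92))
    expect_gte(stop_of(0.92), stop_of(0.88))
  }
})

test_that("at most one stop is recorded and later stages are not evaluated", {
  d <- simulate_trial(table2_case1(), seed = 55)
  res <- tidy(run_trial(d, interim_plan(efs0 = 0.88,
                                        prior = gamma_prior_mean_sd(0.02, 0.005))))
  n_stops <- sum(res$decision != "continue")
  expect_lte(n_stops, 1L)
  if (n_stops == 1L) expect_equal(which(res$decision != "continue"), nrow(res))
})

test_that("the posterior decision scale applies the beta_k thresholds exactly", {
  plan <- interim_plan(efs0 = 0.92, prior = gamma_prior_mean_sd(0.025, 0.01),
                       decision_scale = "posterior")
  expect_equal(plan$prob_thresholds, linear_posterior_thresholds(6, 0.05))
  d <- simulate_trial(table2_case1(), seed = 77)
  res <- tidy(run_trial(d, plan))
  evaluable <- !is.na(res$prob_meets_target)
  stop_rows <- res$decision == "stop-efficacy"
  expect_equal(
    stop_rows[evaluable],
    (res$prob_meets_target >= res$prob_threshold)[evaluable])
})

test_that("adaptive sample size reduces to full accrual with a single final look", {
  cfg <- table2_case1(fixed_group_size = 10)
  plan1 <- interim_plan(analysis_times = 72, efs0 = 0.92,
                        prior = gamma_prior_mean_sd(0.2, 0.01))
  res <- adaptive_sample_size(cfg, plan1, reps = 10, seed = 3)
  expect_true(all(tidy(res)$n_at_stop == 90))
})
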