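# Shared fixtures: small record builders and test-side generators.

make_records <- function(followup_months, event, enroll = 0) {
  tibble::tibble(
    patient_id = sprintf("T%03d", seq_along(followup_months)),
    enroll_time_months = rep_len(enroll, length(followup_months)),
    followup_months = followup_months,
    event = as.integer(event)
  )
}

# Exact exponential survival data with staggered accrual and administrative
# censoring at the trial horizon: the textbook null for the sequential
# procedure (hazard exactly lambda, per year).
gen_exponential_trial <- function(n_per_group, lambda, n_groups = 9,
                                  interval = 4, horizon = 72) {
  enroll <- rep((seq_len(n_groups) - 1) * interval, each = n_per_group)
  n <- length(enroll)
  t_months <- rexp(n, lambda) * 12
  window <- horizon - enroll
  tibble::tibble(
    patient_id = sprintf("E%04d", seq_len(n)),
    enroll_time_months = enroll,
    followup_months = pmin(t_months, window),
    event = as.integer(t_months < window)
  )
}

# Exponential log-likelihood of (followup months, event) records, hazard /yr.
loglik_exp <- function(lambda, data) {
  t_years <- data$followup_months / 12
  sum(data$event) * log(lambda) - lambda * sum(t_years)
}

table1_sim2_case1 <- function(...) {
  sim_config(hazard_range = c(0.02, 0.03), event_rate_range = c(0.07, 0.12), ...)
}

table1_sim1_case1 <- function(...) {
  sim_config(hazard_range = c(0.041, 0.042), event_rate_range = c(0.22, 0.23), ...)
}

table2_case1 <- function(...) {
  sim_config(hazard_range = c(0.02, 0.03), event_rate_range = c(0.05, 0.10), ...)
}

prior_grid_case1 <- function() {
  list(
    strong = gamma_prior_mean_sd(0.025, 0.01),
    moderate = gamma_prior_mean_sd(0.025, 0.02),
    weak = gamma_prior_mean_sd(0.025, 0.05),
    jeffreys = jeffreys_prior()
  )
}
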