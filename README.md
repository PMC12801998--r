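# bayesefs

Bayesian adaptive design and monitoring of **single-arm clinical trials with
a time-to-event endpoint**, aimed at de-intensified oncologic treatment
settings: small populations, high cure rates, very few events, and a
historical control instead of a randomized comparator. Typical users are
trial biostatisticians evaluating whether a de-escalated regimen preserves
event-free survival (EFS) before committing to a randomized study.

## The model

Follow-up times are modelled as exponential with hazard λ (per year); a
patient record contributes `f(t|λ)^δ S(t|λ)^(1−δ)` to the likelihood, so the
data enter only through the event count `D = Σδᵢ` and total exposure
`T = Σtᵢ`. With a conjugate Gamma(α, β) prior on λ (β in pseudo-years of
exposure),

```
λ | data ~ Gamma(α + D, β + T)
```

and every quantity the design needs is closed form:

* posterior-predictive EFS at horizon τ:  `EFŜ(τ) = (β'/(β'+τ))^α'`
* its posterior SD, via the Gamma Laplace transform:
  `σ̂² = (β'/(β'+2τ))^α' − EFŜ²`
* posterior probability of meeting a historical control EFS₀:
  `P(EFS ≥ EFS₀ | data) = P(λ ≤ −log(EFS₀)/τ | data)`, a Gamma CDF.

A single-look trial rejects H₀: EFS < EFS₀ when that posterior probability
reaches 95%. The K-stage adaptive design snapshots the accumulating data at
scheduled calendar times, updates the posterior (prior chaining and pooled
updating coincide by conjugacy), and compares the standardized statistic
`ẑ_k = (EFŜ_k − EFS₀)/σ̂(EFS_k)` with stage boundaries — by default the
linear stage thresholds `β_k = 1 − αk/K` mapped to the z scale, with
O'Brien–Fleming- and Pocock-type error-spending boundaries as alternatives.
Priors are elicited as a hazard mean and SD and moment-matched to Gamma
shape/rate; the Jeffreys prior `π(λ) ∝ 1/λ` is the non-informative option.

A staggered-accrual simulator (Poisson cohorts every 4 months, group-level
hazards and event rates, binomial event counts, administrative and random
censoring) generates trials for operating characteristics: empirical type I
error, power and minimal sample size across a sample-size sweep, and
stopping-time distributions of the interim design.

## Worked example

```r
library(bayesefs)

prior <- gamma_prior_mean_sd(0.025, 0.01)   # strongly informative: mean 0.025/yr, SD 0.01
trial <- simulate_trial(sim_config(hazard_range = c(0.02, 0.03),
                                   event_rate_range = c(0.05, 0.10), seed = 2026))
survival_stats(trial)
#> # A tibble: 1 × 2
#>   n_events exposure_years
#> 1        9           358.

analyze_trial(trial, prior, efs0 = 0.92)
#> <efs_fit> 9 events over 357.6 patient-years
#>   posterior Gamma(15.25, 607.6 /yr); hazard 0.0251 /yr (sd 0.006427)
#>   2-year EFS 0.9511 (posterior sd 0.0122)
#>   P(EFS >= 0.920) = 0.9876
```

Nine events over 358 patient-years update the Gamma(6.25, 250) prior to
Gamma(15.25, 607.6); the predictive 2-year EFS is 95.1% and the posterior
gives 98.8% probability that it meets the 92% historical control — above
95%, so the single-look test would conclude efficacy.

Monitoring the same trial with the six-stage schedule:

```r
monitor <- run_trial(trial, interim_plan(efs0 = 0.92, prior = prior))
monitor
#> <trial_monitor> 3 stage(s) evaluated; decision: stop-efficacy at month 30
#>   stage analysis_time n_enrolled n_events efs_hat     z z_boundary decision
#> 1     1            18         50        0  NA     NA          2.39 continue
#> 2     2            24         58        2   0.949  1.69       2.13 continue
#> 3     3            30         77        2   0.954  2.18       1.96 stop-efficacy
```

The month-18 look has no events yet and is recorded as not evaluable; by
month 30 the z statistic (2.18) crosses the stage boundary (1.96) and the
trial stops early for efficacy with 77 of ~90 patients enrolled.
`tidy()`, `glance()` and `autoplot()` work on every result object, and
`empirical_type1()`, `empirical_power()` and `interim_oc()` compute the
design's operating characteristics. A thin command-line front end lives at
`inst/cli/bayesefs.R` (subcommands `simulate`, `analyze`, `interim`,
`boundaries`, `oc`).

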