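---
title: "Methods: Bayesian adaptive monitoring of single-arm survival trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian adaptive monitoring of single-arm survival trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesefs)
```

## The problem

De-intensified oncologic regimens are evaluated in populations where the
standard of care already achieves high event-free survival (EFS) — think
pediatric lymphoma with 2-year EFS above 90%. Events are rare, eligible
patients are few, and a randomized non-inferiority trial would take many
years. A pragmatic alternative is a single-arm trial tested against a
historical control EFS$_0$, with interim looks so that convincing evidence
can end the trial early. `bayesefs` implements the full chain for that
design: conjugate posterior inference, a predictive EFS test, a multi-stage
monitoring rule, a trial simulator, and Monte-Carlo operating
characteristics.

## Model and assumptions

Event times are exponential with constant hazard $\lambda$ (per year). Each
patient contributes the observed follow-up $t_i$ (months, converted to
years once, in `survival_stats()`) and an event indicator $\delta_i$;
censoring is assumed independent of the event process. The likelihood
depends on the data only through $D=\sum\delta_i$ and $T=\sum t_i$, and a
Gamma$(\alpha,\beta)$ prior (rate-parameterized; $\beta$ acts as
pseudo-exposure in years, $\alpha$ as pseudo-events) gives

$$\lambda \mid \text{data} \sim \text{Gamma}(\alpha + D,\; \beta + T).$$

The constant-hazard assumption is the price of these closed forms. For
high-cure populations over a 2-year horizon it is a deliberately crude but
serviceable summary: the fitted $\lambda$ is an exposure-weighted average
hazard, and the design questions (does EFS clear a benchmark?) are
first-order in that average. Weibull or piecewise hazards, covariates, and
competing risks are out of scope.

All predictive quantities are Gamma Laplace transforms. The predictive EFS
at horizon $\tau$ is $E[e^{-\tau\lambda}] = (\beta'/(\beta'+\tau))^{\alpha'}$
and its posterior variance is
$(\beta'/(\beta'+2\tau))^{\alpha'} - (\beta'/(\beta'+\tau))^{2\alpha'}$ —
exact, not delta-method. The event $\{e^{-\tau\lambda} \ge EFS_0\}$ is
$\{\lambda \le -\log(EFS_0)/\tau\}$, so posterior probabilities of meeting
the control are Gamma CDF evaluations.

## Priors

Priors are elicited as a plausible hazard mean $m$ and SD $s$ (per year)
and moment-matched: $\alpha = m^2/s^2$, $\beta = m/s^2$. The three
informative levels used throughout the simulation studies are SD 0.01
(strong, e.g. Gamma(6.25, 250) at mean 0.025 — worth 6.25 pseudo-events
over 250 pseudo-years), SD 0.02 (moderate), SD 0.05 (weak). The Jeffreys
prior $\pi(\lambda)\propto 1/\lambda$ is the improper Gamma(0, 0) limit;
its posterior mean equals the maximum-likelihood estimate $D/T$ exactly,
and the package refuses to compute predictive quantities until at least one
event makes the posterior proper.

## The single-look test

`single_look_test()` rejects $H_0{:}\ EFS < EFS_0$ when
$P(EFS \ge EFS_0 \mid \text{data}) \ge 0.95$. `empirical_type1()` and
`empirical_power()` estimate its frequentist error rates over a sample-size
grid (default 80–225 in steps of 5, nominal $n$ split into nine equal
enrollment groups). Common random numbers are used everywhere: replicate
$i$ seeds the RNG with `seed + i`, one stream generates the datasets for
each $n$ in increasing order, and all priors are scored on the same
datasets, which stabilizes prior-to-prior comparisons such as the minimal
sample size reaching 80% power.

## The K-stage interim design

`interim_plan()` fixes analyses at calendar months 18, 24, 30, 36, 42, 48
by default: monitoring starts once the earliest cohorts approach the
2-year horizon and continues every 6 months through year 4. At each look
the data are administratively censored at the analysis time
(`snapshot()`), the posterior is refreshed, and the standardized statistic
$\hat z_k = (\widehat{EFS}_k - EFS_0)/\hat\sigma(EFS_k)$ is compared with a
stage boundary. By conjugacy, chaining each stage's posterior into the next
stage's prior is identical to a one-shot update with the cumulative
sufficient statistics; `run_trial()` computes both and verifies the
identity at every stage.

Three boundary families are provided (`z_boundaries()`):

* **linear** (default): stage thresholds $\beta_k = 1 - \alpha k/K$ on the
  posterior-probability scale, i.e. z boundaries
  $\Phi^{-1}(1-\alpha k/K)$ = 2.39, 2.13, 1.96, 1.83, 1.73, 1.64 at
  $K=6$, $\alpha=0.05$. Each look runs at its nominal stage level; the
  family deliberately relaxes the criterion as information accrues and is
  the rule under which the package's simulation studies are run.
* **O'Brien–Fleming-type** and **Pocock-type** error spending at
  information fractions $k/K$, computed by the standard recursion for the
  sequential statistic's joint normal law (trapezoid sub-density
  integration, 4001-point grid, `uniroot` to $10^{-10}$). These control the
  *overall* one-sided crossing probability at $\alpha$ under the canonical
  normal model; the test suite checks the recursion against closed-form
  bivariate quadrature at $K=2$ and Monte-Carlo Brownian paths at $K=6$.

Decisions can also be taken on the exact posterior scale
(`decision_scale = "posterior"`): stop when
$P(EFS \ge EFS_0) \ge \Phi(c_k)$, which for the linear family is exactly
$\beta_k$. An optional futility floor $\gamma_f$ stops the trial when the
posterior probability drops below it; it is off by default because the
design's primary claim is about efficacy stopping.

**Evaluability.** A look whose snapshot contains no events is recorded as
"insufficient data" and does not stop the trial, whatever the prior. With
zero events the posterior is either improper (Jeffreys) or essentially the
prior; a weak Gamma prior then reports EFS near 1 with a small SD, and an
efficacy stop at month 18 would be entirely prior-driven. Requiring at
least one observed event is the operational meaning of "enough follow-up
to analyze".

## The trial simulator

`simulate_trial()` emulates a 6-year trial: nine enrollment cohorts open
every 4 months for 3 years; cohort sizes are `max(Poisson(10), 6)` (about
10.01 expected, so roughly 90 patients per trial) or a fixed override for
equal-group sweeps. Each cohort $j$ draws a hazard
$\lambda_j \sim U(\text{hazard range})$ and an event rate
$p_j \sim U(\text{event-rate range})$; the cohort's event count is
$\mathrm{Binom}(n_j, p_j)$, event times are exponential conditioned to fall
inside the patient's administrative window (enrollment to the 72-month
horizon), other patients are censored at the horizon, and 10% of the
event-free are re-censored at a uniform earlier time.

The binomial event count makes the generator a *cure-mixture*: $p_j$
controls how many events ever happen, $\lambda_j$ controls when. In the
null scenarios the event-rate range numerically matches the probability
that an exponential event with the boundary hazard occurs within the trial
window, so the observed data are calibrated near the null; in the
alternative scenarios the event rate is set below that, encoding the cure
fraction of a de-intensified regimen that works. When $p_j$ is matched
exactly to $1-e^{-\lambda_j W}$ the generator reduces to textbook censored
exponential sampling, and the test suite verifies that the Jeffreys
posterior then recovers the true hazard. What the simulator does *not*
emulate: dropout, accrual ramp-up, within-cohort enrollment jitter,
non-uniform hazards across patients of a cohort, and competing risks —
passing operating characteristics say nothing about those features of real
trials.

Reproducibility is exact: the RNG stream order is fixed (sizes, hazards,
event rates, per-cohort counts and times, censoring picks, censoring
times), so a configuration plus seed is a complete fingerprint of the
dataset.

## Numerical choices and degenerate inputs

* Exposure is summed in months and divided by 12 once; hazards and Gamma
  rates are per-year everywhere else.
* `update_posterior()` with a Jeffreys prior and zero events raises an
  error ("wait for data") rather than returning an improper object; the
  sweep internals count such replicates as non-rejections.
* `predictive_survival_sd()` clamps tiny negative variances from
  floating-point cancellation to zero.
* Chained and pooled posteriors are compared at $10^{-9}$ inside
  `run_trial()`; sequential summation differs from pooled summation only
  in the last floating-point digit.
* Minimal sample size is the smallest grid point whose empirical rate
  reaches the target; the grid step (5 patients) is the resolution of that
  answer. Nominal $n$ is split as `round(n/9)` per cohort and the realized
  total is reported alongside.
* The spending recursion's grid extends 8.5 SDs below zero; boundary
  accuracy is about $10^{-4}$, far inside Monte-Carlo noise.

## Known limitations

* **The sequential z rule is anti-conservative at low event counts.** At
  the event counts this design actually sees (a handful of events at the
  early looks), the Wald-type statistic $\hat z_k$ is strongly
  right-skewed under the null, and information accrues with calendar time
  rather than uniformly in $k/K$. The acceptance suite measures the
  consequence directly: with data generated exactly at the null-boundary
  hazard, the six-look procedure with O'Brien–Fleming-type spending
  boundaries crosses far more often than the nominal 5% (the corresponding
  test is expected to fail and documents the measured rate). Taking
  decisions on the exact Gamma-posterior scale removes most of the skew
  component, and the inflation shrinks as event counts grow, but users who
  need strict frequentist type-I control at these sample sizes should
  calibrate boundaries by simulation against their own null — the
  machinery in `interim_oc()` does exactly that computation. The
  single-look 95% posterior-probability test, by contrast, shows empirical
  type-I error well below 5% across the whole sample-size sweep.
* The exponential likelihood mis-specifies the cure-mixture data it
  monitors; the fitted hazard is an exposure-weighted average, which is
  the intended estimand for the EFS benchmark question but not a
  biological hazard.
* Historical-control comparability (patient mix, eligibility) is assumed,
  not modelled; propensity-style adjustment is out of scope.

## Problem sizes in the test suite

The packaged checks run 1000 replicates per condition for the power,
type-I and interim operating characteristics (a ~30-value sample-size grid
for the sweeps), 600 replicates for the null-boundary crossing check,
$10^6$ posterior draws for the Monte-Carlo oracles of the closed forms,
and $2\times10^5$ Brownian paths for the boundary cross-check — sizes at
which every Monte-Carlo tolerance is three standard errors or better and
the whole suite completes in a few minutes.
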