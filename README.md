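# banditgroups

Simulation and model-based analysis of how individuals, dyads, and triads
learn in two-armed bandit tasks with reward reversals.

## The problem

In a reversal-learning two-armed bandit, a decision unit makes 100 choices
between two boxes paying off with probability 0.7 and 0.3, the roles
swapping at scheduled trials (after trials 30 and 70 by default).
Performance is the number of rewarded trials. The question the package
addresses: does performance rise, fall, or dip with group size — and why?

Its working hypothesis is *learning coherence*: individuals and
majority-ruled triads follow one consistent learning policy, while dyads —
where no majority can form — drift between members' policies. The
prediction is a U-shape: dyads below both individuals and triads.

The package provides, as tested building blocks:

* a task simulator (`task_config()`, `build_schedule()`, `sample_reward()`);
* two Q-learning observation models with softmax choice
  (`P(a=i) ∝ exp(βQ_i)`): the simple delta rule
  `Q ← Q + α(R − Q)` and an asymmetric model with separate learning rates
  `α⁺`/`α⁻` for positive/negative prediction errors plus a choice trace
  `ϕ` (`session_loglik()`);
* per-session MAP estimation with Beta priors on rates and a Gamma prior
  on β (`fit_map()`), and model evidence via WBIC — the mean log-likelihood
  under the posterior tempered at `1/log(n)` (`compute_wbic()`,
  `compare_models()`);
* a synthetic-data generator embodying the coherence hypothesis
  (`group_design()`, `generate_dataset()`): group members keep private
  action values; each trial is either a consensus choice (probability `c`)
  updated by all members, or controlled — and learned from — by a single
  member;
* the group-size statistical pipeline (`unit_records()`,
  `analysis_report()`): Kruskal-Wallis, Bonferroni-adjusted pairwise
  rank-sum tests, within-group contrasts against member aggregates,
  positivity-bias tests, and identity-link Poisson regressions of
  performance on size and size².

## Worked example

```r
library(banditgroups)

# generate a small synthetic study: 60 individuals, 30 dyads, 30 triads
ds <- generate_dataset(group_design(60, 30, 30, seed = 42))
rec <- unit_records(ds)
sapply(split(rec$performance, rec$size), mean)
#>        1        2        3
#> 56.55000 55.20000 59.33333

# the U-shape as a regression: negative size, positive size^2
poisson_regression(rec, "quadratic")
#> Poisson regression (identity link, spec 'quadratic', n = 120), AIC = 779.1
#>           term estimate std_error statistic   p_value
#> 1  (Intercept)   63.383     5.198    12.194 3.364e-34
#> 2         size   -9.575     6.307    -1.518 1.290e-01
#> 3 size_squared    2.742     1.603     1.710 8.723e-02

# fit one unit's learning parameters and score its model evidence
s <- ds$sessions[[1]]
fit_map(s, "simple", seed = 1)
#> MAP fit (simple model): log-posterior -25.793, log-likelihood -23.750
#> simple Q-learning params: alpha = 0.3661, beta = 5.808
compute_wbic(s, "simple", seed = 1)
#> WBIC (simple model): -27.010 (temperature 0.2171, acceptance 0.28)
```

Dyads earn the fewest rewarded trials of the three sizes; at this small n
the quadratic coefficients have the right signs (negative size, positive
size²) but wide standard errors — the full design (hundreds of units per
size) is what the statistical pipeline is sized for. The fitted `alpha` is the fraction of
each prediction error incorporated per trial, `beta` the softmax sharpness
(exploitation weight), and WBIC values are comparable across models per
session (higher is better).

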