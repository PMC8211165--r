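---
title: "Models and methods behind banditgroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind banditgroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(banditgroups)
```

## The scientific question

Do two heads learn better than one, and do three learn better than two?
`banditgroups` studies this in the classic reversal-learning two-armed
bandit: a decision unit — a single person, a dyad, or a triad — makes 100
choices between two boxes, one paying off 70% of the time and the other
30%, with the roles swapping at scheduled trials (by default after trials
30 and 70). Performance is the number of rewarded trials.

The package's working hypothesis is about *learning coherence*. A triad can
settle disagreements by majority rule, so its choices tend to follow one
consistent learning policy, as an individual's trivially do. A dyad has no
majority: control of the choice drifts between members, and the unit's
learning is incoherent. The hypothesis predicts a U-shaped relation between
group size and performance — dyads below both individuals and triads — and
the package provides everything needed to generate data under that
hypothesis, fit learning models to it, and test the prediction.

## Learning models

Both models track an action value $Q_i(t)$ per arm, starting at
$Q_i(1) = 0$, and choose by softmax

$$P(a(t) = i) = \frac{e^{\beta Q_i(t)}}{\sum_{j} e^{\beta Q_j(t)}},$$

where the sum runs over the two arms and $\beta \ge 0$ is the inverse
temperature (exploitation weight; $\beta = 0$ is random choice). Rewards
enter on a 0/1 scale — the 10 points shown to participants are display
metadata. This scaling matters: inverse temperatures around 4–6, the
magnitudes typical of human fits in this task, only make sense against
unit-scaled values.

**Simple model** (`alpha`, `beta`): the chosen arm is updated by the delta
rule with prediction error $\delta(t) = R(t) - Q_i(t)$,

$$Q_i(t+1) = Q_i(t) + \alpha\,\delta(t), \qquad 0 < \alpha \le 1,$$

and the unchosen arm is left unchanged.

**Asymmetric model** (`alpha_plus`, `alpha_minus`, `beta`, `phi`): the
learning rate depends on the sign of the prediction error,

$$Q_i(t+1) = \begin{cases}
  Q_i(t) + \alpha^{+}\delta(t) + \phi & \delta(t) \ge 0\\
  Q_i(t) + \alpha^{-}\delta(t) + \phi & \delta(t) < 0,
\end{cases}$$

with the boundary $\delta = 0$ deliberately on the $\alpha^{+}$ branch.
$\alpha^{+} - \alpha^{-}$ is the *positivity bias*. $\phi$ is a choice
trace capturing perseveration; it is implemented exactly as written — an
additive constant on every update of the chosen arm — rather than as a
separate decaying choice kernel in the softmax, which is the other
convention in the literature. With $\alpha^{+} = \alpha^{-}$ and
$\phi = 0$ the asymmetric model reproduces the simple model exactly
(a property the tests enforce).

## Estimation

Per-session parameters are estimated at the posterior mode (MAP):
likelihood times prior, with Beta(2, 2) priors on learning rates,
Gamma(shape 2, scale 3) on $\beta$, and Normal(0, 1) on $\phi$. These are
weakly informative defaults, standard for reinforcement-learning fits, and
all exposed in `prior_spec()`; flat variants exist so MAP can be checked
against plain maximum likelihood. Optimisation runs on an unconstrained
reparameterisation (logit for rates, log for $\beta$, identity for $\phi$)
with Nelder-Mead from 10 restarts (first restart at the prior mode,
the rest randomised), keeping the best mode; the objective tolerance is
well below the 1e-6 scale that matters for these 2–4 parameter problems.
Since the mode is defined in the natural parameter space and the transform
is monotone, no Jacobian enters the MAP objective.

Model evidence is approximated by WBIC: the mean log-likelihood under the
posterior tempered at inverse temperature $1/\log n$ ($n$ = trials; for
100-trial sessions, 0.2171). The tempered posterior is sampled by
random-walk Metropolis on the same unconstrained scale — here the transform
Jacobian *is* part of the target — with 5,000 retained draws after 1,000
burn-in iterations during which the Gaussian proposal scale adapts toward
roughly 0.3 acceptance and is then frozen. Higher WBIC means better
evidence under this sign convention. Two models are compared across
sessions by a pooled-variance two-sample t-test on the per-session WBICs
(`compare_models()`), with $n_1 + n_2 - 2$ degrees of freedom.

## The synthetic-data generator

No public behavioral dataset accompanies this design, so the generator is a
first-class, tested component. Members' true parameters are drawn from
$\alpha \sim \mathrm{Beta}(2, 2)$,
$\beta \sim \mathrm{Gamma}(2, \text{scale } 2.5)$ and
$\phi \sim \mathrm{Normal}(0, 0.1)$ — weakly informative populations whose
means sit near the magnitudes reported for human players of this task. The
default design mirrors a large classroom study: 322 individual sessions,
138 dyads, 108 triads, with group members drawn from the pool of
individuals so that every group member also has an individual session
(needed for the within-group contrasts).

A group session works as follows. Each trial is *coherent* with
probability $c$ (the coherence parameter: 1 for individuals, 0.1 for
dyads, 0.9 for triads by default): the unit chooses by a consensus softmax
over the member-averaged $Q$ with the member-averaged $\beta$, and every
member updates their values on the outcome. Otherwise the trial is
*incoherent*: a uniformly chosen member's own policy controls the choice,
and — by default — only that member updates their action values.

The "controller-only" update on incoherent trials is the load-bearing
design choice, and it was a genuinely open one. A pure mixture of member
policies (everyone still learning from the shared stream) turns out to be
performance-neutral relative to individuals: per-trial control mixing is a
linear average of the members' choice probabilities, and expected reward is
linear in choice probability, so a dyad that merely alternates control
earns, in expectation, what an average individual earns — no U-shape can
emerge from policy mixing alone. For incoherence to cost anything, it has
to disrupt *learning*: here, members who are not in control disengage and
do not integrate the outcome, so each dyad member effectively learns from
roughly half the trials, degrading their value estimates and with them the
unit's performance. Triads, being mostly coherent, keep members' learning
synchronized and additionally benefit from averaging noisy value estimates
in the consensus policy. The shared-stream alternative remains available
(`incoherent_updates = "all"`) so other formalisations can be swapped in
behind the same interface.

What the generator does *not* emulate: communication content, confidence
sharing, social pressure beyond the coherence mixture, within-session
parameter drift, and order/carry-over effects of repeated participation.
Passing tests on these synthetic data therefore show that the pipeline
detects the U-shape *when the coherence mechanism causes it*; they are not
evidence about any particular human sample.

For model recovery, data are generated from the asymmetric model with all
of its distinguishing features at representative values: positivity bias
$\alpha^{+} - \alpha^{-} = 0.4$ (rates 0.6 / 0.2), $\beta = 5$, and the
choice trace at its population scale, $\phi = 0.1$. A generator with
$\phi = 0$ lies in a subspace where the asymmetric model's extra
flexibility is barely exercised, and 100-trial sessions then carry too
little signal for the tempered-evidence comparison to detect the asymmetry
reliably — a known property of WBIC at short series, not a defect of the
sampler.

## Statistical pipeline

Performance and fitted parameters are compared across sizes by the
Kruskal-Wallis test (midrank tie correction) followed by pairwise Wilcoxon
rank-sum tests with Bonferroni adjustment over the number of pairs
(`wilcox.test` uses the exact distribution where possible, the corrected
normal approximation otherwise). Positivity biases are tested per size by
a one-sample signed-rank test of median zero — reported on the honest
degrees of freedom of a one-sample test, even though group comparisons of
this kind are sometimes printed in 2-df chi-square notation.

Within-group effects compare each group's value (performance or a fitted
parameter) against the max, min and mean of its members' individual-session
values. The default is a two-sample rank test in 1-df chi-square form,
matching how such contrasts are conventionally reported; because the data
are naturally paired, a paired signed-rank variant is available
(`paired = TRUE`) and is the statistically stricter choice.

Performance determinants are estimated by Poisson regression with an
*identity* link: coefficients on the count scale (intercepts near 50 of
100 trials), fitted by the standard IRLS with step-halving that keeps
fitted means positive (`glm`), with a log link available. Size enters
either as condition dummies (dyad or individual baseline) or as
$\mathrm{size} + \mathrm{size}^2$; the U-shape appears as a negative size
and positive size-squared coefficient. AIC is reported per specification.

## Numerical and degenerate-input conventions

* Softmax is computed with max-subtraction, and log-probabilities through
  the stable logistic, so large $\beta Q$ never overflows.
* A zero-trial session has constant likelihood; its MAP is the prior mode.
* WBIC requires at least two trials ($1/\log n$); an MCMC acceptance rate
  outside (0.05, 0.95) is a diagnostic warning, not a failure.
* All-zero bias vectors and identical contrast samples short-circuit to
  p = 1 rather than dividing by a zero variance.
* Every seeded entry point (`generate_dataset()`, `fit_map()`,
  `compute_wbic()`, the pipeline stages) restores the caller's RNG state,
  and the pipeline derives stage seeds from the single run seed, so one
  integer reproduces every artifact byte for byte.

## Problem sizes

The package's own checks run at sizes chosen to balance statistical margin
against desk-scale runtime: likelihood oracles on 100 random sessions;
parameter recovery on 200 hundred-trial sessions; WBIC model recovery on
100 sessions; the U-shape on 500 units per size with 20 seeded replicates
of the regression sign pattern; the regression engine on 100 replicates at
n = 471 with the size composition 262 / 116 / 93. Larger designs are a
matter of changing `group_design()` counts.

## Known limitations

* The coherence mixture is one formalisation of learning incoherence;
  alternatives (weighted consensus, confidence-driven control, partial
  attention) would slot behind the same `simulate_group_session()`
  interface but are not implemented.
* Estimation is per-session; there is no hierarchical pooling across
  members or repeated plays.
* WBIC at 100 trials separates models only when the generating process
  exercises their distinguishing parameters strongly; near-nested
  generators are reported as statistically indistinguishable, which is the
  correct behaviour of an evidence proxy, not a bug.
* The simulator covers two arms only, with piecewise-constant reversal
  schedules; restless bandits and k > 2 arms are out of scope.
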