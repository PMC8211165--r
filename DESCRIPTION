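Package: banditgroups
Title: Group Reinforcement Learning in Two-Armed Bandit Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of individual and small-group
    learning in two-armed bandit tasks with scheduled reward reversals. Provides
    simple and asymmetric Q-learning models with softmax choice, maximum a
    posteriori parameter estimation with beta-gamma priors, model comparison via
    the widely applicable Bayesian information criterion (WBIC), a synthetic-data
    generator embodying a learning-coherence account of group decision-making
    (individuals and majority-ruled triads learn coherently, dyads do not), and
    the group-size statistical pipeline: rank-based tests of the U-shaped
    performance pattern, within-group contrasts against member aggregates, and
    identity-link Poisson regressions of performance on group size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
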