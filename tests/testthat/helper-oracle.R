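# Independent brute-force re-implementation of the session log-likelihood,
# written as an explicit softmax over both arms (no shared code with the
# package's logistic-form loop). Used as the oracle for likelihood tests.
oracle_loglik <- function(choices, rewards, params, model) {
  q <- c(0, 0)
  ll <- 0
  for (t in seq_along(choices)) {
    z <- params$beta * q
    pr <- exp(z - max(z))
    pr <- pr / sum(pr)
    ll <- ll + log(pr[choices[t]])
    i <- choices[t]
    delta <- rewards[t] - q[i]
    if (model == "simple") {
      q[i] <- q[i] + params$alpha * delta
    } else {
      rate <- if (delta >= 0) params$alpha_plus else params$alpha_minus
      q[i] <- q[i] + rate * delta + params$phi
    }
  }
  ll
}

# A session with uniformly random choices and Bernoulli(p) rewards.
random_session <- function(n = 100, p = 0.5, unit_id = "rand") {
  session(unit_id,
          choices = sample(1:2, n, replace = TRUE),
          rewards = stats::rbinom(n, 1, p))
}

random_simple_params <- function() {
  simple_params(alpha = stats::runif(1, 0.05, 1),
                beta = stats::runif(1, 0, 10))
}

random_asym_params <- function() {
  asym_params(alpha_plus = stats::runif(1, 0.05, 1),
              alpha_minus = stats::runif(1, 0.05, 1),
              beta = stats::runif(1, 0, 10),
              phi = stats::rnorm(1, 0, 0.3))
}
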