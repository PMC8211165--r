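test_that("log-posterior decomposes into likelihood plus log priors", {
  set.seed(31)
  pr <- prior_spec()
  for (i in 1:10) {
    s <- random_session(60)
    ps <- random_simple_params()
    lp <- log_posterior(ps, s, pr)
    by_hand <- session_loglik(s, ps) +
      dbeta(ps$alpha, 2, 2, log = TRUE) +
      dgamma(ps$beta, 2, scale = 3, log = TRUE)
    expect_lt(abs(lp - by_hand), 1e-10)

    pa <- random_asym_params()
    lpa <- log_posterior(pa, s, pr)
    by_hand_a <- session_loglik(s, pa) +
      dbeta(pa$alpha_plus, 2, 2, log = TRUE) +
      dbeta(pa$alpha_minus, 2, 2, log = TRUE) +
      dgamma(pa$beta, 2, scale = 3, log = TRUE) +
      dnorm(pa$phi, 0, 1, log = TRUE)
    expect_lt(abs(lpa - by_hand_a), 1e-10)
  }
})

test_that("out-of-support parameters score -Inf", {
  s <- random_session(20)
  expect_identical(log_posterior(list(alpha = 1.5, beta = 2), s,
                                 model = "simple"), -Inf)
  expect_identical(log_posterior(list(alpha = 0.5, beta = -1), s,
                                 model = "simple"), -Inf)
})

test_that("flat priors make log-posterior a constant shift of the likelihood", {
  flat <- prior_spec(alpha_shape1 = 1, alpha_shape2 = 1, beta_prior = "flat",
                     phi_prior = "flat")
  set.seed(32)
  s <- random_session(50)
  shifts <- replicate(10, {
    p <- random_simple_params()
    log_posterior(p, s, flat) - session_loglik(s, p)
  })
  expect_lt(diff(range(shifts)), 1e-12)
})

test_that("a zero-trial session is fitted at the prior mode", {
  empty <- session("none", integer(), integer())
  f <- fit_map(empty, "simple", seed = 33)
  expect_equal(f$params$alpha, 0.5, tolerance = 1e-3)  # Beta(2,2) mode
  expect_equal(f$params$beta, 3, tolerance = 1e-2)     # Gamma(2, scale 3) mode
})

test_that("MAP recovers the generating parameters on one long session", {
  set.seed(34)
  task <- task_config(n_trials = 2000, reversal_trials = seq(100, 1900, 100))
  s <- simulate_agent_session(simple_params(0.6, 5), task)
  f <- fit_map(s, "simple", seed = 35)
  expect_lt(abs(f$params$alpha - 0.6), 0.1)
  expect_lt(abs(f$params$beta - 5), 1)
  expect_true(f$converged)
  expect_gte(f$log_posterior, max(f$restart_log_posteriors) - 1e-9)
})

test_that("MAP fitting is deterministic given a seed", {
  set.seed(36)
  s <- simulate_agent_session(simple_params(0.4, 3))
  f1 <- fit_map(s, "asymmetric", seed = 37)
  f2 <- fit_map(s, "asymmetric", seed = 37)
  expect_identical(f1, f2)
})

test_that("MAP under flat priors coincides with maximum likelihood", {
  flat <- prior_spec(alpha_shape1 = 1, alpha_shape2 = 1, beta_prior = "flat")
  set.seed(38)
  s <- simulate_agent_session(simple_params(0.5, 4))
  f <- fit_map(s, "simple", priors = flat, seed = 39)
  # independent ML optimisation of the likelihood alone
  nll <- function(x) -session_loglik(s, list(alpha = plogis(x[1]),
                                             beta = exp(x[2])),
                                     model = "simple")
  ml <- optim(c(0, 1), nll, method = "Nelder-Mead",
              control = list(reltol = 1e-12, maxit = 5000))
  expect_lt(abs(f$log_likelihood - (-ml$value)), 1e-4)
})

test_that("WBIC uses temperature 1/log(n) and is seed-deterministic", {
  set.seed(40)
  s <- simulate_agent_session(simple_params(0.5, 4))
  w1 <- compute_wbic(s, "simple", n_samples = 500, burn_in = 200, seed = 41)
  w2 <- compute_wbic(s, "simple", n_samples = 500, burn_in = 200, seed = 41)
  expect_equal(w1$temperature, 1 / log(100), tolerance = 1e-12)
  expect_equal(w1$temperature, 0.21715, tolerance = 1e-4)
  expect_identical(w1$wbic, w2$wbic)
  expect_gt(w1$acceptance_rate, 0.05)
  expect_lt(w1$acceptance_rate, 0.95)
  expect_error(compute_wbic(session("x", 1L, 1L), "simple"), "2 trials")
})

test_that("WBIC of a uniform-random session cannot beat the uniform policy", {
  set.seed(42)
  s <- random_session(100, p = 0.5)
  w <- compute_wbic(s, "simple", seed = 43)
  # the uniform policy (beta = 0) is optimal in expectation for random data;
  # allow a small Monte-Carlo margin above 100 * log(0.5)
  expect_lt(w$wbic, 100 * log(0.5) + 2)
})

test_that("model comparison mirrors the pooled-variance t-test", {
  x <- c(-50.1, -49.5, -51.2, -48.8)
  y <- c(-50.9, -52.3, -49.9, -51.8)
  cm <- compare_models(x, y)
  # textbook pooled t
  sp2 <- ((3 * var(x)) + (3 * var(y))) / 6
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(cm$statistic, t_hand, tolerance = 1e-12)
  expect_equal(cm$df, 6)
  expect_equal(cm$p_value, 2 * pt(-abs(t_hand), 6), tolerance = 1e-12)

  same <- rep(-50, 5)
  cm0 <- compare_models(same, same)
  expect_equal(cm0$statistic, 0)
  expect_equal(cm0$p_value, 1)

  # two pooled-sample-sized lists give the pooled df
  set.seed(44)
  cm568 <- compare_models(rnorm(568, -49), rnorm(568, -50))
  expect_equal(cm568$df, 1134)
  expect_error(compare_models(numeric(), 1:3), "non-empty")
})

test_that("fit_sessions and wbic_sessions return one deterministic row per unit", {
  set.seed(45)
  ss <- lapply(1:4, function(i) {
    simulate_agent_session(simple_params(0.5, 4), unit_id = paste0("u", i))
  })
  f1 <- fit_sessions(ss, "simple", n_restarts = 3, seed = 46)
  f2 <- fit_sessions(ss, "simple", n_restarts = 3, seed = 46)
  expect_identical(f1, f2)
  expect_equal(f1$unit_id, paste0("u", 1:4))
  w1 <- wbic_sessions(ss, "simple", n_samples = 300, burn_in = 100, seed = 47)
  w2 <- wbic_sessions(ss, "simple", n_samples = 300, burn_in = 100, seed = 47)
  expect_identical(w1, w2)
  expect_equal(nrow(w1), 4)
})
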