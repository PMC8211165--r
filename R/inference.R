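#' Priors for MAP estimation
#'
#' Learning rates (`alpha`, `alpha_plus`, `alpha_minus`) get a
#' `Beta(alpha_shape1, alpha_shape2)` prior, the inverse temperature a
#' `Gamma(beta_shape, scale = beta_scale)` prior, and the choice trace a
#' `Normal(phi_mean, phi_sd)` prior. Defaults (Beta(2, 2), Gamma(2, scale 3),
#' Normal(0, 1)) are weakly informative and standard for reinforcement-
#' learning model fitting. `beta_prior = "flat"` / `phi_prior = "flat"`
#' substitute improper flat priors (log-density 0 on the support), which
#' together with `Beta(1, 1)` rates makes MAP coincide with maximum
#' likelihood.
#'
#' @param alpha_shape1,alpha_shape2 Beta hyperparameters for learning rates.
#' @param beta_shape,beta_scale Gamma hyperparameters for beta.
#' @param phi_mean,phi_sd Normal hyperparameters for phi.
#' @param beta_prior `"gamma"` or `"flat"`.
#' @param phi_prior `"normal"` or `"flat"`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(alpha_shape1 = 2, alpha_shape2 = 2,
                       beta_shape = 2, beta_scale = 3,
                       phi_mean = 0, phi_sd = 1,
                       beta_prior = c("gamma", "flat"),
                       phi_prior = c("normal", "flat")) {
  stopifnot(alpha_shape1 > 0, alpha_shape2 > 0, beta_shape > 0,
            beta_scale > 0, phi_sd > 0)
  structure(
    list(alpha_shape1 = alpha_shape1, alpha_shape2 = alpha_shape2,
         beta_shape = beta_shape, beta_scale = beta_scale,
         phi_mean = phi_mean, phi_sd = phi_sd,
         beta_prior = match.arg(beta_prior),
         phi_prior = match.arg(phi_prior)),
    class = "prior_spec"
  )
}

log_prior <- function(params, priors, model = model_of(params)) {
  lp_rate <- function(a) {
    if (a <= 0 || a > 1) return(-Inf)
    stats::dbeta(a, priors$alpha_shape1, priors$alpha_shape2, log = TRUE)
  }
  lp_beta <- function(b) {
    if (b < 0) return(-Inf)
    if (priors$beta_prior == "flat") 0
    else stats::dgamma(b, priors$beta_shape, scale = priors$beta_scale,
                       log = TRUE)
  }
  if (model == "simple") {
    lp_rate(params$alpha) + lp_beta(params$beta)
  } else {
    lp_phi <- if (priors$phi_prior == "flat") 0 else
      stats::dnorm(params$phi, priors$phi_mean, priors$phi_sd, log = TRUE)
    lp_rate(params$alpha_plus) + lp_rate(params$alpha_minus) +
      lp_beta(params$beta) + lp_phi
  }
}

#' Log-posterior of model parameters for one session
#'
#' The session log-likelihood plus the summed log prior densities; `-Inf`
#' outside the parameter support.
#'
#' @param params [simple_params()] or [asym_params()].
#' @param session A [session()].
#' @param priors A [prior_spec()].
#' @param model `"simple"` or `"asymmetric"`.
#' @return A single number (possibly `-Inf`).
#' @export
log_posterior <- function(params, session, priors = prior_spec(),
                          model = model_of(params)) {
  lp <- log_prior(params, priors, model)
  if (!is.finite(lp)) return(-Inf)
  lp + session_loglik(session, params, model)
}

# Unconstrained reparameterisation: logit for rates, log for beta, identity
# for phi. x -> params list (plain list, already validated by construction).
theta_of_x <- function(x, model) {
  if (model == "simple") {
    list(alpha = stats::plogis(x[1L]), beta = exp(x[2L]))
  } else {
    list(alpha_plus = stats::plogis(x[1L]), alpha_minus = stats::plogis(x[2L]),
         beta = exp(x[3L]), phi = x[4L])
  }
}

as_params <- function(theta, model) {
  if (model == "simple") {
    simple_params(theta$alpha, theta$beta)
  } else {
    asym_params(theta$alpha_plus, theta$alpha_minus, theta$beta, theta$phi)
  }
}

# log |d theta / d x| for the transform above (needed when *sampling* on the
# unconstrained scale; the MAP mode is located in the natural space, so the
# optimiser omits it).
log_jacobian <- function(x, model) {
  lj_logit <- function(z) stats::plogis(z, log.p = TRUE) +
    stats::plogis(-z, log.p = TRUE)
  if (model == "simple") lj_logit(x[1L]) + x[2L]
  else lj_logit(x[1L]) + lj_logit(x[2L]) + x[3L]
}

loglik_theta <- function(theta, session, model) {
  if (model == "simple") {
    ll_loop(session$choices, session$rewards, theta$alpha, theta$alpha,
            theta$beta, 0)
  } else {
    ll_loop(session$choices, session$rewards, theta$alpha_plus,
            theta$alpha_minus, theta$beta, theta$phi)
  }
}

logprior_theta <- function(theta, priors, model) {
  log_prior(theta, priors, model)
}

#' MAP estimation of Q-learning parameters
#'
#' Maximises likelihood times prior (the posterior mode) for one session by
#' Nelder-Mead on an unconstrained reparameterisation (logit for learning
#' rates, log for the inverse temperature, identity for the choice trace),
#' keeping the best of `n_restarts` random initialisations.
#'
#' @param session A [session()]. A zero-trial session is allowed (constant
#'   likelihood), in which case the fit returns the prior mode.
#' @param model `"simple"` or `"asymmetric"`.
#' @param priors A [prior_spec()].
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Optional seed; identical seeds give identical fits.
#' @param reltol Relative convergence tolerance on the objective.
#' @return A `map_fit`: list with `model`, `params` (a parameter object),
#'   `log_posterior` and `log_likelihood` at the mode, `n_restarts`,
#'   `best_restart` and `converged`.
#' @export
fit_map <- function(session, model = c("simple", "asymmetric"),
                    priors = prior_spec(), n_restarts = 10, seed = NULL,
                    reltol = 1e-10) {
  model <- match.arg(model)
  stopifnot(is_count(n_restarts), n_restarts >= 1)
  d <- if (model == "simple") 2L else 4L
  negobj <- function(x) {
    theta <- theta_of_x(x, model)
    lp <- logprior_theta(theta, priors, model)
    if (!is.finite(lp)) return(1e10)
    v <- lp + loglik_theta(theta, session, model)
    if (!is.finite(v)) 1e10 else -v
  }
  with_seed(seed, {
    best <- NULL
    values <- numeric(n_restarts)
    any_conv <- FALSE
    for (r in seq_len(n_restarts)) {
      x0 <- if (r == 1L) {
        if (model == "simple") c(0, log(3)) else c(0, 0, log(3), 0)
      } else {
        if (model == "simple") {
          c(stats::rnorm(1, 0, 1.5), stats::rnorm(1, log(3), 1))
        } else {
          c(stats::rnorm(2, 0, 1.5), stats::rnorm(1, log(3), 1),
            stats::rnorm(1, 0, 0.5))
        }
      }
      opt <- stats::optim(x0, negobj, method = "Nelder-Mead",
                          control = list(reltol = reltol, maxit = 2000L))
      values[r] <- -opt$value
      if (opt$convergence == 0L) any_conv <- TRUE
      if (is.null(best) || opt$value < best$value) {
        best <- opt
        best$restart <- r
      }
    }
    if (!is.finite(-best$value) || best$value >= 1e10) {
      stop_config("MAP optimisation failed on all %d restarts", n_restarts)
    }
    theta <- theta_of_x(best$par, model)
    params <- as_params(theta, model)
    structure(
      list(
        model = model, params = params,
        log_posterior = -best$value,
        log_likelihood = loglik_theta(theta, session, model),
        n_restarts = as.integer(n_restarts),
        best_restart = best$restart,
        converged = any_conv,
        restart_log_posteriors = values
      ),
      class = "map_fit"
    )
  })
}

#' @export
print.map_fit <- function(x, ...) {
  cat(sprintf("MAP fit (%s model): log-posterior %.3f, log-likelihood %.3f\n",
              x$model, x$log_posterior, x$log_likelihood))
  print(x$params)
  invisible(x)
}

#' WBIC for one session
#'
#' Computes the widely applicable Bayesian information criterion as the mean
#' log-likelihood over a random-walk Metropolis sample from the posterior
#' tempered at inverse temperature `1 / log(n_trials)` (higher WBIC = better
#' model evidence). Sampling runs on the unconstrained scale with the
#' transform Jacobian included in the target; the Gaussian proposal scale is
#' adapted during burn-in toward ~0.3 acceptance and then frozen.
#'
#' @param session A [session()] with at least 2 trials.
#' @param model `"simple"` or `"asymmetric"`.
#' @param priors A [prior_spec()].
#' @param n_samples Post-burn-in samples (default 5000).
#' @param burn_in Burn-in iterations (default 1000).
#' @param proposal_scale Initial proposal standard deviation per coordinate.
#' @param seed Optional seed; identical seeds give identical results.
#' @return A `wbic_result`: list with `wbic`, `temperature`, `n_samples`,
#'   `burn_in`, `acceptance_rate`, `proposal_scale` (post-adaptation) and
#'   `seed`. Acceptance outside (0.05, 0.95) raises a warning, not an error.
#' @export
compute_wbic <- function(session, model = c("simple", "asymmetric"),
                         priors = prior_spec(), n_samples = 5000,
                         burn_in = 1000, proposal_scale = 0.5, seed = NULL) {
  model <- match.arg(model)
  n <- length(session$choices)
  if (n < 2L) stop_config("WBIC needs at least 2 trials (temperature 1/log n)")
  stopifnot(is_count(n_samples), n_samples >= 1, is_count(burn_in),
            proposal_scale > 0)
  temperature <- 1 / log(n)
  d <- if (model == "simple") 2L else 4L
  target <- function(x) {
    theta <- theta_of_x(x, model)
    lp <- logprior_theta(theta, priors, model)
    if (!is.finite(lp)) return(list(t = -Inf, ll = -Inf))
    ll <- loglik_theta(theta, session, model)
    list(t = lp + log_jacobian(x, model) + temperature * ll, ll = ll)
  }
  with_seed(seed, {
    x <- if (model == "simple") c(0, log(3)) else c(0, 0, log(3), 0)
    cur <- target(x)
    scale <- proposal_scale
    acc_window <- 0L
    lls <- numeric(n_samples)
    n_acc <- 0L
    total <- burn_in + n_samples
    for (i in seq_len(total)) {
      prop <- x + stats::rnorm(d, 0, scale)
      cand <- target(prop)
      if (is.finite(cand$t) &&
          log(stats::runif(1L)) < cand$t - cur$t) {
        x <- prop
        cur <- cand
        if (i <= burn_in) acc_window <- acc_window + 1L else n_acc <- n_acc + 1L
      }
      if (i <= burn_in && i %% 50L == 0L) {
        # Robbins-Monro-style scale adaptation toward 0.3 acceptance
        scale <- min(10, max(1e-3, scale * exp(acc_window / 50 - 0.3)))
        acc_window <- 0L
      }
      if (i > burn_in) lls[i - burn_in] <- cur$ll
    }
    acceptance_rate <- n_acc / n_samples
    if (acceptance_rate < 0.05 || acceptance_rate > 0.95) {
      warning(sprintf("WBIC MCMC acceptance rate %.3f outside (0.05, 0.95)",
                      acceptance_rate))
    }
    structure(
      list(wbic = mean(lls), temperature = temperature,
           n_samples = as.integer(n_samples), burn_in = as.integer(burn_in),
           acceptance_rate = acceptance_rate, proposal_scale = scale,
           model = model, seed = seed),
      class = "wbic_result"
    )
  })
}

#' @export
print.wbic_result <- function(x, ...) {
  cat(sprintf(
    "WBIC (%s model): %.3f (temperature %.4f, acceptance %.2f)\n",
    x$model, x$wbic, x$temperature, x$acceptance_rate
  ))
  invisible(x)
}

#' Compare two models' WBIC values
#'
#' Two-sample pooled-variance t-test on per-session WBIC values with
#' `df = n1 + n2 - 2`.
#'
#' @param wbic_simple,wbic_asym Numeric vectors of WBIC values (or lists of
#'   `wbic_result` objects).
#' @return One-row data frame: `statistic`, `df`, `p_value`, `mean_simple`,
#'   `mean_asym`.
#' @export
compare_models <- function(wbic_simple, wbic_asym) {
  as_num <- function(w) {
    if (is.list(w)) vapply(w, function(z) z$wbic, numeric(1)) else as.numeric(w)
  }
  x <- as_num(wbic_simple)
  y <- as_num(wbic_asym)
  if (!length(x) || !length(y)) stop_config("WBIC vectors must be non-empty")
  if (stats::var(c(x, y)) == 0) {
    # identical constant lists: t = 0 by convention
    return(data.frame(statistic = 0, df = length(x) + length(y) - 2,
                      p_value = 1, mean_simple = mean(x), mean_asym = mean(y)))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  data.frame(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, mean_simple = mean(x), mean_asym = mean(y)
  )
}

sessions_of <- function(x) {
  if (inherits(x, "bandit_dataset")) x$sessions
  else if (inherits(x, "session")) list(x)
  else x
}

#' Fit every session of a dataset by MAP
#'
#' @param x A `bandit_dataset` or list of [session()]s.
#' @param model `"simple"` or `"asymmetric"`.
#' @param priors A [prior_spec()].
#' @param n_restarts Restarts per fit.
#' @param seed Optional seed covering the whole run.
#' @return Data frame with one row per unit: identifiers, fitted parameters
#'   (`bias` is `alpha_plus - alpha_minus`), `log_posterior`,
#'   `log_likelihood`, `converged`.
#' @export
fit_sessions <- function(x, model = c("simple", "asymmetric"),
                         priors = prior_spec(), n_restarts = 10, seed = NULL) {
  model <- match.arg(model)
  sess <- sessions_of(x)
  with_seed(seed, {
    rows <- lapply(sess, function(s) {
      f <- fit_map(s, model, priors, n_restarts)
      p <- f$params
      data.frame(
        unit_id = s$unit_id, size = s$size, model = model,
        alpha = if (model == "simple") p$alpha else NA_real_,
        alpha_plus = if (model == "asymmetric") p$alpha_plus else NA_real_,
        alpha_minus = if (model == "asymmetric") p$alpha_minus else NA_real_,
        bias = if (model == "asymmetric") p$alpha_plus - p$alpha_minus
               else NA_real_,
        beta = p$beta,
        phi = if (model == "asymmetric") p$phi else NA_real_,
        log_posterior = f$log_posterior, log_likelihood = f$log_likelihood,
        converged = f$converged, stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Compute WBIC for every session of a dataset
#'
#' @inheritParams fit_sessions
#' @param n_samples,burn_in MCMC settings per session.
#' @return Data frame with one row per unit: `unit_id`, `size`, `model`,
#'   `wbic`, `temperature`, `acceptance_rate`.
#' @export
wbic_sessions <- function(x, model = c("simple", "asymmetric"),
                          priors = prior_spec(), n_samples = 5000,
                          burn_in = 1000, seed = NULL) {
  model <- match.arg(model)
  sess <- sessions_of(x)
  with_seed(seed, {
    rows <- lapply(sess, function(s) {
      w <- compute_wbic(s, model, priors, n_samples, burn_in)
      data.frame(
        unit_id = s$unit_id, size = s$size, model = model, wbic = w$wbic,
        temperature = w$temperature, acceptance_rate = w$acceptance_rate,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}
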