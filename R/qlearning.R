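#' Q-learning model parameters
#'
#' `simple_params()` holds the two parameters of the simple Q-learning model:
#' a learning rate `alpha` in (0, 1] scaling the reward prediction error, and
#' a softmax inverse temperature `beta >= 0` (exploitation weight).
#' `asym_params()` adds asymmetric learning: `alpha_plus` applies when the
#' prediction error is non-negative, `alpha_minus` when it is negative
#' (`alpha_plus - alpha_minus` is the positivity bias), and `phi` is a choice
#' trace added to the chosen arm's value on every update, capturing choice
#' perseveration.
#'
#' Rewards enter the models on a 0/1 scale (the 10-point display value is
#' task metadata), so `beta` is interpreted against unit-scaled action
#' values.
#'
#' @param alpha,alpha_plus,alpha_minus Learning rates in (0, 1].
#' @param beta Inverse temperature, non-negative.
#' @param phi Choice-trace increment (any real, unit-reward scale).
#' @return A parameter object of class `simple_params` or `asym_params`.
#' @examples
#' simple_params(alpha = 0.5, beta = 4)
#' asym_params(alpha_plus = 0.6, alpha_minus = 0.3, beta = 4, phi = 0.05)
#' @export
simple_params <- function(alpha, beta) {
  check_rate(alpha, "alpha")
  check_beta(beta)
  structure(list(alpha = alpha, beta = beta), class = "simple_params")
}

#' @rdname simple_params
#' @export
asym_params <- function(alpha_plus, alpha_minus, beta, phi = 0) {
  check_rate(alpha_plus, "alpha_plus")
  check_rate(alpha_minus, "alpha_minus")
  check_beta(beta)
  stopifnot(is.numeric(phi), length(phi) == 1L, is.finite(phi))
  structure(
    list(alpha_plus = alpha_plus, alpha_minus = alpha_minus,
         beta = beta, phi = phi),
    class = "asym_params"
  )
}

check_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x > 1) {
    stop_config("%s must lie in (0, 1]", name)
  }
}
check_beta <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !is.finite(x)) {
    stop_config("beta must be finite and >= 0")
  }
}

#' @export
print.simple_params <- function(x, ...) {
  cat(sprintf("simple Q-learning params: alpha = %.4g, beta = %.4g\n",
              x$alpha, x$beta))
  invisible(x)
}

#' @export
print.asym_params <- function(x, ...) {
  cat(sprintf(
    "asymmetric Q-learning params: alpha+ = %.4g, alpha- = %.4g, beta = %.4g, phi = %.4g\n",
    x$alpha_plus, x$alpha_minus, x$beta, x$phi
  ))
  invisible(x)
}

model_of <- function(params) {
  if (inherits(params, "simple_params")) "simple"
  else if (inherits(params, "asym_params")) "asymmetric"
  else if (is.list(params) && all(c("alpha_plus", "alpha_minus") %in%
                                  names(params))) "asymmetric"
  else if (is.list(params) && "alpha" %in% names(params)) "simple"
  else stop_config("params must be simple_params or asym_params")
}

#' Initial action-value state
#'
#' Both arms start at Q = 0 on trial 1.
#'
#' @param trial Current trial index (default 1).
#' @return A `q_state`: list with `q` (length-2 numeric) and `trial`.
#' @export
q_state <- function(trial = 1L) {
  structure(list(q = c(left = 0, right = 0), trial = as.integer(trial)),
            class = "q_state")
}

#' Softmax choice probabilities over the two arms
#'
#' P(arm i) = exp(beta * Q_i) / sum_j exp(beta * Q_j), computed with
#' max-subtraction so large `beta * Q` never overflows. `beta = 0` gives the
#' uniform policy.
#'
#' @param state A [q_state()] or a length-2 numeric vector of action values.
#' @param beta Inverse temperature, non-negative.
#' @return Length-2 probability vector (left, right), summing to 1.
#' @export
softmax_policy <- function(state, beta) {
  check_beta(beta)
  q <- if (inherits(state, "q_state")) state$q else state
  stopifnot(is.numeric(q), length(q) == 2L, all(is.finite(q)))
  z <- beta * q
  z <- z - max(z)
  e <- exp(z)
  p <- e / sum(e)
  names(p) <- ARM_LABELS
  p
}

#' One Q-learning update
#'
#' `update_simple()` applies the delta rule to the chosen arm:
#' `Q <- Q + alpha * (R - Q)`; the unchosen arm is unchanged.
#' `update_asymmetric()` uses `alpha_plus` when the prediction error
#' `delta = R - Q` is non-negative (the boundary `delta = 0` is inclusive)
#' and `alpha_minus` when negative, and adds the choice trace `phi` to the
#' chosen arm.
#'
#' @param state A [q_state()].
#' @param choice Chosen arm, label or index.
#' @param reward Reward in \{0, 1\}.
#' @param params [simple_params()] or [asym_params()].
#' @return List with `state` (updated `q_state`, trial advanced) and `trace`
#'   (list `delta`, `branch` in `"simple"`/`"plus"`/`"minus"`).
#' @export
update_simple <- function(state, choice, reward, params) {
  stopifnot(inherits(state, "q_state"), inherits(params, "simple_params"))
  i <- arm_index(choice)
  reward <- check_reward(reward)
  delta <- reward - state$q[[i]]
  state$q[[i]] <- state$q[[i]] + params$alpha * delta
  state$trial <- state$trial + 1L
  list(state = state, trace = list(delta = delta, branch = "simple"))
}

#' @rdname update_simple
#' @export
update_asymmetric <- function(state, choice, reward, params) {
  stopifnot(inherits(state, "q_state"), inherits(params, "asym_params"))
  i <- arm_index(choice)
  reward <- check_reward(reward)
  delta <- reward - state$q[[i]]
  branch <- if (delta >= 0) "plus" else "minus"
  rate <- if (delta >= 0) params$alpha_plus else params$alpha_minus
  state$q[[i]] <- state$q[[i]] + rate * delta + params$phi
  state$trial <- state$trial + 1L
  list(state = state, trace = list(delta = delta, branch = branch))
}

check_reward <- function(reward) {
  if (!is.numeric(reward) || length(reward) != 1L || !(reward %in% c(0, 1))) {
    stop_config("reward must be 0 or 1")
  }
  as.numeric(reward)
}

# Fast internal trial loop shared by likelihood and its callers.
# choices: integer 1/2; rewards: 0/1. Simple model: ap = am = alpha, phi = 0.
# Returns the summed log choice probability under sequential Q updates from 0.
ll_loop <- function(choices, rewards, ap, am, beta, phi) {
  q1 <- 0; q2 <- 0; ll <- 0
  for (t in seq_along(choices)) {
    d <- beta * (q1 - q2)
    # log P(chosen) via the stable two-option logistic
    ll <- ll + stats::plogis(if (choices[t] == 1L) d else -d, log.p = TRUE)
    if (choices[t] == 1L) {
      delta <- rewards[t] - q1
      q1 <- q1 + (if (delta >= 0) ap else am) * delta + phi
    } else {
      delta <- rewards[t] - q2
      q2 <- q2 + (if (delta >= 0) ap else am) * delta + phi
    }
  }
  ll
}

#' Session log-likelihood under a Q-learning model
#'
#' Replays the observed choices and rewards from `Q(1) = 0`, updating action
#' values with the model's rule, and sums the log softmax probability of each
#' observed choice.
#'
#' @param session A [session()] (or any list with integer `choices` in
#'   \{1, 2\} and `rewards` in \{0, 1\}).
#' @param params [simple_params()] or [asym_params()]; must match `model`.
#' @param model `"simple"` or `"asymmetric"`; defaults to the class of
#'   `params`.
#' @return The log-likelihood (a single number; `<= 0` whenever `phi = 0`).
#' @export
session_loglik <- function(session, params, model = model_of(params)) {
  model <- match.arg(model, c("simple", "asymmetric"))
  if (inherits(params, c("simple_params", "asym_params")) &&
      model != model_of(params)) {
    stop_config("params class does not match model '%s'", model)
  }
  ch <- session$choices
  rw <- session$rewards
  if (length(ch) != length(rw)) {
    stop_config("choices and rewards differ in length (%d vs %d)",
                length(ch), length(rw))
  }
  if (model == "simple") {
    ll_loop(ch, rw, params$alpha, params$alpha, params$beta, 0)
  } else {
    ll_loop(ch, rw, params$alpha_plus, params$alpha_minus,
            params$beta, params$phi)
  }
}
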