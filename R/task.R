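#' Two-armed bandit task configuration
#'
#' Describes a reversal-learning two-armed bandit: one arm pays off with
#' probability `p_advantageous`, the other with `p_disadvantageous`, and the
#' roles swap after each trial listed in `reversal_trials`. With the defaults
#' the right arm pays 70% on trials 1-30, 30% on 31-70 and 70% again on
#' 71-100. Rewards are binary; `reward_points` is only the displayed value of
#' a win.
#'
#' Trials are 1-based; a reversal "at trial r" means the swap takes effect
#' from trial r + 1 onward.
#'
#' @param n_trials Number of trials per session (default 100).
#' @param p_advantageous Win probability of the advantageous arm (default 0.7).
#' @param p_disadvantageous Win probability of the disadvantageous arm
#'   (default 0.3).
#' @param reversal_trials Strictly increasing trial indices after which the
#'   arm roles swap; each must lie in `[1, n_trials - 1]`. Default `c(30, 70)`.
#' @param initial_advantageous_arm `"left"` or `"right"` (default `"right"`).
#' @param reward_points Points displayed per win (metadata only, default 10).
#' @return An object of class `task_config`.
#' @examples
#' cfg <- task_config()
#' sch <- build_schedule(cfg)
#' head(as.data.frame(sch))
#' @export
task_config <- function(n_trials = 100,
                        p_advantageous = 0.70,
                        p_disadvantageous = 0.30,
                        reversal_trials = c(30, 70),
                        initial_advantageous_arm = "right",
                        reward_points = 10) {
  if (!is_count(n_trials) || n_trials < 1) {
    stop_config("n_trials must be a positive integer")
  }
  if (!is_prob(p_advantageous) || !is_prob(p_disadvantageous) ||
      !(p_disadvantageous < p_advantageous)) {
    stop_config("need 0 <= p_disadvantageous < p_advantageous <= 1")
  }
  reversal_trials <- as.numeric(reversal_trials)
  if (length(reversal_trials)) {
    if (any(reversal_trials != floor(reversal_trials)) ||
        any(reversal_trials < 1) || any(reversal_trials >= n_trials)) {
      stop_config("reversal_trials must be integers in [1, n_trials - 1]")
    }
    if (any(diff(reversal_trials) <= 0)) {
      stop_config("reversal_trials must be strictly increasing")
    }
  }
  initial_advantageous_arm <- match.arg(initial_advantageous_arm, ARM_LABELS)
  structure(
    list(
      n_trials = as.integer(n_trials),
      p_advantageous = p_advantageous,
      p_disadvantageous = p_disadvantageous,
      reversal_trials = as.integer(reversal_trials),
      initial_advantageous_arm = initial_advantageous_arm,
      reward_points = reward_points
    ),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf(
    "Two-armed bandit task: %d trials, p = %.2f/%.2f, %s arm advantageous first\n",
    x$n_trials, x$p_advantageous, x$p_disadvantageous,
    x$initial_advantageous_arm
  ))
  cat(sprintf(
    "reversals after trials: %s\n",
    if (length(x$reversal_trials)) paste(x$reversal_trials, collapse = ", ")
    else "(none)"
  ))
  invisible(x)
}

#' Build the per-trial reward schedule
#'
#' Expands a [task_config()] into an `n_trials x 2` matrix of win
#' probabilities (columns `left`, `right`). Every row is a permutation of
#' `{p_advantageous, p_disadvantageous}` and rows change only after reversal
#' trials.
#'
#' @param config A [task_config()].
#' @return A `tab_schedule`: the win-probability matrix with the config as an
#'   attribute. Use `as.data.frame()` to get a `(trial, p_left, p_right)`
#'   table for export.
#' @export
build_schedule <- function(config) {
  stopifnot(inherits(config, "task_config"))
  n <- config$n_trials
  adv <- matrix(0, nrow = n, ncol = 2, dimnames = list(NULL, ARM_LABELS))
  # segment boundaries: 1 .. r1 | r1+1 .. r2 | ...
  bounds <- c(0L, config$reversal_trials, n)
  adv_arm <- arm_index(config$initial_advantageous_arm)
  win <- adv
  for (s in seq_len(length(bounds) - 1L)) {
    rows <- (bounds[s] + 1L):bounds[s + 1L]
    win[rows, adv_arm] <- config$p_advantageous
    win[rows, 3L - adv_arm] <- config$p_disadvantageous
    adv_arm <- 3L - adv_arm
  }
  structure(win, class = c("tab_schedule", "matrix"), config = config)
}

#' @export
as.data.frame.tab_schedule <- function(x, ...) {
  data.frame(
    trial = seq_len(nrow(x)),
    p_left = unname(x[, 1L]),
    p_right = unname(x[, 2L])
  )
}

#' @export
print.tab_schedule <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Reward schedule: %d trials x 2 arms\n", nrow(x)))
  if (!is.null(cfg)) print(cfg)
  invisible(x)
}

#' Sample a binary reward from the schedule
#'
#' Draws reward 1 with the scheduled win probability of `arm` at `trial`,
#' else 0, advancing the global RNG stream by one uniform draw.
#'
#' @param schedule A [build_schedule()] result.
#' @param trial 1-based trial index.
#' @param arm Arm label (`"left"`/`"right"`) or index (1/2).
#' @return Integer reward, 0 or 1.
#' @export
sample_reward <- function(schedule, trial, arm) {
  if (!is_count(trial) || trial < 1 || trial > nrow(schedule)) {
    stop_config("trial %s out of range 1..%d", format(trial), nrow(schedule))
  }
  a <- arm_index(arm)
  as.integer(stats::runif(1L) < schedule[trial, a])
}
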