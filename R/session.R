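#' A bandit session
#'
#' One decision-making unit's complete record of a two-armed bandit run: the
#' chosen arm and binary reward at each trial, plus unit metadata (size 1 =
#' individual, 2 = dyad, 3 = triad). Synthetic sessions additionally carry
#' their generating ground truth.
#'
#' @param unit_id Unit identifier.
#' @param choices Integer vector of chosen arms (1 = left, 2 = right) or arm
#'   labels.
#' @param rewards Integer vector of rewards in \{0, 1\}, same length.
#' @param size Unit size, 1, 2 or 3.
#' @param member_ids Character vector of member identifiers
#'   (length = `size`).
#' @param schedule Optional `tab_schedule` the session was played on.
#' @param test_id Optional test label (e.g. `"test1"`).
#' @param ground_truth Optional list of generating parameters/coherence
#'   (synthetic data only).
#' @return An object of class `session`.
#' @export
session <- function(unit_id, choices, rewards, size = 1L,
                    member_ids = as.character(unit_id), schedule = NULL,
                    test_id = NA_character_, ground_truth = NULL) {
  choices <- arm_index(choices)
  rewards <- as.integer(rewards)
  if (length(choices) != length(rewards)) {
    stop_config("choices and rewards differ in length")
  }
  if (length(rewards) && !all(rewards %in% c(0L, 1L))) {
    stop_config("rewards must all be 0 or 1")
  }
  size <- as.integer(size)
  if (!size %in% 1:3) stop_config("size must be 1, 2 or 3")
  member_ids <- as.character(member_ids)
  if (length(member_ids) != size) {
    stop_config("length(member_ids) must equal size")
  }
  structure(
    list(
      unit_id = as.character(unit_id), size = size, member_ids = member_ids,
      choices = choices, rewards = rewards, schedule = schedule,
      test_id = test_id, ground_truth = ground_truth
    ),
    class = "session"
  )
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf(
    "Bandit session %s (size %d, members: %s): %d trials, performance %d\n",
    x$unit_id, x$size, paste(x$member_ids, collapse = ","),
    length(x$choices), performance(x)
  ))
  invisible(x)
}

#' Session performance: number of rewarded trials
#'
#' The performance measure is the count of trials that paid off; total points
#' are this count times the task's `reward_points` (10 by default).
#'
#' @param session A [session()].
#' @return Integer count of rewarded trials.
#' @export
performance <- function(session) {
  sum(session$rewards)
}
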