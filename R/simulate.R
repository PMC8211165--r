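#' Population distribution of member parameters
#'
#' Members' true learning parameters are drawn independently from weakly
#' informative population distributions: learning rates from
#' `Beta(alpha_shape1, alpha_shape2)`, inverse temperatures from
#' `Gamma(beta_shape, scale = beta_scale)`, and choice traces from
#' `Normal(phi_mean, phi_sd)`. The defaults (Beta(2, 2); Gamma(2, scale 2.5),
#' mean 5; Normal(0, 0.1)) are centred near the magnitudes typical of human
#' bandit fits without asserting any particular sample's values.
#'
#' @param alpha_shape1,alpha_shape2 Beta hyperparameters for learning rates.
#' @param beta_shape,beta_scale Gamma hyperparameters for the inverse
#'   temperature.
#' @param phi_mean,phi_sd Normal hyperparameters for the choice trace.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(alpha_shape1 = 2, alpha_shape2 = 2,
                            beta_shape = 2, beta_scale = 2.5,
                            phi_mean = 0, phi_sd = 0.1) {
  stopifnot(alpha_shape1 > 0, alpha_shape2 > 0, beta_shape > 0,
            beta_scale > 0, phi_sd > 0)
  structure(
    list(alpha_shape1 = alpha_shape1, alpha_shape2 = alpha_shape2,
         beta_shape = beta_shape, beta_scale = beta_scale,
         phi_mean = phi_mean, phi_sd = phi_sd),
    class = "population_spec"
  )
}

#' A group member with ground-truth parameters
#'
#' @param member_id Identifier.
#' @param params [simple_params()] or [asym_params()].
#' @return An object of class `member_profile`.
#' @export
member_profile <- function(member_id, params) {
  model_of(params) # validates class
  structure(list(member_id = as.character(member_id), params = params),
            class = "member_profile")
}

#' Draw member profiles from a population
#'
#' @param n Number of members.
#' @param population A [population_spec()].
#' @param model `"simple"` or `"asymmetric"`.
#' @param ids Optional character vector of member ids.
#' @return List of [member_profile()] objects. Uses the global RNG stream.
#' @export
sample_members <- function(n, population = population_spec(),
                           model = c("simple", "asymmetric"),
                           ids = sprintf("M%04d", seq_len(n))) {
  model <- match.arg(model)
  stopifnot(is_count(n), length(ids) == n)
  draw_rate <- function(k) {
    a <- stats::rbeta(k, population$alpha_shape1, population$alpha_shape2)
    pmin(pmax(a, 1e-6), 1) # keep inside (0, 1]
  }
  lapply(seq_len(n), function(i) {
    if (model == "simple") {
      p <- simple_params(
        alpha = draw_rate(1),
        beta = stats::rgamma(1, population$beta_shape,
                             scale = population$beta_scale)
      )
    } else {
      p <- asym_params(
        alpha_plus = draw_rate(1),
        alpha_minus = draw_rate(1),
        beta = stats::rgamma(1, population$beta_shape,
                             scale = population$beta_scale),
        phi = stats::rnorm(1, population$phi_mean, population$phi_sd)
      )
    }
    member_profile(ids[i], p)
  })
}

# Core generative trial loop, shared by agent and group simulation so that a
# singleton "group" consumes the identical random stream as an agent.
# win: n x 2 win-probability matrix; per-member parameter vectors; c_coh in
# [0,1]; controller_only: if TRUE, on incoherent trials only the controlling
# member updates their action values.
sim_loop <- function(win, ap, am, betas, phis, c_coh, controller_only) {
  k <- length(betas)
  q <- matrix(0, nrow = k, ncol = 2)
  n <- nrow(win)
  choices <- integer(n)
  rewards <- integer(n)
  mean_beta <- mean(betas)
  for (t in seq_len(n)) {
    if (k == 1L) {
      coh <- TRUE
    } else {
      coh <- stats::runif(1L) < c_coh
      if (!coh) m <- sample.int(k, 1L)
    }
    d <- if (coh) {
      mean_beta * (mean(q[, 1L]) - mean(q[, 2L]))
    } else {
      betas[m] * (q[m, 1L] - q[m, 2L])
    }
    ch <- if (stats::runif(1L) < stats::plogis(d)) 1L else 2L
    r <- as.integer(stats::runif(1L) < win[t, ch])
    choices[t] <- ch
    rewards[t] <- r
    upd <- if (coh || !controller_only) seq_len(k) else m
    delta <- r - q[upd, ch]
    rate <- ifelse(delta >= 0, ap[upd], am[upd])
    q[upd, ch] <- q[upd, ch] + rate * delta + phis[upd]
  }
  list(choices = choices, rewards = rewards)
}

params_vectors <- function(params_list) {
  get1 <- function(p, plus) {
    if (inherits(p, "simple_params")) p$alpha
    else if (plus) p$alpha_plus else p$alpha_minus
  }
  list(
    ap = vapply(params_list, get1, numeric(1), plus = TRUE),
    am = vapply(params_list, get1, numeric(1), plus = FALSE),
    betas = vapply(params_list, function(p) p$beta, numeric(1)),
    phis = vapply(params_list,
                  function(p) if (is.null(p$phi)) 0 else p$phi, numeric(1))
  )
}

#' Simulate one agent playing the bandit
#'
#' Choices are sampled from the softmax policy each trial; the chosen arm's
#' value is updated with the model's rule using the sampled reward.
#'
#' @param params [simple_params()] or [asym_params()].
#' @param task A [task_config()].
#' @param unit_id,member_id Identifiers recorded on the session.
#' @return A [session()] of `task$n_trials` trials with ground truth attached.
#'   Uses the global RNG stream.
#' @export
simulate_agent_session <- function(params, task = task_config(),
                                   unit_id = "agent", member_id = unit_id) {
  simulate_group_session(list(member_profile(member_id, params)),
                         coherence = 1, task = task, unit_id = unit_id)
}

#' Simulate a group session under the learning-coherence model
#'
#' Each trial is either *coherent* (with probability `coherence`): the group
#' chooses by a consensus softmax over the member-averaged action values with
#' the member-averaged inverse temperature, and every member updates their
#' values on the outcome; or *incoherent*: a uniformly chosen member's own
#' policy controls the trial. Under the default
#' `incoherent_updates = "controller"`, only that controlling member updates
#' their action values on incoherent trials — non-controlling members
#' disengage, which is what makes sustained incoherence (dyads) costly.
#' `incoherent_updates = "all"` keeps every member updating on the shared
#' stream regardless of control. A singleton group is exactly
#' [simulate_agent_session()] (identical output under identical seeds).
#'
#' @param members List of 1-3 [member_profile()]s with same-model parameters.
#' @param coherence Probability of a coherent (consensus) trial, in [0, 1].
#' @param task A [task_config()].
#' @param incoherent_updates `"controller"` or `"all"`.
#' @param unit_id,test_id Identifiers recorded on the session.
#' @return A [session()] with ground truth (members, parameters, coherence).
#'   Uses the global RNG stream.
#' @export
simulate_group_session <- function(members, coherence,
                                   task = task_config(),
                                   incoherent_updates = c("controller", "all"),
                                   unit_id = "group",
                                   test_id = NA_character_) {
  incoherent_updates <- match.arg(incoherent_updates)
  if (!length(members)) stop_config("members must contain 1-3 member profiles")
  if (length(members) > 3L) stop_config("groups larger than 3 are not supported")
  if (!is_prob(coherence)) stop_config("coherence must lie in [0, 1]")
  stopifnot(all(vapply(members, inherits, logical(1), "member_profile")))
  params_list <- lapply(members, `[[`, "params")
  models <- vapply(params_list, model_of, character(1))
  if (length(unique(models)) != 1L) {
    stop_config("all members must use the same model")
  }
  sch <- build_schedule(task)
  pv <- params_vectors(params_list)
  out <- sim_loop(unclass(sch), pv$ap, pv$am, pv$betas, pv$phis,
                  coherence, incoherent_updates == "controller")
  session(
    unit_id = unit_id,
    choices = out$choices,
    rewards = out$rewards,
    size = length(members),
    member_ids = vapply(members, `[[`, character(1), "member_id"),
    schedule = sch,
    test_id = test_id,
    ground_truth = list(
      model = models[1L],
      coherence = coherence,
      incoherent_updates = incoherent_updates,
      members = members
    )
  )
}

#' Design of a synthetic individuals/dyads/triads study
#'
#' Defaults mimic the scale of a large classroom study: 322 individual
#' sessions, 138 dyads and 108 triads, with every group member also playing
#' an individual session (`membership_overlap`). Coherence defaults encode
#' the learning-coherence hypothesis: individuals are trivially coherent
#' (c = 1), dyads — where no majority can form — are largely incoherent
#' (c = 0.1), and triads — where majority rule operates — are largely
#' coherent (c = 0.9).
#'
#' @param n_individual_sessions,n_dyads,n_triads Unit counts per size.
#' @param coherence Length-3 numeric: coherence for sizes 1, 2, 3.
#' @param population A [population_spec()].
#' @param membership_overlap If `TRUE` (default), group members are drawn
#'   from the pool of individual-session members, so every dyad/triad member
#'   also has an individual session.
#' @param model `"simple"` or `"asymmetric"` generative model.
#' @param task A [task_config()].
#' @param incoherent_updates Passed to [simulate_group_session()].
#' @param seed Optional integer seed making [generate_dataset()] fully
#'   reproducible.
#' @return An object of class `group_design`.
#' @export
group_design <- function(n_individual_sessions = 322,
                         n_dyads = 138,
                         n_triads = 108,
                         coherence = c(1, 0.1, 0.9),
                         population = population_spec(),
                         membership_overlap = TRUE,
                         model = c("simple", "asymmetric"),
                         task = task_config(),
                         incoherent_updates = c("controller", "all"),
                         seed = NULL) {
  model <- match.arg(model)
  incoherent_updates <- match.arg(incoherent_updates)
  stopifnot(is_count(n_individual_sessions), is_count(n_dyads),
            is_count(n_triads), inherits(population, "population_spec"),
            inherits(task, "task_config"))
  coherence <- as.numeric(coherence)
  if (length(coherence) != 3L || !all(vapply(coherence, is_prob, logical(1)))) {
    stop_config("coherence must be 3 probabilities (sizes 1, 2, 3)")
  }
  structure(
    list(
      n_individual_sessions = as.integer(n_individual_sessions),
      n_dyads = as.integer(n_dyads), n_triads = as.integer(n_triads),
      coherence = coherence, population = population,
      membership_overlap = isTRUE(membership_overlap), model = model,
      task = task, incoherent_updates = incoherent_updates, seed = seed
    ),
    class = "group_design"
  )
}

gt_row <- function(unit_id, size, coherence, model, member) {
  p <- member$params
  data.frame(
    unit_id = unit_id, size = size, member_id = member$member_id,
    coherence = coherence, model = model,
    alpha = if (model == "simple") p$alpha else NA_real_,
    alpha_plus = if (model == "asymmetric") p$alpha_plus else NA_real_,
    alpha_minus = if (model == "asymmetric") p$alpha_minus else NA_real_,
    beta = p$beta,
    phi = if (model == "asymmetric") p$phi else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Generate a ground-truth-labelled synthetic dataset
#'
#' Draws a member pool from the design's population, gives every pool member
#' an individual session, and simulates dyads and triads whose members are
#' sampled (without replacement within a group) from that pool, each size
#' playing under its designed coherence. The run is fully reproducible from
#' `design$seed`.
#'
#' @param design A [group_design()].
#' @return A `bandit_dataset`: list with `sessions` (list of [session()]s),
#'   `units` (one row per unit), `ground_truth` (one row per unit-member with
#'   the generating parameters) and the `design`.
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "group_design"))
  with_seed(design$seed, {
    n_ind <- design$n_individual_sessions
    pool <- sample_members(n_ind, design$population, design$model)
    sessions <- list()
    units <- list()
    gt <- list()
    add_unit <- function(sess) {
      sessions[[length(sessions) + 1L]] <<- sess
      units[[length(units) + 1L]] <<- data.frame(
        unit_id = sess$unit_id, size = sess$size,
        member_ids = paste(sess$member_ids, collapse = ";"),
        test_id = sess$test_id, stringsAsFactors = FALSE
      )
      for (m in sess$ground_truth$members) {
        gt[[length(gt) + 1L]] <<- gt_row(sess$unit_id, sess$size,
                                         sess$ground_truth$coherence,
                                         sess$ground_truth$model, m)
      }
    }
    for (i in seq_len(n_ind)) {
      add_unit(simulate_group_session(
        pool[i], coherence = design$coherence[1L], task = design$task,
        incoherent_updates = design$incoherent_updates,
        unit_id = sprintf("I%04d", i), test_id = "test1"
      ))
    }
    make_groups <- function(n_groups, size, prefix, test_id) {
      for (g in seq_len(n_groups)) {
        if (design$membership_overlap) {
          if (n_ind < size) {
            stop_config(
              "membership_overlap requires at least %d individual members", size
            )
          }
          members <- pool[sample.int(n_ind, size)]
        } else {
          members <- sample_members(
            size, design$population, design$model,
            ids = sprintf("%s%03d_m%d", prefix, g, seq_len(size))
          )
        }
        add_unit(simulate_group_session(
          members, coherence = design$coherence[size], task = design$task,
          incoherent_updates = design$incoherent_updates,
          unit_id = sprintf("%s%04d", prefix, g), test_id = test_id
        ))
      }
    }
    make_groups(design$n_dyads, 2L, "D", "test2")
    make_groups(design$n_triads, 3L, "T", "test3")
    empty_units <- data.frame(unit_id = character(), size = integer(),
                              member_ids = character(), test_id = character(),
                              stringsAsFactors = FALSE)
    structure(
      list(
        sessions = sessions,
        units = if (length(units)) do.call(rbind, units) else empty_units,
        ground_truth = if (length(gt)) do.call(rbind, gt) else NULL,
        design = design
      ),
      class = "bandit_dataset"
    )
  })
}

#' @export
print.bandit_dataset <- function(x, ...) {
  tab <- table(factor(x$units$size, levels = 1:3))
  cat(sprintf(
    "Synthetic bandit dataset: %d units (%d individuals, %d dyads, %d triads)\n",
    nrow(x$units), tab[[1]], tab[[2]], tab[[3]]
  ))
  invisible(x)
}
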