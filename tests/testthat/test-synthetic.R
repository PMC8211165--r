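test_that("agent sessions have the task's length and carry ground truth", {
  set.seed(21)
  s <- simulate_agent_session(simple_params(0.5, 3))
  expect_equal(length(s$choices), 100)
  expect_equal(length(s$rewards), 100)
  expect_equal(s$ground_truth$model, "simple")
  s2 <- simulate_agent_session(asym_params(0.6, 0.3, 2, 0.05),
                               task_config(n_trials = 40,
                                           reversal_trials = c(15, 30)))
  expect_equal(length(s2$choices), 40)
})

test_that("a beta = 0 agent earns the random-policy rate of 50/100", {
  set.seed(22)
  perf <- replicate(1000, performance(
    simulate_agent_session(simple_params(0.5, 0))
  ))
  # random policy earns (0.7 + 0.3)/2 per trial; 3 SE band
  se <- sd(perf) / sqrt(length(perf))
  expect_lt(abs(mean(perf) - 50), 3 * se)
})

test_that("a sharp learner outperforms a random chooser", {
  set.seed(23)
  sharp <- replicate(500, performance(
    simulate_agent_session(simple_params(0.6, 6))
  ))
  rand <- replicate(500, performance(
    simulate_agent_session(simple_params(0.6, 0))
  ))
  expect_gt(mean(sharp), mean(rand))
})

test_that("a singleton group reproduces the agent simulation exactly", {
  p <- asym_params(0.55, 0.35, 4, 0.02)
  m <- member_profile("m1", p)
  for (cc in c(0, 0.4, 1)) {
    set.seed(24)
    g <- simulate_group_session(list(m), coherence = cc, unit_id = "u")
    set.seed(24)
    a <- simulate_agent_session(p, unit_id = "u", member_id = "m1")
    expect_identical(g$choices, a$choices)
    expect_identical(g$rewards, a$rewards)
  }
})

test_that("a shared-learning dyad of identical members behaves like one agent", {
  p <- simple_params(0.5, 4)
  set.seed(25)
  # under shared-stream updates, identical members make every controller's
  # policy the same function, so performance is distributionally the same
  dy <- replicate(400, performance(simulate_group_session(
    list(member_profile("a", p), member_profile("b", p)), coherence = 0,
    incoherent_updates = "all"
  )))
  ag <- replicate(400, performance(simulate_agent_session(p)))
  expect_gt(wilcox.test(dy, ag)$p.value, 0.01)
})

test_that("controller-only learning makes even identical-member dyads worse", {
  p <- simple_params(0.5, 4)
  set.seed(125)
  dy <- replicate(400, performance(simulate_group_session(
    list(member_profile("a", p), member_profile("b", p)), coherence = 0
  )))
  ag <- replicate(400, performance(simulate_agent_session(p)))
  # disengaged members learn from only part of the stream; this is the
  # mechanism that makes sustained incoherence costly
  expect_lt(mean(dy), mean(ag))
})

test_that("mixed-control dyads show an effective beta between the members'", {
  set.seed(26)
  n <- 120
  betas <- replicate(n, {
    mem <- list(member_profile("lo", simple_params(0.5, 1)),
                member_profile("hi", simple_params(0.5, 8)))
    g <- simulate_group_session(mem, coherence = 0)
    fit_map(g, "simple", n_restarts = 4)$params$beta
  })
  expect_gt(mean(betas), 1)
  expect_lt(mean(betas), 8)
})

test_that("raising coherence does not decrease the fitted group beta", {
  set.seed(27)
  pop <- population_spec()
  mean_beta <- vapply(c(0, 0.5, 1), function(cc) {
    mean(replicate(80, {
      mem <- sample_members(2, pop)
      g <- simulate_group_session(mem, coherence = cc)
      fit_map(g, "simple", n_restarts = 3)$params$beta
    }))
  }, numeric(1))
  expect_true(all(diff(mean_beta) >= 0))
})

test_that("generate_dataset emits the designed unit counts", {
  ds <- generate_dataset(group_design(12, 5, 4, seed = 28))
  expect_equal(sum(ds$units$size == 1), 12)
  expect_equal(sum(ds$units$size == 2), 5)
  expect_equal(sum(ds$units$size == 3), 4)
  expect_equal(length(ds$sessions), 21)
  # ground truth consistent with sessions: same unit ids, one row per member
  expect_setequal(unique(ds$ground_truth$unit_id), ds$units$unit_id)
  expect_equal(nrow(ds$ground_truth), 12 + 5 * 2 + 4 * 3)
})

test_that("an all-zero design yields an empty dataset without error", {
  ds <- generate_dataset(group_design(0, 0, 0, seed = 1))
  expect_equal(length(ds$sessions), 0)
  expect_equal(nrow(ds$units), 0)
})

test_that("membership overlap gives every group member an individual session", {
  ds <- generate_dataset(group_design(10, 6, 6, seed = 29))
  ind_members <- ds$units$member_ids[ds$units$size == 1]
  grp <- ds$units[ds$units$size > 1, ]
  for (i in seq_len(nrow(grp))) {
    members <- strsplit(grp$member_ids[i], ";")[[1]]
    expect_true(all(members %in% ind_members))
  }
  expect_error(generate_dataset(group_design(1, 1, 1, seed = 1)),
               "membership_overlap")
})

test_that("identical design seeds reproduce the dataset exactly", {
  d <- group_design(6, 3, 3, seed = 30)
  t1 <- write_sessions(generate_dataset(d), tempfile(fileext = ".csv"))
  t2 <- write_sessions(generate_dataset(d), tempfile(fileext = ".csv"))
  expect_identical(t1, t2)
})
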