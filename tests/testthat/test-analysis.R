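test_that("performance counts rewarded trials", {
  expect_equal(performance(session("a", rep(1L, 100), rep(1L, 100))), 100)
  expect_equal(performance(session("b", rep(1L, 100), rep(0L, 100))), 0)
  expect_equal(performance(session("c", rep(1L, 100),
                                   rep(c(1L, 0L), 50))), 50)
  # rewarded + unrewarded = n_trials
  set.seed(51)
  s <- random_session(100, p = 0.4)
  expect_equal(performance(s) + sum(s$rewards == 0), 100)
})

test_that("Kruskal-Wallis matches hand rank arithmetic and handles ties", {
  x <- list(g1 = c(1, 3, 5), g2 = c(2, 4, 6), g3 = c(7, 8, 9))
  kw <- kruskal_wallis(x)
  # hand computation: H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2, no ties
  ranks <- rank(unlist(x))
  rbar <- tapply(ranks, rep(1:3, each = 3), mean)
  H <- 12 / (9 * 10) * sum(3 * (rbar - 5)^2)
  expect_equal(kw$statistic, H, tolerance = 1e-12)
  expect_equal(kw$df, 2)

  same <- list(a = 1:5, b = 1:5, c = 1:5)
  kw0 <- kruskal_wallis(same)
  expect_lt(kw0$statistic, 1e-10)
  expect_gt(kw0$p_raw, 0.999)

  expect_error(kruskal_wallis(list(a = 1:3)), "2 groups")
  expect_error(kruskal_wallis(list(a = 1:3, b = numeric())), "non-empty")
})

test_that("pairwise rank-sum tests use Bonferroni over the number of pairs", {
  set.seed(52)
  g <- list(i = rnorm(12), d = rnorm(12), t = rnorm(12))
  pw <- pairwise_wilcoxon_bonferroni(g)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_adjusted, pmin(1, 3 * pw$p_raw))
  expect_true(all(pw$p_adjusted >= pw$p_raw))

  same <- list(a = 1:6, b = 1:6)
  expect_equal(pairwise_wilcoxon_bonferroni(same)$p_adjusted, 1)
})

test_that("rank-sum p-value matches exact enumeration for small samples", {
  x <- c(1.2, 3.4, 2.2)
  y <- c(5.1, 4.4, 6.0, 7.2)
  pw <- pairwise_wilcoxon_bonferroni(list(x = x, y = y))
  # enumerate all assignments of the 7 ranks to the x-group
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[1:3]) - 3 * 4 / 2
  combos <- combn(7, 3)
  w_all <- apply(combos, 2, function(ix) sum(seq_len(7)[ix]) - 6)
  p_exact <- mean(w_all <= w_obs) + mean(w_all >= (3 * 4 - w_obs))
  expect_equal(pw$p_raw, p_exact, tolerance = 1e-12)
})

test_that("within-group contrasts report a 1-df chi-square and a direction", {
  v <- c(3, 1, 4, 1, 5, 9, 2, 6)
  same <- within_group_contrast(v, v)
  expect_gt(same$p_raw, 0.999)
  expect_equal(same$direction, "none")
  expect_equal(same$df, 1)

  set.seed(53)
  g <- rnorm(60)
  a <- rnorm(60, mean = 2)
  shifted <- within_group_contrast(g, a)
  expect_lt(shifted$p_raw, 0.01)
  expect_equal(shifted$direction, "aggregate_higher")

  paired <- within_group_contrast(g, a, paired = TRUE)
  expect_lt(paired$p_raw, 0.01)
  expect_equal(paired$method, "wilcoxon_signed_rank")

  expect_error(within_group_contrast(1:3, 1:4), "length")
})

test_that("positivity-bias test behaves under null, shifted and degenerate input", {
  set.seed(54)
  null_rate <- mean(replicate(100, {
    positivity_bias_test(rnorm(200, 0, 0.3))$p_raw >= 0.05
  }))
  expect_gte(null_rate, 0.9)

  pos <- positivity_bias_test(runif(50, 0.05, 0.4))
  expect_lt(pos$p_raw, 0.001)
  expect_equal(pos$direction, "positive")

  zero <- positivity_bias_test(rep(0, 20))
  expect_equal(zero$p_raw, 1)
  expect_equal(zero$direction, "none")
  expect_error(positivity_bias_test(numeric()), "non-empty")
})

test_that("identity-link Poisson intercept-only fit equals the sample mean", {
  set.seed(55)
  y <- rpois(40, 30)
  f <- poisson_regression(data.frame(performance = y, size = rep(1:2, 20)),
                          "intercept")
  expect_equal(f$estimate[1], mean(y), tolerance = 1e-8)
})

test_that("regression AIC matches its definition on a small fit", {
  set.seed(56)
  d <- data.frame(performance = rpois(12, 20), size = rep(1:3, 4))
  f <- poisson_regression(d, "quadratic")
  # by definition: -2 * max log-likelihood + 2 * number of coefficients
  co <- setNames(f$estimate, f$term)
  mu <- co[1] + co["size"] * d$size + co["size_squared"] * d$size^2
  ll <- sum(dpois(d$performance, mu, log = TRUE))
  expect_equal(attr(f, "aic"), -2 * ll + 2 * 3, tolerance = 1e-6)
})

test_that("regression inputs are validated", {
  d <- data.frame(performance = c(1.5, 2, 3), size = 1:3)
  expect_error(poisson_regression(d, "quadratic"), "integer")
  d2 <- data.frame(performance = c(-1L, 2L, 3L), size = 1:3)
  expect_error(poisson_regression(d2, "quadratic"), "non-negative")
  d3 <- data.frame(performance = rpois(10, 20), size = rep(1L, 10))
  expect_error(poisson_regression(d3, "quadratic"), "rank")
})

test_that("unit records join fits and member aggregates consistently", {
  ds <- generate_dataset(group_design(8, 4, 3, seed = 57))
  fs <- fit_sessions(ds, "simple", n_restarts = 2, seed = 58)
  rec <- unit_records(ds, fits_simple = fs)
  expect_equal(nrow(rec), 15)
  grp <- rec[rec$size > 1, ]
  ok <- complete.cases(grp$performance_member_min, grp$performance_member_max)
  expect_true(all(ok))
  expect_true(all(grp$performance_member_min <= grp$performance_member_mean))
  expect_true(all(grp$performance_member_mean <= grp$performance_member_max))
  expect_true(all(is.na(rec$performance_member_max[rec$size == 1])))
  # aggregates are computed from the members' own individual sessions
  ind <- rec[rec$size == 1, ]
  u <- ds$units[ds$units$size == 2, ][1, ]
  members <- strsplit(u$member_ids, ";")[[1]]
  ind_units <- ds$units$unit_id[ds$units$size == 1][
    match(members, ds$units$member_ids[ds$units$size == 1])]
  expect_equal(rec$performance_member_mean[rec$unit_id == u$unit_id],
               mean(ind$performance[match(ind_units, ind$unit_id)]))
})

test_that("test statistics are invariant to unit reordering", {
  set.seed(59)
  x <- list(a = rnorm(20), b = rnorm(20, 0.5), c = rnorm(20, 1))
  shuffled <- lapply(x, sample)
  expect_equal(kruskal_wallis(x)$statistic,
               kruskal_wallis(shuffled)$statistic, tolerance = 1e-12)
  expect_equal(pairwise_wilcoxon_bonferroni(x)$p_raw,
               pairwise_wilcoxon_bonferroni(shuffled)$p_raw,
               tolerance = 1e-12)
})

test_that("the analysis report assembles every section", {
  ds <- generate_dataset(group_design(10, 5, 5, seed = 60))
  fs <- fit_sessions(ds, "simple", n_restarts = 2, seed = 61)
  fa <- fit_sessions(ds, "asymmetric", n_restarts = 2, seed = 61)
  rec <- unit_records(ds, fs, fa)
  rep <- analysis_report(rec)
  expect_s3_class(rep, "analysis_report")
  expect_false(is.null(rep$descriptives))
  expect_true(all(c("performance", "alpha", "beta", "bias", "beta_asym") %in%
                  rep$omnibus$variable))
  expect_equal(unique(rep$pairwise$p_adjusted >= rep$pairwise$p_raw), TRUE)
  expect_true(all(c("dummies1", "dummies2", "quadratic") %in%
                  rep$regressions$spec))
  expect_true(all(rep$positivity_bias$condition %in%
                  c("individual", "dyad", "triad")))
})
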