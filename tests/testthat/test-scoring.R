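test_that("lottery stats reproduce the two-outcome variance computation", {
  # p = 1/6, x = 100: ev = 16.667, risk = 100 * sqrt(5/36)
  s <- lottery_stats(trial_of(1, 100, 5), "pink")
  expect_equal(s$p, 1 / 6)
  expect_equal(s$ev, 100 / 6)
  expect_equal(s$risk, 100 * sqrt(5 / 36), tolerance = 1e-12)
  # brute force over {hit: 50 w.p. 1/2, miss: 0}
  s2 <- lottery_stats(trial_of(3, 50, 25), "pink")
  expect_equal(s2$ev, 25)
  expect_equal(s2$variance, 625)
  expect_equal(s2$risk, 25)
  # degenerate payoff: x = 0 gives zero risk
  degenerate <- tibble::tibble(n_pink = 2, reward_pink = 0, reward_blue = 5)
  expect_equal(lottery_stats(degenerate, "pink")$risk, 0)
})

test_that("risk equals the closed form x * sqrt(p(1-p)) on the full choice grid", {
  tt <- enumerate_trial_types()
  for (color in c("pink", "blue")) {
    s <- lottery_stats(tt, color)
    expect_equal(s$risk, s$x * sqrt(s$p * (1 - s$p)), tolerance = 1e-12)
    expect_true(all(s$risk >= 0))
  }
})

test_that("risk is monotone in the reward and maximized at p = 1/2", {
  # fixed p (3 pink boxes), increasing pink reward
  risks <- sapply(c(5, 25, 50, 75, 100), function(x) {
    lottery_stats(trial_of(3, x, 5), "pink")$risk
  })
  expect_true(all(diff(risks) > 0))
  # fixed reward, p sweeping k/6 for k = 1..5: maximum at k = 3
  by_p <- sapply(1:5, function(k) {
    lottery_stats(trial_of(k, 50, 5), "pink")$risk
  })
  expect_equal(which.max(by_p), 3L)
})

test_that("Monte-Carlo payoff SD matches the closed-form risk", {
  # batch-means Monte-Carlo standard error: the delta-method SE of the SD
  # degenerates for symmetric two-point payoffs (p = 1/2), so the SE is
  # estimated from independent batch SDs instead
  tt <- enumerate_trial_types()
  set.seed(31)
  picks <- sample(nrow(tt), 3)
  for (i in picks) {
    trial <- tt[i, ]
    pay <- sample_payoffs(trial, "pink", 2e5, seed = 1000 + i)
    batch_sd <- vapply(split(pay, rep(1:20, each = 1e4)), sd, numeric(1))
    s <- lottery_stats(trial, "pink")
    mc_se <- sd(batch_sd) / sqrt(length(batch_sd))
    expect_lt(abs(mean(batch_sd) - s$risk), 3 * mc_se)
  }
})

test_that("choice optimality scores the higher-EV option and credits exact ties", {
  t1 <- trial_of(1, 100, 5) # ev pink 16.67 vs blue 4.17
  expect_equal(choice_optimality(t1, "pink"), 1)
  expect_equal(choice_optimality(t1, "blue"), 0)
  # equality case found by enumerating the space: 25 * 1/6 = 5 * 5/6
  tie <- trial_of(1, 25, 5)
  expect_true(ev_tie(tie))
  expect_equal(choice_optimality(tie, "pink"), 1)
  expect_equal(choice_optimality(tie, "blue"), 1)
  tt <- enumerate_trial_types()
  expect_gt(sum(ev_tie(tt)), 0)
})

test_that("a full run aggregates to 125 rows with means over presentations", {
  run <- one_run()
  scored <- aggregate_run(run)
  expect_equal(nrow(scored), 125L)
  expect_true(all(scored$n_presentations == 2L))
  expect_true(all(scored$co %in% c(0, 0.5, 1)))
  # averaging preserves range and the mean of equal values is that value
  per_pres <- lottery_stats(run, run$chosen_color)$risk
  by_code <- split(per_pres, run$trial_code)
  expect_true(all(
    scored$risk >= sapply(by_code, min)[as.character(scored$trial_code)] - 1e-12 &
    scored$risk <= sapply(by_code, max)[as.character(scored$trial_code)] + 1e-12
  ))
  # both presentations of each type share the configuration, so averaged
  # risk equals the single-presentation risk when the same color is chosen
  expect_equal(sort(unique(round(scored$risk - sapply(
    by_code, mean
  )[as.character(scored$trial_code)], 10))), 0)
})

test_that("opposite optimality on the two presentations averages to 0.5", {
  run <- one_run()
  # choose pink on presentation 1, blue on presentation 2
  mixed <- resolve_choices(run, ifelse(run$presentation == 1, "pink", "blue"))
  scored <- aggregate_run(mixed)
  tt <- enumerate_trial_types()
  tie_codes <- tt$trial_code[ev_tie(tt)]
  non_tie <- !scored$trial_code %in% tie_codes
  expect_true(all(scored$co[non_tie] == 0.5))
  expect_true(all(scored$co[!non_tie] == 1))
})

test_that("aggregate_run refuses records spanning several runs", {
  run1 <- one_run(1)
  run2 <- one_run(2)
  run2$stimulation <- "SPL"
  expect_error(aggregate_run(rbind(run1, run2)), "single run")
  expect_error(aggregate_run(run1[0, ]), "")
})

test_that("a missing presentation averages over the one available", {
  run <- one_run()
  drop_code <- run$trial_code[1]
  partial <- run[!(run$trial_code == drop_code & run$presentation == 2), ]
  scored <- aggregate_run(partial)
  expect_equal(nrow(scored), 125L)
  expect_equal(scored$n_presentations[scored$trial_code == drop_code], 1L)
})

test_that("the IQR filter uses interpolated quartiles and 1.5 IQR fences", {
  # quartiles of {1,1,1,1,100} by linear interpolation: Q1 = Q3 = 1
  f <- iqr_filter(c(1, 1, 1, 1, 100))
  expect_equal(f$n_removed, 1L)
  expect_equal(f$mask, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # identical values: IQR 0 keeps the common value
  f2 <- iqr_filter(rep(3.3, 10))
  expect_equal(f2$n_removed, 0L)
  # oracle fences for {0.5, 0.6, 0.7, 0.8}: Q1 0.575, Q3 0.725,
  # fences [0.35, 0.95] retain everything
  f3 <- iqr_filter(c(0.5, 0.6, 0.7, 0.8))
  expect_equal(unname(f3$fences), c(0.35, 0.95))
  expect_equal(f3$n_removed, 0L)
  expect_error(iqr_filter(c(1, 2, 3)), "at least 4")
})

test_that("response-time filtering respects scope and reports an audit count", {
  scored <- score_trials(simulate_cohort(tiny_design(), seed = 9))
  g <- filter_response_times(scored, "global")
  expect_equal(nrow(g$data) + g$n_removed, nrow(scored))
  expect_true(all(g$data$rt >= g$fences$lower & g$data$rt <= g$fences$upper))
  p <- filter_response_times(scored, "participant")
  expect_equal(nrow(p$fences), length(unique(scored$participant)))
})

test_that("response time is the keypress delay in seconds", {
  expect_equal(response_time(10, 10.89), 0.89)
  expect_equal(response_time(5, 5), 0)
  expect_equal(response_time(1000, 1890, unit = "ms"), 0.890)
  expect_error(response_time(2, 1), "precede")
})
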