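test_that("effect-size conversion follows f = sqrt(eta2 / (1 - eta2))", {
  expect_equal(partial_eta_to_f(0.691), 1.4954, tolerance = 1e-4)
  expect_equal(partial_eta_to_f(0), 0)
  expect_equal(partial_eta_to_f(0.5), 1) # closed form sqrt(0.5/0.5)
  expect_error(partial_eta_to_f(1), "0, 1")
  expect_error(partial_eta_to_f(-0.1), "0, 1")
})

test_that("ICC is the defining variance ratio", {
  expect_equal(icc_from_components(c(192.99, 1.56), 16.88),
               194.55 / 211.43, tolerance = 1e-12)
  expect_equal(icc_from_components(0, 5), 0)
  expect_error(icc_from_components(-1, 5), ">= 0")
})

test_that("fixed effects match the least-squares oracle when random variance is nil", {
  # 200-row table with no participant or trial-type variance: the mixed
  # model's fixed effects must equal the OLS solution on the same design
  spec <- effect_spec(sigma2 = 4, tau_trialtype_participant = 0,
                      tau_participant = 0)
  d <- cohort_design(n_placebo = 3, n_probiotics = 3, n_dropped_runs = 0,
                     n_trial_types = 6)
  dat <- simulate_lmm_dataset(spec, d, seed = 21)
  fit <- fit_lmm(dat, "risk")
  ols <- lm(risk ~ session * group * stimulation,
            data = transform(dat, session = factor(session),
                             group = factor(group, c("placebo", "probiotics")),
                             stimulation = factor(stimulation,
                                                  c("sham", "SPL", "VMPFC"))))
  expect_equal(fit$coefficients$estimate,
               unname(coef(ols)[fit$coefficients$term]),
               tolerance = 1e-4)
  # degenerate components shrink toward zero
  expect_lt(sum(fit$varcomp$variance[fit$varcomp$grouping != "Residual"]),
            0.5)
  expect_lt(fit$icc, 0.15)
})

test_that("the fit report satisfies its internal identities", {
  dat <- simulate_lmm_dataset(effect_spec(), tiny_design(), seed = 31)
  fit <- fit_lmm(dat, "risk")
  tau <- fit$varcomp$variance[fit$varcomp$grouping != "Residual"]
  expect_equal(fit$icc, sum(tau) / (sum(tau) + fit$sigma2))
  expect_gte(fit$r2_conditional, fit$r2_marginal)
  expect_true(fit$r2_marginal >= 0 && fit$r2_conditional <= 1)
  expect_true(all(fit$coefficients$ci_low <= fit$coefficients$estimate &
                    fit$coefficients$estimate <= fit$coefficients$ci_high))
  expect_equal(fit$n_obs, nrow(dat))
  expect_equal(unname(fit$n_groups[["participant"]]),
               length(unique(dat$participant)))
  expect_error(fit_lmm(dat[, setdiff(names(dat), "group")], "risk"),
               "missing column")
})

test_that("fixed effects are invariant to row order and grouping relabels", {
  dat <- simulate_lmm_dataset(effect_spec(), tiny_design(), seed = 41)
  fit <- fit_lmm(dat, "risk")
  shuffled <- dat[sample(nrow(dat)), ]
  fit_shuffled <- fit_lmm(shuffled, "risk")
  expect_equal(fit$coefficients$estimate, fit_shuffled$coefficients$estimate,
               tolerance = 1e-6)
  relabeled <- dat
  relabeled$participant <- paste0("XX_", relabeled$participant)
  relabeled$trial_code <- paste0("code_", as.integer(
    factor(relabeled$trial_code)
  ))
  fit_relabeled <- fit_lmm(relabeled, "risk")
  expect_equal(fit$coefficients$estimate, fit_relabeled$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("the repetition model recovers an injected block effect", {
  dat <- simulate_lmm_dataset(null_effect_spec(sigma2 = 4), tiny_design(),
                              seed = 51)
  delta <- c(A = 0, B = 3, C = -2)
  dat$risk <- dat$risk + delta[dat$repetition]
  fit <- fit_repetition_model(dat, "risk")
  co <- fit$coefficients
  estB <- co$estimate[co$term == "repetitionB"]
  estC <- co$estimate[co$term == "repetitionC"]
  seB <- co$std_error[co$term == "repetitionB"]
  seC <- co$std_error[co$term == "repetitionC"]
  expect_lt(abs(estB - 3), 4 * seB)
  expect_lt(abs(estC - (-2)), 4 * seC)
  # guard: a single repetition level cannot be modeled
  one_level <- dat
  one_level$repetition <- "A"
  expect_error(fit_repetition_model(one_level, "risk"), "2 levels")
})

test_that("heart-rate and scale models use participant-only intercepts with REML", {
  set.seed(61)
  hr_grid <- tidyr::expand_grid(
    participant = sprintf("p%02d", 1:20),
    session = 1:2,
    stimulation = c("sham", "SPL", "VMPFC"),
    time = c("before", "after")
  )
  hr_grid$group <- ifelse(as.integer(sub("p", "", hr_grid$participant)) <= 10,
                          "placebo", "probiotics")
  u <- rnorm(20, 0, 3)
  names(u) <- sprintf("p%02d", 1:20)
  hr_grid$hr <- 70 - 1.48 * (hr_grid$time == "after") +
    u[hr_grid$participant] + rnorm(nrow(hr_grid), 0, 2)
  fit <- fit_hr_lmm(hr_grid)
  expect_equal(fit$method, "REML")
  expect_equal(names(fit$n_groups), "participant")
  est <- fit$coefficients$estimate[fit$coefficients$term == "timeafter"]
  se <- fit$coefficients$std_error[fit$coefficients$term == "timeafter"]
  expect_lt(abs(est - (-1.48)), 4 * se)

  scale_tbl <- unique(hr_grid[c("participant", "session", "group")])
  scale_tbl$bscs <- 40 + u[scale_tbl$participant] +
    rnorm(nrow(scale_tbl), 0, 1)
  sfit <- fit_scale_lmm(scale_tbl, "bscs")
  expect_equal(sfit$method, "REML")
  expect_true(all(c("session2", "groupprobiotics", "session2:groupprobiotics")
                  %in% sfit$coefficients$term))
})

test_that("standardized coefficients are invariant to response rescaling", {
  dat <- simulate_lmm_dataset(effect_spec(), tiny_design(), seed = 71)
  fit <- fit_lmm(dat, "risk")
  std <- standardized_coefficients(fit, dat)
  rescaled <- dat
  rescaled$risk <- rescaled$risk * 7
  fit7 <- fit_lmm(rescaled, "risk")
  std7 <- standardized_coefficients(fit7, rescaled)
  expect_equal(std$std_estimate, std7$std_estimate, tolerance = 1e-6)
  expect_equal(attr(std, "method"), "response-SD scaling")
  # an exactly null coefficient standardizes to zero
  fake <- fit
  fake$coefficients$estimate[2] <- 0
  expect_equal(standardized_coefficients(fake, dat)$std_estimate[2], 0)
  constant <- dat
  constant$risk <- 1
  expect_error(standardized_coefficients(fit, constant), "zero variance")
})

test_that("a coefficient near the study's scale standardizes to the study's order", {
  # response SD from the generative components is about sqrt(211) ~ 14.5,
  # so a raw interaction of 0.27 is ~0.02 on the standardized scale
  dat <- simulate_lmm_dataset(effect_spec(), cohort_design(), seed = 81)
  fit_sd <- sd(dat$risk)
  expect_equal(0.27 / fit_sd, 0.02, tolerance = 0.25)
})
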