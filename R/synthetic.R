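#' Parameters of a simulated task-playing agent
#'
#' The task itself specifies no choice process, so the simulator uses a
#' mean-variance utility agent as an explicit stand-in: each option (color)
#' has utility `U = ev + risk_appetite * risk`, and the agent chooses pink
#' with softmax probability `plogis(choice_temperature * (U_pink - U_blue))`.
#' `choice_temperature` is an inverse-temperature: large values approach the
#' utility-maximizing choice, 0 gives random 50/50 choices. Response times
#' are lognormal; condition modifiers act additively on `risk_appetite` and
#' on the lognormal location (log-seconds).
#'
#' @param risk_appetite Utility weight on the option's risk score (0 =
#'   risk-neutral; positive = risk-seeking).
#' @param choice_temperature Softmax inverse-temperature, > 0 (in utility
#'   units of points).
#' @param rt_meanlog,rt_sdlog Location/scale of the lognormal response-time
#'   law, in log-seconds.
#' @param mods Named list of condition modifiers:
#'   `risk_appetite_session2`, `risk_appetite_probiotics`,
#'   `risk_appetite_session2_probiotics` (shifts of `risk_appetite`), and
#'   `rt_meanlog_session2`, `rt_meanlog_probiotics`,
#'   `rt_meanlog_session2_probiotics` (shifts of `rt_meanlog`). Defaults give
#'   a session-2 speed-up and a small slow-down plus extra risk appetite
#'   under probiotics in session 2, mirroring the direction of the study
#'   design's expected effects; magnitudes are simulator configuration, not
#'   empirical claims.
#' @return An object of class `mgt_agent_params`.
#' @export
agent_params <- function(risk_appetite = 0.1,
                         choice_temperature = 0.15,
                         rt_meanlog = log(0.9),
                         rt_sdlog = 0.35,
                         mods = list()) {
  if (!is.numeric(choice_temperature) || choice_temperature <= 0) {
    stop("`choice_temperature` must be > 0", call. = FALSE)
  }
  if (!is.numeric(rt_sdlog) || rt_sdlog <= 0) {
    stop("`rt_sdlog` must be > 0", call. = FALSE)
  }
  if (!is.finite(risk_appetite)) {
    stop("`risk_appetite` must be finite", call. = FALSE)
  }
  defaults <- list(
    risk_appetite_session2 = 0,
    risk_appetite_probiotics = 0.02,
    risk_appetite_session2_probiotics = 0.05,
    rt_meanlog_session2 = -0.25,
    rt_meanlog_probiotics = 0.03,
    rt_meanlog_session2_probiotics = 0.06
  )
  unknown <- setdiff(names(mods), names(defaults))
  if (length(unknown)) {
    stop("unknown modifier(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(mods)] <- mods
  structure(
    list(
      risk_appetite = risk_appetite,
      choice_temperature = choice_temperature,
      rt_meanlog = rt_meanlog,
      rt_sdlog = rt_sdlog,
      mods = defaults
    ),
    class = "mgt_agent_params"
  )
}

#' Layout of a simulated study cohort
#'
#' Defaults reproduce the study conditions: 60 participants (31 placebo, 29
#' probiotics, 36 women), 2 sessions separated by the intervention, 3
#' stimulation conditions per session in randomized order, one 250-trial run
#' per condition, and 5 runs (from distinct participants) lost to recording
#' failures.
#'
#' @param n_placebo,n_probiotics Group sizes.
#' @param n_women Number of participants labeled female (a bookkeeping label;
#'   it drives no effects). Default `NULL` gives 36 for the 60-participant
#'   study layout and the same 0.6 proportion for reduced cohorts.
#' @param sessions Number of sessions (2).
#' @param stimulations Stimulation condition labels.
#' @param n_dropped_runs Number of unrecorded runs, each assigned to a
#'   distinct participant.
#' @param n_trial_types Number of trial types per run; 125 for the full task,
#'   smaller values draw a random subset of the space for reduced-scale
#'   simulation experiments.
#' @return An object of class `mgt_cohort_design`.
#' @export
cohort_design <- function(n_placebo = 31L, n_probiotics = 29L,
                          n_women = NULL, sessions = 2L,
                          stimulations = mgt_stimulation_levels(),
                          n_dropped_runs = 5L, n_trial_types = 125L) {
  n <- n_placebo + n_probiotics
  if (is.null(n_women)) n_women <- round(n * 36 / 60)
  if (n_dropped_runs > n) {
    stop("dropped runs must come from distinct participants, so ",
         "`n_dropped_runs` cannot exceed the cohort size", call. = FALSE)
  }
  if (n_trial_types < 1L || n_trial_types > 125L) {
    stop("`n_trial_types` must be between 1 and 125", call. = FALSE)
  }
  if (n_women > n) stop("`n_women` cannot exceed the cohort size",
                        call. = FALSE)
  structure(
    list(
      n_placebo = as.integer(n_placebo),
      n_probiotics = as.integer(n_probiotics),
      n_women = as.integer(n_women),
      sessions = as.integer(sessions),
      stimulations = stimulations,
      n_dropped_runs = as.integer(n_dropped_runs),
      n_trial_types = as.integer(n_trial_types)
    ),
    class = "mgt_cohort_design"
  )
}

#' Generative fixed effects and variance components for the risk score
#'
#' The generative model for trial-type-averaged risk mirrors the study's
#' primary mixed model: treatment-coded fixed effects of session, group and
#' stimulation (reference cell: placebo, session 1, sham) plus a
#' participant random intercept, a trial-type-within-participant random
#' intercept, and residual noise. Defaults are the fitted values of the
#' study conditions this simulator emulates (intercept 25.33, session 2 x
#' probiotics 0.27; variance components 16.88 residual, 192.99 trial type
#' within participant, 1.56 participant).
#'
#' @param intercept Grand intercept on the risk scale (reference cell mean).
#' @param session2,group_probiotics,stim_SPL,stim_VMPFC Main effects.
#' @param session2_probiotics,session2_SPL,session2_VMPFC,probiotics_SPL,probiotics_VMPFC
#'   Two-way interactions.
#' @param session2_probiotics_SPL,session2_probiotics_VMPFC Three-way
#'   interactions.
#' @param sigma2 Residual variance.
#' @param tau_trialtype_participant Variance of the trial-type-within-
#'   participant random intercept.
#' @param tau_participant Variance of the participant random intercept.
#' @return An object of class `mgt_effect_spec`.
#' @export
effect_spec <- function(intercept = 25.33,
                        session2 = 0.00,
                        group_probiotics = 1.32,
                        stim_SPL = -0.03,
                        stim_VMPFC = 0.08,
                        session2_probiotics = 0.27,
                        session2_SPL = -0.28,
                        session2_VMPFC = -0.19,
                        probiotics_SPL = 0.14,
                        probiotics_VMPFC = -0.15,
                        session2_probiotics_SPL = 0.13,
                        session2_probiotics_VMPFC = -0.03,
                        sigma2 = 16.88,
                        tau_trialtype_participant = 192.99,
                        tau_participant = 1.56) {
  vars <- c(sigma2, tau_trialtype_participant, tau_participant)
  if (any(vars < 0)) stop("variances must be >= 0", call. = FALSE)
  structure(
    list(
      fixed = c(
        intercept = intercept,
        session2 = session2,
        group_probiotics = group_probiotics,
        stim_SPL = stim_SPL,
        stim_VMPFC = stim_VMPFC,
        session2_probiotics = session2_probiotics,
        session2_SPL = session2_SPL,
        session2_VMPFC = session2_VMPFC,
        probiotics_SPL = probiotics_SPL,
        probiotics_VMPFC = probiotics_VMPFC,
        session2_probiotics_SPL = session2_probiotics_SPL,
        session2_probiotics_VMPFC = session2_probiotics_VMPFC
      ),
      sigma2 = sigma2,
      tau_trialtype_participant = tau_trialtype_participant,
      tau_participant = tau_participant
    ),
    class = "mgt_effect_spec"
  )
}

#' @rdname effect_spec
#' @details `null_effect_spec()` keeps the intercept and variance components
#'   but zeroes every other fixed effect — the null generative model used for
#'   type-I-error experiments.
#' @param ... Passed on to [effect_spec()] to override defaults.
#' @export
null_effect_spec <- function(...) {
  args <- list(
    session2 = 0, group_probiotics = 0, stim_SPL = 0, stim_VMPFC = 0,
    session2_probiotics = 0, session2_SPL = 0, session2_VMPFC = 0,
    probiotics_SPL = 0, probiotics_VMPFC = 0,
    session2_probiotics_SPL = 0, session2_probiotics_VMPFC = 0
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(effect_spec, args)
}

# Participant roster: ids, group, gender, per-participant dropped run.
build_roster <- function(design) {
  n <- design$n_placebo + design$n_probiotics
  ids <- sprintf("p%02d", seq_len(n))
  group <- sample(c(rep("placebo", design$n_placebo),
                    rep("probiotics", design$n_probiotics)))
  gender <- sample(c(rep("female", design$n_women),
                     rep("male", n - design$n_women)))
  tibble::tibble(participant = ids, group = group, gender = gender)
}

# Registry of dropped runs: n_dropped_runs distinct participants, each losing
# one random session x stimulation block.
draw_dropped_runs <- function(design, roster) {
  if (design$n_dropped_runs == 0L) {
    return(tibble::tibble(participant = character(), session = integer(),
                          stimulation = character()))
  }
  who <- sample(roster$participant, design$n_dropped_runs)
  tibble::tibble(
    participant = who,
    session = sample(seq_len(design$sessions), design$n_dropped_runs,
                     replace = TRUE),
    stimulation = sample(design$stimulations, design$n_dropped_runs,
                         replace = TRUE)
  )
}

#' Simulate one agent choice on one trial
#'
#' @param agent An [agent_params()] object.
#' @param trial One row of the trial-type table.
#' @return `"pink"` or `"blue"` (uses the current RNG state; wrap in
#'   `set.seed()` for reproducibility).
#' @export
simulate_agent_choice <- function(agent, trial) {
  p <- pink_choice_prob(trial, agent$risk_appetite, agent$choice_temperature)
  ifelse(runif(nrow(trial)) < p, "pink", "blue")
}

# Softmax probability of choosing pink under mean-variance utility,
# vectorized over trials. b may be a vector (per-trial risk appetite).
pink_choice_prob <- function(trials, b, lambda) {
  pink <- lottery_stats(trials, "pink")
  blue <- lottery_stats(trials, "blue")
  du <- (pink$ev + b * pink$risk) - (blue$ev + b * blue$risk)
  stats::plogis(lambda * du)
}

#' Simulate a full study-shaped cohort at the choice level
#'
#' Generates the complete trial-level record of the study design: every
#' participant plays one run of the task per stimulation condition in each
#' session (conditions in randomized order), choices are produced by the
#' mean-variance softmax agent of [agent_params()], tokens are resolved into
#' hits and points, and response times are drawn from the agent's lognormal
#' law. Runs listed in the dropped-run registry are removed, emulating
#' unrecorded data.
#'
#' @param design A [cohort_design()].
#' @param agent An [agent_params()] object giving the population-level agent;
#'   per-participant heterogeneity is added via `b_sd` (risk appetite) and
#'   `rt_sd` (log-RT location).
#' @param seed Integer seed; the output is a pure function of
#'   (design, agent, heterogeneity, seed).
#' @param b_sd,rt_sd Between-participant SDs of risk appetite and lognormal
#'   RT location.
#' @return Trial-level tibble (one row per presentation) with the columns
#'   participant, group, gender, session, stimulation, repetition,
#'   run_position, trial_code, n_pink, reward_pink, reward_blue,
#'   chosen_color, hit, points, rt_seconds. The dropped-run registry is
#'   attached as `attr(, "dropped_runs")`.
#' @export
simulate_cohort <- function(design = cohort_design(),
                            agent = agent_params(),
                            seed = 1L,
                            b_sd = 0.05, rt_sd = 0.15) {
  set.seed(seed)
  roster <- build_roster(design)
  dropped <- draw_dropped_runs(design, roster)
  roster$b0 <- rnorm(nrow(roster), agent$risk_appetite, b_sd)
  roster$rt0 <- rnorm(nrow(roster), agent$rt_meanlog, rt_sd)
  keep_codes <- if (design$n_trial_types < 125L) {
    sample(enumerate_trial_types()$trial_code, design$n_trial_types)
  } else NULL
  plan_seeds <- matrix(
    sample.int(.Machine$integer.max, nrow(roster) * design$sessions),
    nrow = nrow(roster)
  )
  m <- agent$mods
  out <- vector("list", nrow(roster) * design$sessions)
  k <- 0L
  for (i in seq_len(nrow(roster))) {
    probio <- roster$group[i] == "probiotics"
    for (s in seq_len(design$sessions)) {
      order_s <- sample(design$stimulations)
      plan <- build_session_plan(s, order_s, plan_seeds[i, s])
      if (!is.null(keep_codes)) {
        plan <- plan[plan$trial_code %in% keep_codes, , drop = FALSE]
      }
      s2 <- s == 2L
      b <- roster$b0[i] +
        s2 * m$risk_appetite_session2 +
        probio * m$risk_appetite_probiotics +
        s2 * probio * m$risk_appetite_session2_probiotics
      p_pink <- pink_choice_prob(plan, b, agent$choice_temperature)
      chosen <- ifelse(runif(nrow(plan)) < p_pink, "pink", "blue")
      plan <- resolve_choices(plan, chosen)
      mu_rt <- roster$rt0[i] +
        s2 * m$rt_meanlog_session2 +
        probio * m$rt_meanlog_probiotics +
        s2 * probio * m$rt_meanlog_session2_probiotics
      plan$rt_seconds <- rlnorm(nrow(plan), mu_rt, agent$rt_sdlog)
      plan$participant <- roster$participant[i]
      plan$group <- roster$group[i]
      plan$gender <- roster$gender[i]
      k <- k + 1L
      out[[k]] <- plan
    }
  }
  trials <- dplyr::bind_rows(out)
  if (nrow(dropped)) {
    key <- paste(trials$participant, trials$session, trials$stimulation)
    drop_key <- paste(dropped$participant, dropped$session,
                      dropped$stimulation)
    trials <- trials[!key %in% drop_key, , drop = FALSE]
  }
  trials <- trials[, c("participant", "group", "gender", "session",
                       "stimulation", "repetition", "run_position",
                       "trial_code", "n_pink", "reward_pink", "reward_blue",
                       "chosen_color", "hit", "points", "rt_seconds")]
  attr(trials, "dropped_runs") <- dropped
  trials
}

#' Simulate trial-type-averaged risk scores from the generative mixed model
#'
#' Draws a scored-observation table directly from the mixed model the study
#' fits: for participant j, trial type t, session s, stimulation c,
#' \deqn{risk = X\beta + u_j + u_{jt} + \epsilon,}
#' with `u_j ~ N(0, tau_participant)`, `u_jt ~ N(0,
#' tau_trialtype_participant)` (one draw per participant x trial code, shared
#' across that participant's six runs) and residual `epsilon` per
#' observation. Ground truth is attached as `attr(, "effects")`.
#'
#' @param effects An [effect_spec()].
#' @param design A [cohort_design()].
#' @param seed Integer seed.
#' @return Scored tibble with columns participant, group, session,
#'   stimulation, repetition, trial_code, risk.
#' @export
simulate_lmm_dataset <- function(effects = effect_spec(),
                                 design = cohort_design(),
                                 seed = 1L) {
  set.seed(seed)
  roster <- build_roster(design)
  dropped <- draw_dropped_runs(design, roster)
  codes <- enumerate_trial_types()$trial_code
  if (design$n_trial_types < 125L) {
    codes <- sample(codes, design$n_trial_types)
  }
  grid <- tidyr::expand_grid(
    participant = roster$participant,
    session = seq_len(design$sessions),
    stimulation = design$stimulations,
    trial_code = codes
  )
  grid <- dplyr::left_join(grid, roster[c("participant", "group")],
                           by = "participant")
  # repetition = randomized block order of the three conditions per session
  rep_order <- tidyr::expand_grid(
    participant = roster$participant,
    session = seq_len(design$sessions)
  )
  rep_map <- lapply(seq_len(nrow(rep_order)), function(i) {
    tibble::tibble(
      participant = rep_order$participant[i],
      session = rep_order$session[i],
      stimulation = sample(design$stimulations),
      repetition = LETTERS[seq_along(design$stimulations)]
    )
  })
  grid <- dplyr::left_join(grid, dplyr::bind_rows(rep_map),
                           by = c("participant", "session", "stimulation"))

  b <- effects$fixed
  s2 <- as.numeric(grid$session == 2L)
  pr <- as.numeric(grid$group == "probiotics")
  spl <- as.numeric(grid$stimulation == "SPL")
  vmp <- as.numeric(grid$stimulation == "VMPFC")
  mu <- b[["intercept"]] +
    b[["session2"]] * s2 +
    b[["group_probiotics"]] * pr +
    b[["stim_SPL"]] * spl + b[["stim_VMPFC"]] * vmp +
    b[["session2_probiotics"]] * s2 * pr +
    b[["session2_SPL"]] * s2 * spl + b[["session2_VMPFC"]] * s2 * vmp +
    b[["probiotics_SPL"]] * pr * spl + b[["probiotics_VMPFC"]] * pr * vmp +
    b[["session2_probiotics_SPL"]] * s2 * pr * spl +
    b[["session2_probiotics_VMPFC"]] * s2 * pr * vmp

  u_p <- setNames(rnorm(nrow(roster), 0, sqrt(effects$tau_participant)),
                  roster$participant)
  pt_key <- paste(grid$participant, grid$trial_code, sep = ":")
  pt_levels <- unique(pt_key)
  u_pt <- setNames(
    rnorm(length(pt_levels), 0, sqrt(effects$tau_trialtype_participant)),
    pt_levels
  )
  eps <- rnorm(nrow(grid), 0, sqrt(effects$sigma2))
  grid$risk <- mu + u_p[grid$participant] + u_pt[pt_key] + eps

  if (nrow(dropped)) {
    key <- paste(grid$participant, grid$session, grid$stimulation)
    drop_key <- paste(dropped$participant, dropped$session,
                      dropped$stimulation)
    grid <- grid[!key %in% drop_key, , drop = FALSE]
  }
  grid <- grid[, c("participant", "group", "session", "stimulation",
                   "repetition", "trial_code", "risk")]
  attr(grid, "effects") <- effects
  attr(grid, "dropped_runs") <- dropped
  grid
}
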