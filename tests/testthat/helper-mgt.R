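# Shared fixtures, built in code.

# A small cohort layout for fast end-to-end runs.
tiny_design <- function(n_dropped_runs = 0L, n_trial_types = 10L) {
  cohort_design(
    n_placebo = 3L, n_probiotics = 3L,
    n_dropped_runs = n_dropped_runs, n_trial_types = n_trial_types
  )
}

# One complete simulated run (single participant/session/stimulation).
one_run <- function(seed = 404) {
  plan <- build_session_plan(1, c("sham", "SPL", "VMPFC"), seed)
  run <- plan[plan$stimulation == "sham", ]
  run$participant <- "p01"
  run$group <- "placebo"
  run <- resolve_choices(run, "pink")
  run$rt_seconds <- rlnorm(nrow(run), log(0.9), 0.3)
  run
}

# A lookup into the enumerated space by configuration.
trial_of <- function(n_pink, reward_pink, reward_blue) {
  tt <- enumerate_trial_types()
  tt[tt$n_pink == n_pink & tt$reward_pink == reward_pink &
       tt$reward_blue == reward_blue, ]
}
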