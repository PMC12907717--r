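# Map effect_spec names to lme4 fixed-effect term labels under treatment
# coding with reference cell (placebo, session 1, sham).
effect_term_map <- function() {
  c(
    intercept = "(Intercept)",
    session2 = "session2",
    group_probiotics = "groupprobiotics",
    stim_SPL = "stimulationSPL",
    stim_VMPFC = "stimulationVMPFC",
    session2_probiotics = "session2:groupprobiotics",
    session2_SPL = "session2:stimulationSPL",
    session2_VMPFC = "session2:stimulationVMPFC",
    probiotics_SPL = "groupprobiotics:stimulationSPL",
    probiotics_VMPFC = "groupprobiotics:stimulationVMPFC",
    session2_probiotics_SPL = "session2:groupprobiotics:stimulationSPL",
    session2_probiotics_VMPFC = "session2:groupprobiotics:stimulationVMPFC"
  )
}

#' Parameter-recovery experiment for the simulate-fit pipeline
#'
#' Repeatedly draws a dataset from the generative mixed model
#' ([simulate_lmm_dataset()]), refits the primary model ([fit_lmm()]), and
#' summarizes how well each fixed effect is recovered: mean estimate, bias
#' (with its Monte-Carlo standard error), RMSE, 95% Wald CI coverage of the
#' true value, and rejection rate at `alpha`. This is the package's main
#' verification surface: under a null generative model the rejection rate
#' doubles as a type-I-error estimate.
#'
#' @param effects Generative [effect_spec()] (ground truth).
#' @param design [cohort_design()]; reduced designs (fewer participants /
#'   trial types) keep large experiments tractable.
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer root seed; per-replicate seeds are derived from it.
#' @param terms Effect names (in [effect_spec()] naming) to track; default
#'   `"session2_probiotics"`, the study's critical interaction.
#' @param alpha Test level for the rejection-rate summary.
#' @return An object of class `mgt_recovery`: a summary tibble (one row per
#'   tracked term) plus per-replicate estimates in `attr(, "draws")` and the
#'   count of failed fits.
#' @export
recovery_experiment <- function(effects = effect_spec(),
                                design = cohort_design(),
                                n_reps = 100L,
                                seed = 1L,
                                terms = "session2_probiotics",
                                alpha = 0.05) {
  if (n_reps < 1L) stop("`n_reps` must be >= 1", call. = FALSE)
  term_map <- effect_term_map()
  unknown <- setdiff(terms, names(term_map))
  if (length(unknown)) {
    stop("unknown term(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  truth <- effects$fixed[terms]
  labels <- term_map[terms]

  draws <- vector("list", n_reps)
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    res <- tryCatch({
      dat <- simulate_lmm_dataset(effects, design, seed = rep_seeds[r])
      fit <- fit_lmm(dat, "risk")
      co <- fit$coefficients
      idx <- match(labels, co$term)
      tibble::tibble(
        rep = r,
        term = terms,
        estimate = co$estimate[idx],
        se = co$std_error[idx],
        ci_low = co$ci_low[idx],
        ci_high = co$ci_high[idx],
        p_value = co$p_value[idx],
        converged = fit$converged
      )
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else draws[[r]] <- res
  }
  draws <- dplyr::bind_rows(draws)
  if (nrow(draws) == 0L) {
    stop("all replicates failed to fit", call. = FALSE)
  }
  summary_tbl <- draws |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      true_value = unname(truth[dplyr::first(.data$term)]),
      mean_estimate = mean(.data$estimate),
      bias = .data$mean_estimate - .data$true_value,
      mc_se = if (dplyr::n() > 1L) {
        sd(.data$estimate) / sqrt(dplyr::n())
      } else NA_real_,
      rmse = sqrt(mean((.data$estimate - .data$true_value)^2)),
      coverage = mean(.data$ci_low <= .data$true_value &
                        .data$true_value <= .data$ci_high),
      rejection_rate = mean(.data$p_value < alpha),
      .groups = "drop"
    )
  structure(
    list(summary = summary_tbl, n_failed = n_failed, alpha = alpha,
         n_reps = n_reps),
    class = "mgt_recovery",
    draws = draws
  )
}

#' @export
print.mgt_recovery <- function(x, ...) {
  cat("Parameter recovery over", x$n_reps, "replicates (",
      x$n_failed, "failed fits )\n")
  print(as.data.frame(x$summary), digits = 4)
  invisible(x)
}
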