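#' Configuration of an end-to-end pipeline run
#'
#' Bundles everything a run needs so that (config, seed) alone reproduces it:
#' simulation mode and design, scoring options, model and contrast choices,
#' and the output directory. Serializes to YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param seed Integer root seed.
#' @param mode `"agents"` (simulate choices, then score) or `"lmm"`
#'   (simulate trial-type-averaged risk directly from the generative model).
#' @param design A [cohort_design()].
#' @param effects An [effect_spec()] (used by both modes: `lmm` mode draws
#'   from it; `agents` mode ignores it).
#' @param agent An [agent_params()] (agents mode only).
#' @param iqr_scope Response-time outlier-filter scope, `"global"` or
#'   `"participant"`.
#' @param tie_rule Choice-optimality tie rule; only `"credit"` (either choice
#'   on an equal-EV trial scores 1) is implemented, the field is recorded for
#'   audit completeness.
#' @param model Response to model: `"risk"`, `"co"` or `"rt"`.
#' @param contrast_family Family passed to [contrast_analysis()].
#' @param out_dir Output directory, or `NULL` to keep results in memory.
#' @return A list of class `mgt_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            mode = c("lmm", "agents"),
                            design = cohort_design(),
                            effects = effect_spec(),
                            agent = agent_params(),
                            iqr_scope = "global",
                            tie_rule = "credit",
                            model = "risk",
                            contrast_family = "table2",
                            out_dir = NULL) {
  mode <- match.arg(mode)
  structure(
    list(seed = as.integer(seed), mode = mode, design = design,
         effects = effects, agent = agent, iqr_scope = iqr_scope,
         tie_rule = tie_rule, model = model,
         contrast_family = contrast_family, out_dir = out_dir),
    class = "mgt_pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config Config to serialize.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- lapply(config, function(x) {
    if (inherits(x, c("mgt_cohort_design", "mgt_effect_spec",
                      "mgt_agent_params"))) {
      unclass(x)
    } else x
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  design <- do.call(cohort_design, raw$design)
  fixed <- raw$effects$fixed
  effects <- do.call(effect_spec, c(
    as.list(setNames(unlist(fixed), names(fixed))),
    raw$effects[c("sigma2", "tau_trialtype_participant", "tau_participant")]
  ))
  agent <- agent_params(
    risk_appetite = raw$agent$risk_appetite,
    choice_temperature = raw$agent$choice_temperature,
    rt_meanlog = raw$agent$rt_meanlog,
    rt_sdlog = raw$agent$rt_sdlog,
    mods = raw$agent$mods
  )
  pipeline_config(
    seed = raw$seed, mode = raw$mode, design = design, effects = effects,
    agent = agent, iqr_scope = raw$iqr_scope, tie_rule = raw$tie_rule,
    model = raw$model, contrast_family = raw$contrast_family,
    out_dir = raw$out_dir
  )
}

#' Run the full simulate-score-filter-fit-contrast pipeline
#'
#' Executes every stage of the study analysis on synthetic data and returns a
#' manifest reconciling row counts across stages (planned runs x 125 averaged
#' observations, minus dropped runs, minus response-time outliers). When
#' `config$out_dir` is set, each stage's table is written there (CSV for
#' tables, JSON for the fit report and manifest) and the manifest records
#' file checksums; reruns of the same config reproduce them byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @return A list with `manifest`, `scored`, `fit`, `contrasts` and (agents
#'   mode) `trials` plus `rt_fit` on the outlier-filtered table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mgt_pipeline_config"))
  design <- config$design
  stage_counts <- list()
  dropped <- NULL
  trials <- NULL
  rt_fit <- NULL
  rt_removed <- NA_integer_

  if (config$mode == "agents") {
    trials <- simulate_cohort(design, config$agent, seed = config$seed)
    dropped <- attr(trials, "dropped_runs")
    stage_counts$trial_level <- nrow(trials)
    scored <- score_trials(trials)
    stage_counts$scored <- nrow(scored)
    rt <- filter_response_times(scored, config$iqr_scope)
    rt_removed <- rt$n_removed
    stage_counts$rt_post_filter <- nrow(rt$data)
    fit <- fit_lmm(scored, config$model)
    rt_fit <- fit_lmm(rt$data, "rt")
  } else {
    scored <- simulate_lmm_dataset(config$effects, design,
                                   seed = config$seed)
    dropped <- attr(scored, "dropped_runs")
    stage_counts$scored <- nrow(scored)
    fit <- fit_lmm(scored, "risk")
  }
  contrasts <- contrast_analysis(fit, config$contrast_family)

  manifest <- list(
    source = "synthetic",
    mode = config$mode,
    seed = config$seed,
    model = config$model,
    tie_rule = config$tie_rule,
    iqr_scope = config$iqr_scope,
    contrast_family = config$contrast_family,
    planned_runs = (design$n_placebo + design$n_probiotics) *
      design$sessions * length(design$stimulations),
    dropped_runs = if (!is.null(dropped)) as.data.frame(dropped) else NULL,
    stage_counts = stage_counts,
    rt_outliers_removed = rt_removed,
    checksums = NULL
  )

  expected_scored <- (manifest$planned_runs - design$n_dropped_runs) *
    design$n_trial_types
  if (stage_counts$scored != expected_scored) {
    stop("stage count drift: scored rows ", stage_counts$scored,
         " != expected ", expected_scored, call. = FALSE)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(scored = file.path(config$out_dir, "scored.csv"))
    write_behavioral_table(scored, paths[["scored"]])
    if (!is.null(trials)) {
      paths[["trials"]] <- file.path(config$out_dir, "trials.csv")
      write_behavioral_table(trials, paths[["trials"]])
    }
    paths[["fit"]] <- file.path(config$out_dir, "fit.json")
    jsonlite::write_json(fit_to_list(fit), paths[["fit"]],
                         auto_unbox = TRUE, digits = NA)
    paths[["contrasts"]] <- file.path(config$out_dir, "contrasts.csv")
    write.csv(as.data.frame(contrasts), paths[["contrasts"]],
              row.names = FALSE)
    manifest$checksums <- as.list(tools::md5sum(unname(paths)))
    names(manifest$checksums) <- names(paths)
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  out <- list(manifest = manifest, scored = scored, fit = fit,
              contrasts = contrasts)
  if (!is.null(trials)) {
    out$trials <- trials
    out$rt_fit <- rt_fit
  }
  out
}
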