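#' Expected value, variance and risk score of a chosen lottery option
#'
#' Choosing a color with `k` of the six boxes and reward `x` points yields
#' `x` with probability `p = k/6` and 0 otherwise. The risk taken on that
#' trial is the standard deviation of this payoff distribution,
#' \deqn{Var(X) = p (x - E(X))^2 + (1 - p)(0 - E(X))^2, \quad Risk = \sqrt{Var(X)},}
#' which simplifies algebraically to \eqn{x \sqrt{p(1-p)}}.
#'
#' @param trials A table with `n_pink`, `reward_pink`, `reward_blue` (one or
#'   more rows).
#' @param chosen_color Character vector (`"pink"`/`"blue"`), recycled.
#' @return A tibble with columns `p`, `x`, `ev`, `variance`, `risk`.
#' @examples
#' t1 <- tibble::tibble(n_pink = 1, reward_pink = 100, reward_blue = 5)
#' lottery_stats(t1, "pink") # p = 1/6, ev = 16.67, risk = 37.27
#' @export
lottery_stats <- function(trials, chosen_color) {
  if (!all(chosen_color %in% c("pink", "blue"))) {
    stop("`chosen_color` must be \"pink\" or \"blue\"", call. = FALSE)
  }
  chosen_color <- rep_len(chosen_color, nrow(trials))
  k <- ifelse(chosen_color == "pink", trials$n_pink, 6L - trials$n_pink)
  if (any(k < 1L | k > 5L)) {
    stop("chosen color must have between 1 and 5 boxes", call. = FALSE)
  }
  x <- ifelse(chosen_color == "pink", trials$reward_pink, trials$reward_blue)
  p <- k / 6
  ev <- x * p
  variance <- p * (x - ev)^2 + (1 - p) * (0 - ev)^2
  tibble::tibble(p = p, x = as.numeric(x), ev = ev,
                 variance = variance, risk = sqrt(variance))
}

#' Binary choice-optimality score
#'
#' Scores 1 when the chosen color has the higher expected value of the two
#' options and 0 otherwise. When the two expected values are exactly equal
#' (ties exist in the enumerated space, e.g. 25 x 1/6 = 5 x 5/6) no higher-EV
#' option exists and either choice scores 1; tie trials can be identified
#' with `ev_tie()` for sensitivity analyses.
#'
#' @inheritParams lottery_stats
#' @return Numeric vector of 0/1 scores.
#' @export
choice_optimality <- function(trials, chosen_color) {
  chosen_color <- rep_len(chosen_color, nrow(trials))
  ev_pink <- trials$reward_pink * trials$n_pink / 6
  ev_blue <- trials$reward_blue * (6 - trials$n_pink) / 6
  ev_chosen <- ifelse(chosen_color == "pink", ev_pink, ev_blue)
  ev_other <- ifelse(chosen_color == "pink", ev_blue, ev_pink)
  as.numeric(ev_chosen >= ev_other)
}

#' @rdname choice_optimality
#' @return For `ev_tie`, a logical vector flagging trials whose two options
#'   have exactly equal expected value.
#' @export
ev_tie <- function(trials) {
  ev_pink <- trials$reward_pink * trials$n_pink
  ev_blue <- trials$reward_blue * (6 - trials$n_pink)
  ev_pink == ev_blue
}

#' Response time from trial-start and keypress timestamps
#'
#' @param trial_start,keypress Numeric timestamps, `keypress >= trial_start`.
#' @param unit Unit of the timestamps; `"s"` (default) or `"ms"`.
#' @return Response time in seconds.
#' @export
response_time <- function(trial_start, keypress, unit = c("s", "ms")) {
  unit <- match.arg(unit)
  dt <- keypress - trial_start
  if (any(dt < 0)) {
    stop("keypress cannot precede trial start", call. = FALSE)
  }
  if (unit == "ms") dt <- dt / 1000
  dt
}

# Per-presentation scores appended to a trial-level table.
score_presentations <- function(trials) {
  stats <- lottery_stats(trials, trials$chosen_color)
  trials$risk <- stats$risk
  trials$co <- choice_optimality(trials, trials$chosen_color)
  trials
}

#' Average presentation-level scores by trial type
#'
#' Each run presents every trial type twice; the dependent variables are
#' averaged over the (normally two) presentations of each type, yielding 125
#' observations per run — the unit of analysis of the mixed models. Choice
#' optimality therefore takes values in {0, 0.5, 1}. If one presentation of
#' a type is missing, the average is taken over the single available one.
#'
#' @param records Trial-level table for a single run (one
#'   participant x session x stimulation), with `chosen_color` and
#'   `rt_seconds` columns.
#' @return A tibble with one row per `trial_code` and columns `risk`, `co`,
#'   `rt` plus the run's identifying columns.
#' @export
aggregate_run <- function(records) {
  id_cols <- intersect(
    c("participant", "group", "session", "stimulation", "repetition"),
    names(records)
  )
  n_runs <- nrow(unique(records[id_cols]))
  if (n_runs != 1L) {
    stop("`records` must come from a single run; found ", n_runs,
         call. = FALSE)
  }
  if (nrow(records) == 0L) {
    stop("`records` is empty", call. = FALSE)
  }
  score_trials(records)
}

#' Score a trial-level table into averaged observations
#'
#' Computes the per-presentation risk score and choice optimality, then
#' averages risk, choice optimality and response time by trial type within
#' every participant x session x stimulation run (see [aggregate_run()]).
#'
#' @param trials Trial-level table as produced by [simulate_cohort()] or read
#'   via [read_behavioral_table()].
#' @return Scored long-format tibble, one row per run x trial code.
#' @export
score_trials <- function(trials) {
  trials <- score_presentations(trials)
  id_cols <- intersect(
    c("participant", "group", "session", "stimulation", "repetition",
      "trial_code"),
    names(trials)
  )
  has_rt <- "rt_seconds" %in% names(trials)
  out <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_cols))) |>
    dplyr::summarise(
      risk = mean(.data$risk),
      co = mean(.data$co),
      rt = if (has_rt) mean(.data$rt_seconds) else NA_real_,
      n_presentations = dplyr::n(),
      .groups = "drop"
    )
  out
}

#' Interquartile-range outlier fences
#'
#' Retains values `v` with `Q1 - 1.5 IQR <= v <= Q3 + 1.5 IQR`, the quartiles
#' computed by linear interpolation between order statistics
#' (`stats::quantile()` type 7). The interpolation rule matters: removal
#' counts depend on it, so it is fixed and documented here.
#'
#' @param values Numeric vector, at least 4 non-missing values.
#' @return A list with `mask` (logical, `NA` values retained as `NA`),
#'   `n_removed`, and the `fences`.
#' @export
iqr_filter <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 4L) {
    stop("need at least 4 non-missing values to place IQR fences",
         call. = FALSE)
  }
  q <- quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
  mask <- values >= fences[["lower"]] & values <= fences[["upper"]]
  list(mask = mask, n_removed = sum(!mask, na.rm = TRUE), fences = fences)
}

#' Remove response-time outliers from a scored table
#'
#' Applies the 1.5 x IQR rule of [iqr_filter()] to the trial-type-averaged
#' response times. By default the fences are computed once over the fully
#' assembled table (`scope = "global"`); `scope = "participant"` instead
#' places fences within each participant.
#'
#' @param scored Scored table from [score_trials()] with an `rt` column.
#' @param scope `"global"` (default) or `"participant"`.
#' @return A list with `data` (rows surviving the filter), `n_removed`, and
#'   `fences` (a tibble; one row per scope group).
#' @export
filter_response_times <- function(scored, scope = c("global", "participant")) {
  scope <- match.arg(scope)
  if (scope == "global") {
    f <- iqr_filter(scored$rt)
    keep <- !is.na(f$mask) & f$mask
    fences <- tibble::tibble(scope = "global",
                             lower = f$fences[["lower"]],
                             upper = f$fences[["upper"]])
  } else {
    parts <- split(seq_len(nrow(scored)), scored$participant)
    keep <- logical(nrow(scored))
    fences <- lapply(names(parts), function(p) {
      idx <- parts[[p]]
      f <- iqr_filter(scored$rt[idx])
      keep[idx] <<- !is.na(f$mask) & f$mask
      tibble::tibble(scope = p, lower = f$fences[["lower"]],
                     upper = f$fences[["upper"]])
    })
    fences <- dplyr::bind_rows(fences)
  }
  list(
    data = scored[keep, , drop = FALSE],
    n_removed = sum(!keep),
    fences = fences
  )
}
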