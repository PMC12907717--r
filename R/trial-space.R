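#' @importFrom rlang .data
#' @importFrom stats rnorm runif rlnorm quantile sd var pnorm qnorm setNames
#' @importFrom utils head read.csv write.csv
NULL

#' Reward levels and stimulation conditions of the task
#'
#' The six-box lottery task draws each color's reward from five fixed point
#' values, and each session administers one run of the task under each of
#' three theta-burst stimulation conditions.
#'
#' @name mgt-constants
#' @keywords internal
mgt_reward_levels <- function() c(5L, 25L, 50L, 75L, 100L)

#' @rdname mgt-constants
#' @keywords internal
mgt_stimulation_levels <- function() c("sham", "SPL", "VMPFC")

#' Enumerate the complete lottery trial space
#'
#' The task shows six boxes, of which 1 to 5 are pink (the rest blue), each
#' color carrying a reward drawn from {5, 25, 50, 75, 100} points. The full
#' space of distinct configurations is therefore 5 x 5 x 5 = 125 trial types.
#' Each run of the task presents every type exactly twice.
#'
#' @return A tibble of 125 rows with columns `n_pink`, `reward_pink`,
#'   `reward_blue` and a stable unique `trial_code`, in a deterministic order
#'   (by pink-box count, then pink reward, then blue reward).
#' @examples
#' types <- enumerate_trial_types()
#' nrow(types) # 125
#' @export
enumerate_trial_types <- function() {
  rewards <- mgt_reward_levels()
  grid <- expand.grid(
    reward_blue = rewards,
    reward_pink = rewards,
    n_pink = 1:5,
    KEEP.OUT.ATTRS = FALSE
  )
  grid <- grid[, c("n_pink", "reward_pink", "reward_blue")]
  grid$trial_code <- sprintf(
    "P%d_%03d_%03d", grid$n_pink, grid$reward_pink, grid$reward_blue
  )
  tibble::as_tibble(grid)
}

# Random box coloring + token placement for a block of trials.
# Returns token_box (uniform over 1..6), the pink positions as a string, and
# the color of the box hiding the token. Coloring is a uniform random subset
# of positions of size n_pink, independent of the token position.
draw_box_layout <- function(n_pink) {
  n <- length(n_pink)
  token_box <- sample.int(6L, n, replace = TRUE)
  keys <- matrix(runif(n * 6L), nrow = n)
  ranks <- matrix(0L, nrow = n, ncol = 6L)
  for (i in seq_len(n)) ranks[i, ] <- rank(keys[i, ], ties.method = "first")
  is_pink <- ranks <= n_pink
  token_pink <- is_pink[cbind(seq_len(n), token_box)]
  pink_positions <- vapply(
    seq_len(n),
    function(i) paste(which(is_pink[i, ]), collapse = ","),
    character(1)
  )
  tibble::tibble(
    token_box = token_box,
    pink_positions = pink_positions,
    token_color = ifelse(token_pink, "pink", "blue")
  )
}

#' Build a randomized session plan
#'
#' A session consists of three runs of the task, one per stimulation
#' condition, administered in the given order. Each run presents all 125
#' trial types twice (250 trials) in a uniformly random order, with the token
#' hidden uniformly at random behind one of the six boxes and the box coloring
#' re-randomized at every presentation.
#'
#' @param session Session number, 1 or 2.
#' @param stimulation_order Character permutation of
#'   `c("sham", "SPL", "VMPFC")` giving the block order.
#' @param seed Integer seed; identical inputs and seed reproduce the plan
#'   exactly.
#' @return A tibble of 750 rows (3 runs x 250 presentations) with columns
#'   `session`, `stimulation`, `repetition` (block A/B/C), `run_position`,
#'   `presentation`, the trial-type fields, `token_box`, `pink_positions` and
#'   `token_color`.
#' @export
build_session_plan <- function(session, stimulation_order, seed) {
  if (!session %in% c(1L, 2L)) {
    stop("`session` must be 1 or 2", call. = FALSE)
  }
  conditions <- mgt_stimulation_levels()
  if (length(stimulation_order) != 3L ||
      !setequal(stimulation_order, conditions)) {
    stop("`stimulation_order` must be a permutation of ",
         paste(conditions, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  types <- enumerate_trial_types()
  runs <- lapply(seq_along(stimulation_order), function(block) {
    idx <- sample(rep(seq_len(nrow(types)), 2L))
    run <- types[idx, ]
    run$session <- as.integer(session)
    run$stimulation <- stimulation_order[[block]]
    run$repetition <- LETTERS[block]
    run$run_position <- seq_len(nrow(run))
    pres <- stats::ave(run$run_position, run$trial_code, FUN = seq_along)
    run$presentation <- as.integer(pres)
    dplyr::bind_cols(run, draw_box_layout(run$n_pink))
  })
  plan <- dplyr::bind_rows(runs)
  plan[, c("session", "stimulation", "repetition", "run_position",
           "presentation", "trial_code", "n_pink", "reward_pink",
           "reward_blue", "token_box", "pink_positions", "token_color")]
}

#' Resolve choices into hit/miss outcomes
#'
#' A choice is a hit when the token's box carries the chosen color, in which
#' case the participant earns that color's reward; a miss earns zero points.
#'
#' @param trials A session-plan tibble (or any table with `token_color`,
#'   `reward_pink`, `reward_blue`).
#' @param chosen_color Character vector, `"pink"` or `"blue"`, recycled to
#'   the number of trials.
#' @return `trials` with `chosen_color`, `hit` (logical) and `points` columns
#'   appended.
#' @export
resolve_choices <- function(trials, chosen_color) {
  if (!all(chosen_color %in% c("pink", "blue"))) {
    stop("`chosen_color` must be \"pink\" or \"blue\"", call. = FALSE)
  }
  chosen_color <- rep_len(chosen_color, nrow(trials))
  hit <- chosen_color == trials$token_color
  reward <- ifelse(chosen_color == "pink",
                   trials$reward_pink, trials$reward_blue)
  trials$chosen_color <- chosen_color
  trials$hit <- hit
  trials$points <- ifelse(hit, reward, 0L)
  trials
}

#' @rdname resolve_choices
#' @param trial A single-row trial instance.
#' @return For `resolve_choice`, a list with `hit` and `points`.
#' @export
resolve_choice <- function(trial, chosen_color) {
  out <- resolve_choices(trial[1, , drop = FALSE], chosen_color)
  list(hit = out$hit[[1]], points = out$points[[1]])
}

#' Simulate payoffs of repeatedly playing one lottery
#'
#' Draws independent token placements (uniform over the six boxes under a
#' fresh random coloring each time) and returns the payoff of the given
#' choice on each draw. Used as a Monte-Carlo oracle for the closed-form
#' risk score.
#'
#' @param trial One row of [enumerate_trial_types()].
#' @param chosen_color `"pink"` or `"blue"`.
#' @param n Number of independent draws.
#' @param seed Optional integer seed.
#' @return Integer vector of `n` payoffs in points.
#' @export
sample_payoffs <- function(trial, chosen_color, n, seed = NULL) {
  stopifnot(chosen_color %in% c("pink", "blue"))
  if (!is.null(seed)) set.seed(seed)
  k <- if (chosen_color == "pink") trial$n_pink else 6L - trial$n_pink
  x <- if (chosen_color == "pink") trial$reward_pink else trial$reward_blue
  hit <- sample.int(6L, n, replace = TRUE) <= k
  as.integer(hit) * as.integer(x)
}

#' Select the trial paid out at the end of a session
#'
#' At the end of each session one trial is drawn for payment by picking a
#' block number (1-3) and a trial number. Trial numbers 1-10 are the practice
#' trials and are ineligible; valid task trials occupy positions 11 through
#' 260 (10 practice + 250 task trials). Each point is worth EUR 0.10.
#'
#' @param runs A list of three run tables (each 250 rows with a `points`
#'   column, in presentation order), or a full session table with a
#'   `repetition` column.
#' @param block_index Block number between 1 and 3.
#' @param trial_index Trial number between 11 and 260 (numbers 1-10 point at
#'   practice trials and are rejected, as is anything above 260).
#' @return A list with `block`, `trial`, `points` and `euros`.
#' @export
select_payment_trial <- function(runs, block_index, trial_index) {
  if (is.data.frame(runs)) {
    runs <- split(runs, runs$repetition)
  }
  if (length(runs) != 3L) {
    stop("`runs` must contain exactly 3 blocks", call. = FALSE)
  }
  if (!is.numeric(block_index) || length(block_index) != 1L ||
      !block_index %in% 1:3) {
    stop("`block_index` must be between 1 and 3", call. = FALSE)
  }
  if (!is.numeric(trial_index) || length(trial_index) != 1L ||
      trial_index != round(trial_index) || trial_index > 260) {
    stop("`trial_index` must be an integer between 11 and 260", call. = FALSE)
  }
  if (trial_index <= 10) {
    stop("trial numbers 1-10 are practice trials and are not eligible",
         call. = FALSE)
  }
  run <- runs[[block_index]]
  if (nrow(run) != 250L) {
    stop("each block must hold 250 task trials", call. = FALSE)
  }
  points <- run$points[[trial_index - 10L]]
  list(
    block = as.integer(block_index),
    trial = as.integer(trial_index),
    points = as.integer(points),
    euros = round(points * 0.10, 2)
  )
}
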