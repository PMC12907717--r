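schema_columns <- function(schema) {
  switch(
    schema,
    trial = c("participant", "session", "stimulation", "trial_code",
              "n_pink", "reward_pink", "reward_blue", "chosen_color",
              "hit", "points", "rt_seconds"),
    scored = c("participant", "group", "session", "stimulation",
               "trial_code", "risk"),
    hr = c("participant", "group", "session", "stimulation", "time", "hr"),
    stop("unknown schema: ", schema, call. = FALSE)
  )
}

#' Read and validate a behavioral table
#'
#' Reads a comma-separated, UTF-8, header-first CSV holding trial-level,
#' scored, or heart-rate data, optionally renaming columns via an explicit
#' mapping (deposited datasets may use different headers; no guessing is
#' attempted). Validation rejects missing required columns, unknown factor
#' levels, and duplicated participant x session x stimulation x trial_code
#' rows in scored tables. Trial codes absent from the enumerated space are
#' re-mapped from `(n_pink, reward_pink, reward_blue)` when those columns are
#' present, otherwise rejected.
#'
#' @param path CSV file path.
#' @param schema `"trial"`, `"scored"` or `"hr"`.
#' @param mapping Optional named character vector `c(required_name =
#'   file_column, ...)` renaming file columns onto the schema.
#' @param expected_participants Optional participant count to enforce.
#' @param partial_runs For trial-level tables whose runs do not have the full
#'   250 presentations: `"keep"` (default; a warning is emitted and the
#'   available presentations are used) or `"drop"` (the whole run is
#'   removed, mirroring unrecorded-run handling).
#' @return A validated tibble.
#' @export
read_behavioral_table <- function(path,
                                  schema = c("trial", "scored", "hr"),
                                  mapping = NULL,
                                  expected_participants = NULL,
                                  partial_runs = c("keep", "drop")) {
  schema <- match.arg(schema)
  partial_runs <- match.arg(partial_runs)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- tibble::as_tibble(
    read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  )
  if (!is.null(mapping)) {
    found <- mapping[mapping %in% names(x)]
    names(x)[match(found, names(x))] <- names(found)
  }
  required <- schema_columns(schema)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if ("stimulation" %in% names(x)) {
    bad <- setdiff(unique(x$stimulation), mgt_stimulation_levels())
    if (length(bad)) {
      stop("unknown stimulation level(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if ("group" %in% names(x)) {
    bad <- setdiff(unique(x$group), c("placebo", "probiotics"))
    if (length(bad)) {
      stop("unknown group level(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if ("session" %in% names(x) && !all(x$session %in% c(1L, 2L))) {
    stop("`session` must be 1 or 2", call. = FALSE)
  }
  if ("chosen_color" %in% names(x)) {
    bad <- setdiff(unique(x$chosen_color), c("pink", "blue"))
    if (length(bad)) {
      stop("unknown chosen_color value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(expected_participants)) {
    n <- length(unique(x$participant))
    if (n != expected_participants) {
      stop("expected ", expected_participants, " participants, found ", n,
           call. = FALSE)
    }
  }
  if ("trial_code" %in% names(x)) {
    space <- enumerate_trial_types()
    unknown <- !x$trial_code %in% space$trial_code
    if (any(unknown)) {
      geom_cols <- c("n_pink", "reward_pink", "reward_blue")
      if (all(geom_cols %in% names(x))) {
        remapped <- dplyr::left_join(
          x[unknown, geom_cols], space, by = geom_cols
        )$trial_code
        if (anyNA(remapped)) {
          stop("trial codes could not be mapped onto the enumerated space",
               call. = FALSE)
        }
        x$trial_code[unknown] <- remapped
      } else {
        stop("unknown trial code(s) and no geometry columns to map them by",
             call. = FALSE)
      }
    }
  }
  if (schema == "scored") {
    key <- paste(x$participant, x$session, x$stimulation, x$trial_code)
    if (anyDuplicated(key)) {
      stop("duplicated participant x session x stimulation x trial_code rows",
           call. = FALSE)
    }
  }
  if (schema == "trial") {
    run_sizes <- x |>
      dplyr::count(.data$participant, .data$session, .data$stimulation)
    short <- run_sizes[run_sizes$n != 250L, , drop = FALSE]
    if (nrow(short)) {
      warning(nrow(short), " run(s) do not have 250 presentations; policy: ",
              partial_runs, call. = FALSE)
      if (partial_runs == "drop") {
        key <- paste(x$participant, x$session, x$stimulation)
        bad_key <- paste(short$participant, short$session, short$stimulation)
        x <- x[!key %in% bad_key, , drop = FALSE]
      }
    }
  }
  x
}

#' @rdname read_behavioral_table
#' @param x Table to write.
#' @export
write_behavioral_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Serialize an mgt_fit to a plain list (for JSON reports).
fit_to_list <- function(fit) {
  list(
    response = fit$response,
    method = fit$method,
    coefficients = as.data.frame(fit$coefficients),
    varcomp = as.data.frame(fit$varcomp),
    icc = fit$icc,
    r2_marginal = fit$r2_marginal,
    r2_conditional = fit$r2_conditional,
    aic = fit$aic,
    converged = fit$converged,
    n_obs = fit$n_obs,
    n_groups = as.list(fit$n_groups)
  )
}
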