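#' Estimated-marginal-means contrast analysis
#'
#' Computes model-based cell means over the session x group x stimulation
#' grid and forms pairwise differences with standard errors from the fixed-
#' effect covariance matrix. Inference is asymptotic (z ratios), and p-values
#' are Bonferroni-adjusted within the family of contrasts requested in a
#' single call (`p_adj = min(1, m * p)` with `m` the number of rows).
#'
#' @param fit An `mgt_fit` from [fit_lmm()].
#' @param family Which contrasts to compute:
#'   * `"table2"` (default) — the study's full planned family: session 2 -
#'     session 1 within each group x stimulation cell (6 rows), probiotics -
#'     placebo within each stimulation x session cell (6 rows), and the
#'     consecutive stimulation contrasts SPL - sham and VMPFC - SPL within
#'     each group x session cell (8 rows); 20 rows in all.
#'   * `"sessions"`, `"groups"`, `"stimulations"` — one of those subsets.
#'   * A named list of numeric coefficient vectors over the cells of the
#'     session x group x stimulation grid (in the row order of
#'     `emmeans::emmeans(fit$model, ~ session * group * stimulation)`).
#' @return A tibble of class `mgt_contrasts` with columns `group`,
#'   `stimulation`, `session`, `contrast`, `estimate`, `se`, `z_ratio`,
#'   `p_value`, `p_adj`; the family size is attached as
#'   `attr(, "family_size")`.
#' @export
contrast_analysis <- function(fit, family = "table2") {
  emm <- emmeans::emmeans(fit$model, ~ session * group * stimulation,
                          lmer.df = "asymptotic")
  pieces <- list()
  if (is.character(family)) {
    family <- match.arg(family,
                        c("table2", "sessions", "groups", "stimulations"))
    if (family %in% c("table2", "sessions")) {
      pieces$sessions <- emmeans::contrast(
        emm, "revpairwise", by = c("group", "stimulation")
      )
    }
    if (family %in% c("table2", "groups")) {
      pieces$groups <- emmeans::contrast(
        emm, "revpairwise", by = c("stimulation", "session")
      )
    }
    if (family %in% c("table2", "stimulations")) {
      pieces$stimulations <- emmeans::contrast(
        emm, "consec", by = c("group", "session")
      )
    }
  } else if (is.list(family)) {
    if (is.null(names(family)) || any(!nzchar(names(family)))) {
      stop("custom contrast lists must be named", call. = FALSE)
    }
    pieces$custom <- emmeans::contrast(emm, method = family)
  } else {
    stop("`family` must be a character option or a named list",
         call. = FALSE)
  }
  rows <- lapply(pieces, function(p) {
    s <- summary(p, infer = c(FALSE, TRUE), adjust = "none")
    df <- as.data.frame(s)
    tibble::tibble(
      group = if ("group" %in% names(df)) as.character(df$group) else NA,
      stimulation = if ("stimulation" %in% names(df)) {
        as.character(df$stimulation)
      } else NA,
      session = if ("session" %in% names(df)) as.character(df$session)
                else NA,
      contrast = as.character(df$contrast),
      estimate = df$estimate,
      se = df$SE,
      z_ratio = df$z.ratio,
      p_value = df$p.value
    )
  })
  out <- dplyr::bind_rows(rows)
  # degenerate contrasts (all-zero coefficients) estimate 0 with no sampling
  # variability: report z = 0, p = 1 rather than NaN
  degenerate <- out$estimate == 0 & out$se == 0
  out$z_ratio[degenerate] <- 0
  out$p_value[degenerate] <- 1
  m <- nrow(out)
  out$p_adj <- pmin(1, m * out$p_value)
  attr(out, "family_size") <- m
  class(out) <- c("mgt_contrasts", class(out))
  out
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for an explicit family size `m`; monotone in `m`.
#'
#' @param p Raw p-values.
#' @param m Family size (defaults to `length(p)`).
#' @return Adjusted p-values in [0, 1].
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  pmin(1, m * p)
}
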