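#' Intraclass correlation from variance components
#'
#' The share of total variance attributable to the random intercepts:
#' `ICC = sum(tau) / (sum(tau) + sigma2)`.
#'
#' @param tau Numeric vector of random-intercept variances.
#' @param sigma2 Residual variance.
#' @return The ICC, in [0, 1].
#' @examples
#' icc_from_components(c(192.99, 1.56), 16.88) # 0.92
#' @export
icc_from_components <- function(tau, sigma2) {
  if (any(tau < 0) || sigma2 < 0) stop("variances must be >= 0",
                                       call. = FALSE)
  sum(tau) / (sum(tau) + sigma2)
}

#' Convert partial eta squared to Cohen's f
#'
#' `f = sqrt(eta2 / (1 - eta2))`; the standardized effect size used for the
#' study's a priori power computation.
#'
#' @param eta2 Partial eta squared, in [0, 1).
#' @return Cohen's f.
#' @examples
#' partial_eta_to_f(0.691) # 1.4954
#' @export
partial_eta_to_f <- function(eta2) {
  if (any(eta2 < 0 | eta2 >= 1)) {
    stop("`eta2` must lie in [0, 1)", call. = FALSE)
  }
  sqrt(eta2 / (1 - eta2))
}

# Coerce analysis factors to the study's reference levels:
# placebo, session 1, sham stimulation, repetition A.
prepare_factors <- function(data) {
  if ("session" %in% names(data)) {
    data$session <- factor(data$session, levels = sort(unique(data$session)))
  }
  if ("group" %in% names(data)) {
    data$group <- factor(data$group,
                         levels = intersect(c("placebo", "probiotics"),
                                            unique(data$group)))
  }
  if ("stimulation" %in% names(data)) {
    data$stimulation <- factor(
      data$stimulation,
      levels = intersect(mgt_stimulation_levels(), unique(data$stimulation))
    )
  }
  if ("repetition" %in% names(data)) {
    data$repetition <- factor(data$repetition,
                              levels = sort(unique(data$repetition)))
  }
  if ("time" %in% names(data)) {
    data$time <- factor(data$time,
                        levels = intersect(c("before", "after"),
                                           unique(data$time)))
  }
  data$participant <- factor(data$participant)
  if ("trial_code" %in% names(data)) {
    data$trial_code <- factor(data$trial_code)
  }
  data
}

# Fit an lmer model, retrying with bobyqa if the default optimizer flags
# convergence trouble. Singular fits (a variance component estimated at the
# boundary) are recorded in the notes but are not convergence failures.
# Returns list(model, converged, notes).
fit_lmer_robust <- function(formula, data, reml) {
  quiet_lmer <- function(control) {
    notes <- character()
    fit <- withCallingHandlers(
      lme4::lmer(formula, data = data, REML = reml, control = control),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        notes <<- c(notes, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      }
    )
    singular_only <- all(grepl("singular", notes, ignore.case = TRUE))
    converged <- length(fit@optinfo$conv$lme4) == 0 &&
      (length(notes) == 0 || singular_only)
    list(fit = fit, converged = converged, notes = notes)
  }
  first <- quiet_lmer(lme4::lmerControl(calc.derivs = TRUE))
  if (first$converged) {
    return(list(model = first$fit, converged = TRUE, notes = first$notes))
  }
  retry <- quiet_lmer(lme4::lmerControl(optimizer = "bobyqa",
                                        optCtrl = list(maxfun = 1e5)))
  if (retry$converged) {
    return(list(model = retry$fit, converged = TRUE,
                notes = c(first$notes, "recovered with bobyqa retry")))
  }
  list(model = first$fit, converged = FALSE,
       notes = unique(c(first$notes, retry$notes)))
}

# Assemble the standard report from a fitted lmerMod.
build_fit_result <- function(fitted, response, data, method) {
  model <- fitted$model
  co <- as.data.frame(summary(model)$coefficients)
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  z <- est / se
  coefficients <- tibble::tibble(
    term = rownames(co),
    estimate = est,
    std_error = se,
    ci_low = est - qnorm(0.975) * se,
    ci_high = est + qnorm(0.975) * se,
    statistic = z,
    p_value = 2 * pnorm(-abs(z))
  )
  vc <- as.data.frame(lme4::VarCorr(model))
  resid_var <- vc$vcov[vc$grp == "Residual"]
  ranef_rows <- vc[vc$grp != "Residual", , drop = FALSE]
  varcomp <- tibble::tibble(
    grouping = c(ranef_rows$grp, "Residual"),
    variance = c(ranef_rows$vcov, resid_var)
  )
  tau <- ranef_rows$vcov
  icc <- if (length(tau)) icc_from_components(tau, resid_var) else 0
  X <- stats::model.matrix(model)
  var_fixed <- var(as.vector(X %*% lme4::fixef(model)))
  total <- var_fixed + sum(tau) + resid_var
  structure(
    list(
      model = model,
      response = response,
      method = method,
      coefficients = coefficients,
      varcomp = varcomp,
      sigma2 = resid_var,
      icc = icc,
      r2_marginal = var_fixed / total,
      r2_conditional = (var_fixed + sum(tau)) / total,
      aic = stats::AIC(model),
      converged = fitted$converged,
      notes = fitted$notes,
      n_obs = stats::nobs(model),
      n_groups = lme4::ngrps(model)
    ),
    class = "mgt_fit"
  )
}

#' @export
print.mgt_fit <- function(x, ...) {
  cat("Linear mixed model (", x$method, ") for `", x$response, "`\n",
      sep = "")
  cat("Observations:", x$n_obs, " Groups:",
      paste(names(x$n_groups), x$n_groups, collapse = ", "), "\n")
  cat(sprintf("ICC %.3f | R2 marginal %.4f / conditional %.4f | AIC %.1f\n",
              x$icc, x$r2_marginal, x$r2_conditional, x$aic))
  if (!x$converged) cat("WARNING: fit did not converge cleanly\n")
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Fit the study's primary linear mixed models
#'
#' Fits `response ~ session * group * stimulation` with random intercepts for
#' participant and for trial code nested within participant, by maximum
#' likelihood — the model used for the risk score, choice optimality and
#' response time. Reference levels are placebo, session 1, sham. Inference
#' uses asymptotic (Wald z) statistics, appropriate at the tens of thousands
#' of observations the design yields.
#'
#' @param data Scored table with columns `participant`, `group`, `session`,
#'   `stimulation`, `trial_code` and the response.
#' @param response Name of the response column: `"risk"`, `"co"` or `"rt"`.
#' @param reml Use REML instead of ML (default FALSE, matching the study's
#'   ML estimation for the behavioral models).
#' @return An object of class `mgt_fit`: coefficient table with Wald CIs and
#'   p-values, variance components, ICC, marginal/conditional R2
#'   (variance-decomposition definitions of Nakagawa & Schielzeth), AIC, a
#'   convergence flag and group counts.
#' @export
fit_lmm <- function(data, response = "risk", reml = FALSE) {
  check_model_columns(data, response,
                      c("participant", "group", "session", "stimulation",
                        "trial_code"))
  data <- prepare_factors(data)
  f <- stats::as.formula(paste(
    response,
    "~ session * group * stimulation",
    "+ (1 | participant:trial_code) + (1 | participant)"
  ))
  fitted <- fit_lmer_robust(f, data, reml)
  build_fit_result(fitted, response, data, if (reml) "REML" else "ML")
}

#' Post hoc model including task repetition
#'
#' Extends [fit_lmm()] with the within-session block order (repetition A, B,
#' C) as a fixed factor, fully crossed with session, group and stimulation up
#' to the four-way interaction.
#'
#' @inheritParams fit_lmm
#' @export
fit_repetition_model <- function(data, response = "risk", reml = FALSE) {
  check_model_columns(data, response,
                      c("participant", "group", "session", "stimulation",
                        "trial_code", "repetition"))
  if (length(unique(data$repetition)) < 2L) {
    stop("`repetition` must have at least 2 levels", call. = FALSE)
  }
  data <- prepare_factors(data)
  f <- stats::as.formula(paste(
    response,
    "~ session * group * stimulation * repetition",
    "+ (1 | participant:trial_code) + (1 | participant)"
  ))
  fitted <- fit_lmer_robust(f, data, reml)
  build_fit_result(fitted, response, data, if (reml) "REML" else "ML")
}

#' Heart-rate and questionnaire-scale mixed models
#'
#' `fit_hr_lmm()` fits `hr ~ session + group + stimulation + time +
#' session:group` with a participant random intercept, by REML — `time`
#' distinguishes the measurement taken before vs after stimulation.
#' `fit_scale_lmm()` fits `response ~ session * group` with a participant
#' random intercept, by REML, the generic specification used for the control
#' scales.
#'
#' @param data Table with `participant`, `session`, `group`, `stimulation`,
#'   `time` and `hr` columns (for `fit_hr_lmm`); `participant`, `session`,
#'   `group` and the response (for `fit_scale_lmm`).
#' @param response Response column name for `fit_scale_lmm`.
#' @return An `mgt_fit` object.
#' @export
fit_hr_lmm <- function(data) {
  check_model_columns(data, "hr",
                      c("participant", "group", "session", "stimulation",
                        "time"))
  data <- prepare_factors(data)
  f <- hr ~ session + group + stimulation + time + session:group +
    (1 | participant)
  fitted <- fit_lmer_robust(f, data, reml = TRUE)
  build_fit_result(fitted, "hr", data, "REML")
}

#' @rdname fit_hr_lmm
#' @export
fit_scale_lmm <- function(data, response) {
  check_model_columns(data, response, c("participant", "group", "session"))
  data <- prepare_factors(data)
  f <- stats::as.formula(paste(response,
                               "~ session * group + (1 | participant)"))
  fitted <- fit_lmer_robust(f, data, reml = TRUE)
  build_fit_result(fitted, response, data, "REML")
}

check_model_columns <- function(data, response, required) {
  missing_cols <- setdiff(c(response, required), names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Coefficients on the standardized-response scale
#'
#' Re-expresses fixed effects after dividing the response by its overall
#' standard deviation. Factor contrasts are not additionally standardized;
#' the scaling method is stamped into the `method` attribute of the output
#' (the original analysis does not state its method, so this one is recorded
#' explicitly).
#'
#' @param fit An `mgt_fit`.
#' @param data The table the model was fitted to (source of the response SD).
#' @return Tibble of terms with `std_estimate`, `std_ci_low`, `std_ci_high`.
#' @export
standardized_coefficients <- function(fit, data) {
  y <- data[[fit$response]]
  s <- sd(y, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    stop("response has zero variance; cannot standardize", call. = FALSE)
  }
  out <- tibble::tibble(
    term = fit$coefficients$term,
    std_estimate = fit$coefficients$estimate / s,
    std_ci_low = fit$coefficients$ci_low / s,
    std_ci_high = fit$coefficients$ci_high / s
  )
  attr(out, "method") <- "response-SD scaling"
  attr(out, "response_sd") <- s
  out
}
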