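#' Validate a survival-record table
#'
#' Checks the per-patient follow-up table consumed by the outcome analyses:
#' `patient_id`, `time_days` (non-negative), `event` (logical first composite
#' event), `event_type` (`"death"`, `"mi"`, `"revasc"` or `"none"`), plus one
#' or more logical exposure columns.
#'
#' @param records A data.frame.
#' @param exposure_cols Character vector of exposure column names required to
#'   be present.
#' @return The validated data.frame (invisibly coerced types).
#' @export
validate_survival_records <- function(records,
                                      exposure_cols = character()) {
  need <- c("patient_id", "time_days", "event", "event_type", exposure_cols)
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("survival records missing columns: ", paste(miss, collapse = ", "))
  if (any(records$time_days < 0)) stop("negative follow-up times")
  records$event <- as.logical(records$event)
  bad <- !records$event & records$event_type != "none"
  if (any(bad)) stop("event_type must be 'none' for censored records")
  records
}

#' Kaplan-Meier curves by exposure group
#'
#' Product-limit survival estimate per exposure group.
#'
#' @param records Survival-record data.frame (see
#'   [validate_survival_records()]).
#' @param exposure Name of a logical exposure column.
#' @return A `survival::survfit` object.
#' @export
kaplan_meier <- function(records, exposure) {
  records <- validate_survival_records(records, exposure)
  g <- records[[exposure]]
  if (any(tapply(rep(1, nrow(records)), g, sum, default = 0) == 0) ||
      length(unique(g)) < 1 || nrow(records) == 0)
    stop("empty exposure group")
  survival::survfit(survival::Surv(records$time_days, records$event) ~ g)
}

#' Kaplan-Meier curve as a step-function table
#'
#' @param fit A `survfit` object.
#' @return A data.frame with `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_table <- function(fit) {
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) "all" else as.character(s$strata)
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, surv = s$surv)
}

#' Two-group log-rank test
#'
#' @inheritParams kaplan_meier
#' @return List with `chisq` (1 df statistic) and `p`.
#' @export
logrank_test <- function(records, exposure) {
  records <- validate_survival_records(records, exposure)
  g <- records[[exposure]]
  if (length(unique(g)) != 2) stop("log-rank needs exactly two groups")
  if (sum(records$event) < 1) stop("log-rank needs at least one event")
  sd <- survival::survdiff(
    survival::Surv(records$time_days, records$event) ~ g)
  list(chisq = unname(sd$chisq), p = 1 - pchisq(unname(sd$chisq), df = 1))
}

#' Univariable Cox proportional-hazards model
#'
#' Partial-likelihood fit with Efron tie handling (Breslow available), Wald
#' confidence interval and p-value. With no events in one exposure arm the
#' partial likelihood is monotone; the result is flagged as non-converged.
#'
#' @inheritParams kaplan_meier
#' @param ties Tie-handling method passed to `survival::coxph`.
#' @return An object of class `"cox_result"`: list with `hr`, `ci95`, `p`,
#'   `log_hr`, `se`, `n_events`, `converged`, `fit`.
#' @export
cox_univariable <- function(records, exposure, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  records <- validate_survival_records(records, exposure)
  g <- records[[exposure]]
  if (length(unique(g)) < 2) stop("both exposure levels must be present")
  n_events <- sum(records$event)
  if (n_events < 1) stop("at least one event required")
  arm_events <- tapply(records$event, g, sum)
  converged <- all(arm_events > 0)
  if (!converged)
    warning("no events in one exposure arm: monotone partial likelihood, ",
            "hazard ratio diverges")
  fit_call <- function() survival::coxph(
    survival::Surv(records$time_days, records$event) ~ g, ties = ties)
  fit <- if (converged) fit_call() else suppressWarnings(fit_call())
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1, 1]))
  z <- qnorm(0.975)
  structure(list(hr = exp(beta), ci95 = exp(c(beta - z * se, beta + z * se)),
                 p = 2 * pnorm(-abs(beta / se)), log_hr = beta, se = se,
                 n_events = n_events, converged = converged, fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("HR %.2f (95%% CI %.2f-%.2f), p = %.3g, %d events%s\n",
              x$hr, x$ci95[1], x$ci95[2], x$p, x$n_events,
              if (x$converged) "" else " [non-converged]"))
  invisible(x)
}

#' Binary 2-year outcome from survival records
#'
#' Dichotomises follow-up for the C-statistic: `TRUE` when the first
#' composite event occurred within `horizon` days, `FALSE` when followed
#' event-free to at least `min_followup` days, `NA` (excluded) when censored
#' event-free before `min_followup`.
#'
#' @param records Survival-record data.frame.
#' @param horizon Days defining the outcome window (default 730).
#' @param min_followup Minimum event-free follow-up to count as negative
#'   (default 700, i.e. 2 years minus the 30-day visit window).
#' @return Logical vector aligned with `records`.
#' @export
binary_outcome_2y <- function(records, horizon = 730, min_followup = 700) {
  ev <- records$event & records$time_days <= horizon
  neg <- !ev & (records$time_days >= min_followup | records$event)
  out <- rep(NA, nrow(records))
  out[ev] <- TRUE
  out[neg & !ev] <- FALSE
  out
}

#' C-statistic of a binary exposure for a binary outcome
#'
#' Mann-Whitney AUC of the exposure flag for the outcome; for a binary
#' marker this equals (sensitivity + specificity) / 2. The confidence
#' interval uses the DeLong variance.
#'
#' @param exposure Logical exposure flags.
#' @param outcome Logical outcomes (both classes must be present); `NA`
#'   entries are dropped pairwise.
#' @return An object of class `"cstat_result"`: list with `c`, `ci95`, `n`,
#'   and the underlying `pROC::roc` object.
#' @export
binary_cstat <- function(exposure, outcome) {
  keep <- !is.na(exposure) & !is.na(outcome)
  exposure <- as.logical(exposure)[keep]
  outcome <- as.logical(outcome)[keep]
  if (length(unique(outcome)) < 2)
    stop("degenerate outcome: both classes required")
  r <- pROC::roc(response = outcome, predictor = as.numeric(exposure),
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- if (auc %in% c(0, 1))  # DeLong variance degenerates at the extremes
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  else as.numeric(pROC::ci.auc(r, method = "delong"))
  structure(list(c = as.numeric(pROC::auc(r)), ci95 = c(ci[1], ci[3]),
                 n = length(outcome), roc = r),
            class = "cstat_result")
}

#' @export
print.cstat_result <- function(x, ...) {
  cat(sprintf("C-statistic %.2f (95%% CI %.2f-%.2f), n = %d\n",
              x$c, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' C-statistic from published arm counts
#'
#' Reconstructs the binary-exposure C-statistic from event counts per
#' exposure arm, as printed in outcome tables.
#'
#' @param events_exposed,n_exposed Events and size of the exposed arm.
#' @param events_unexposed,n_unexposed Events and size of the unexposed arm.
#' @return A `"cstat_result"` (see [binary_cstat()]).
#' @export
cstat_from_counts <- function(events_exposed, n_exposed,
                              events_unexposed, n_unexposed) {
  exposure <- rep(c(TRUE, FALSE), c(n_exposed, n_unexposed))
  outcome <- c(rep(c(TRUE, FALSE), c(events_exposed,
                                     n_exposed - events_exposed)),
               rep(c(TRUE, FALSE), c(events_unexposed,
                                     n_unexposed - events_unexposed)))
  binary_cstat(exposure, outcome)
}

#' DeLong test for paired C-statistics
#'
#' Covariance-adjusted z-test for the difference of two AUCs computed on the
#' same patients. A predictor compared with itself returns a difference of 0
#' and p = 1.
#'
#' @param exposure_a,exposure_b Two exposure flags scored on the identical
#'   patient set.
#' @param outcome Logical outcomes; `NA` entries are dropped pairwise.
#' @return List with `delta` (C_a - C_b), `p`, `c_a`, `c_b`.
#' @export
delong_paired_test <- function(exposure_a, exposure_b, outcome) {
  if (length(exposure_a) != length(exposure_b) ||
      length(exposure_a) != length(outcome))
    stop("predictors and outcome must cover the identical patient set")
  keep <- !is.na(exposure_a) & !is.na(exposure_b) & !is.na(outcome)
  a <- as.numeric(exposure_a[keep]); b <- as.numeric(exposure_b[keep])
  y <- as.logical(outcome[keep])
  ra <- pROC::roc(y, a, levels = c(FALSE, TRUE), direction = "<",
                  quiet = TRUE)
  rb <- pROC::roc(y, b, levels = c(FALSE, TRUE), direction = "<",
                  quiet = TRUE)
  delta <- as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb))
  if (identical(a, b))
    return(list(delta = 0, p = 1, c_a = as.numeric(pROC::auc(ra)),
                c_b = as.numeric(pROC::auc(rb))))
  tt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  list(delta = delta, p = tt$p.value, c_a = as.numeric(pROC::auc(ra)),
       c_b = as.numeric(pROC::auc(rb)))
}
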