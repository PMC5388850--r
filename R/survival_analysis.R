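# Kaplan-Meier recurrence-free-survival curves and log-rank comparison,
# including stratification by QUS-predicted response.

validate_survival_records <- function(records) {
  need <- c("months", "event")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop_format("survival records missing column(s): ",
                paste(missing, collapse = ", "))
  if (nrow(records) < 1) stop_invalid("need at least one survival record")
  if (any(!is.finite(records$months) | records$months < 0))
    stop_invalid("times must be finite and >= 0")
  if (any(!records$event %in% c(0, 1)))
    stop_invalid("event flags must be 0/1")
  records
}

#' Kaplan-Meier curve
#'
#' Product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i / n_i)`.
#' Censored observations reduce the risk set without producing steps; ties
#' between events and censorings at the same time are resolved events-first
#' (the standard convention). Computed with the survival package.
#'
#' @param records data.frame with `months` (non-negative time to event or
#'   censoring) and `event` (1 = recurrence/death, 0 = censored).
#' @return object of class `km_curve`: `time`, `surv`, `n_risk`, `n_event`,
#'   `n_censor` at each distinct observed time, plus `n` records.
#' @export
km_curve <- function(records) {
  records <- validate_survival_records(records)
  fit <- survival::survfit(survival::Surv(months, event) ~ 1, data = records)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 n = nrow(records)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step-function evaluation; `S(t) = 1` before the first
#' event.
#'
#' @param curve a [km_curve()].
#' @param times numeric vector of times.
#' @export
km_surv_at <- function(curve, times) {
  ev <- curve$n_event > 0
  tt <- curve$time[ev]; ss <- curve$surv[ev]
  vapply(times, function(t) {
    i <- which(tt <= t)
    if (!length(i)) 1 else ss[max(i)]
  }, numeric(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events\n",
              x$n, sum(x$n_event)))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xmax = NULL, ...) {
  t <- c(0, x$time); s <- c(1, x$surv)
  if (!is.null(xmax)) { keep <- t <= xmax; t <- t[keep]; s <- s[keep] }
  graphics::plot(t, s, type = "s", ylim = c(0, 1), xlab = "months",
                 ylab = "recurrence-free survival", ...)
  invisible(x)
}

#' Log-rank test between two groups
#'
#' Standard log-rank chi-square with 1 degree of freedom over the pooled
#' event times (survival::survdiff). Undefined (NA statistic/p) when neither
#' group has an event.
#'
#' @param records data.frame with `months`, `event` and a two-level `group`
#'   column.
#' @return list: `chisq`, `p_value`, `n` per group.
#' @export
log_rank <- function(records) {
  records <- validate_survival_records(records)
  if (!"group" %in% names(records))
    stop_format("survival records missing column(s): group")
  g <- factor(records$group)
  if (nlevels(g) != 2) stop_invalid("log-rank needs exactly two groups")
  if (sum(records$event) == 0)
    return(list(chisq = NA_real_, p_value = NA_real_, n = table(g)))
  sd <- survival::survdiff(survival::Surv(months, event) ~ group,
                           data = records)
  list(chisq = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = table(g))
}

#' Survival stratification by predicted response
#'
#' Replaces the grouping of the survival records with the classifier's
#' predicted labels (matched by patient id) and recomputes the two
#' Kaplan-Meier curves and the log-rank comparison, mirroring the
#' truth-stratified analysis.
#'
#' @param result a [loocv_evaluate()] result (named predictions), or a named
#'   character vector of predicted labels.
#' @param records data.frame with `patient_id`, `months`, `event`.
#' @return list: `curves` (named list of [km_curve()] per predicted group),
#'   `log_rank`, `records` (with the `group` column replaced).
#' @export
stratify_by_prediction <- function(result, records) {
  pred <- if (inherits(result, "qus_loocv")) result$predicted else result
  records <- validate_survival_records(records)
  if (!"patient_id" %in% names(records))
    stop_format("survival records missing column(s): patient_id")
  i <- match(records$patient_id, names(pred))
  if (anyNA(i))
    stop_invalid("missing prediction for patient(s): ",
                 paste(records$patient_id[is.na(i)], collapse = ", "))
  records$group <- as.character(pred[i])
  curves <- lapply(split(records, records$group), km_curve)
  list(curves = curves, log_rank = log_rank(records), records = records)
}
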