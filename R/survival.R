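#' Median-split grouping by response level
#'
#' Patients strictly above the cohort median are HIGH; values at or below
#' the median (including ties at the median) are LOW. With an even number of
#' patients the median is the midpoint of the two central order statistics.
#'
#' @param values Named numeric vector (names = patient ids) of the response
#'   level used for splitting, length >= 2.
#' @return Character vector of `"HIGH"`/`"LOW"`, named like `values`.
#' @export
median_split <- function(values) {
  if (length(values) < 2) abort("need at least 2 patients")
  m <- median(values)
  if (all(values == values[1])) {
    warn("all response values identical; every patient grouped LOW")
  }
  out <- ifelse(values > m, "HIGH", "LOW")
  names(out) <- names(values)
  out
}

#' Kaplan-Meier survival curve of one group
#'
#' Product-limit estimator: starts at 1, drops only at event times; censored
#' times reduce the risk set without a drop.
#'
#' @param months Follow-up times (> 0).
#' @param event Logical (or 0/1) event indicator.
#' @return Tibble of the step function: `time`, `n_risk`, `n_event`,
#'   `survival` — one row per distinct observed time, plus time 0.
#' @export
km_curve <- function(months, event) {
  if (!length(months)) abort("need at least one record")
  if (any(months <= 0)) abort("months must be > 0")
  fit <- survival::survfit(survival::Surv(months, as.integer(event)) ~ 1)
  tibble::tibble(
    time = c(0, fit$time),
    n_risk = c(fit$n, fit$n.risk),
    n_event = c(0L, fit$n.event),
    survival = c(1, fit$surv))
}

#' Mantel-Cox log-rank comparison of two survival groups
#'
#' At each distinct event time the observed number of events in the HIGH
#' group is compared with its hypergeometric expectation given the risk
#' sets; the statistic is `(sum(O) - sum(E))^2 / sum(V)`, referred to a
#' chi-square distribution with 1 degree of freedom (two-sided). Ties use
#' the simultaneous-risk-set convention and censoring at an event time is
#' counted after the event.
#'
#' @param records Tibble with `months`, `event` and `group`
#'   (`"HIGH"`/`"LOW"`), e.g. from [read_survival_table()] after
#'   [median_split()].
#' @return List with `chi_square`, `p`, `n_high`, `n_low`; both entries are
#'   `NA` (undefined-test sentinel) when the total log-rank variance is zero.
#' @export
logrank_test <- function(records) {
  g <- factor(records$group, levels = c("HIGH", "LOW"))
  if (any(is.na(g))) abort("group must be HIGH or LOW")
  if (!all(table(g) > 0)) abort("both groups must be non-empty")
  if (!any(records$event > 0)) abort("need at least one event")
  sd <- tryCatch(
    survival::survdiff(
      survival::Surv(records$months, as.integer(records$event)) ~ g),
    error = function(e) NULL)
  if (is.null(sd) || !is.finite(sd$chisq)) {
    return(list(chi_square = NA_real_, p = NA_real_,
                n_high = sum(g == "HIGH"), n_low = sum(g == "LOW")))
  }
  list(chi_square = unname(sd$chisq),
       p = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n_high = sum(g == "HIGH"), n_low = sum(g == "LOW"))
}

#' Survival analysis of a response-graded cohort
#'
#' Convenience wrapper: median-split on a response value, then Kaplan-Meier
#' curves per group and the log-rank test.
#'
#' @param records Survival tibble with `patient_id`, `months`, `event` and
#'   either `group` or `value` (response level to median-split).
#' @return List with `groups` (patient -> HIGH/LOW), `curves` (named list of
#'   KM tibbles) and `test` (log-rank result).
#' @export
survival_by_response <- function(records) {
  if (!"group" %in% names(records)) {
    if (!"value" %in% names(records)) abort("need a group or value column")
    records$group <- median_split(
      setNames(records$value, records$patient_id))
  }
  curves <- lapply(split(records, records$group), function(d) {
    km_curve(d$months, d$event)
  })
  list(groups = setNames(records$group, records$patient_id),
       curves = curves,
       test = logrank_test(records))
}
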