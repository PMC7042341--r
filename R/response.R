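#' Background-subtracted (net) response
#'
#' Specific cytokine response as the stimulated percentage minus the
#' unstimulated (NS) control, floored at zero.
#'
#' @param pct_stim,pct_ns Percentages in `[0, 100]`.
#' @return Net response in percentage points (vectorised).
#' @export
net_response <- function(pct_stim, pct_ns) {
  if (any(c(pct_stim, pct_ns) < 0 | c(pct_stim, pct_ns) > 100, na.rm = TRUE)) {
    abort("percentages must lie in [0, 100]")
  }
  pmax(pct_stim - pct_ns, 0)
}

#' Responder call from a net response
#'
#' @param net Net response (percentage points, >= 0).
#' @param floor Closed threshold: responder iff `net >= floor`
#'   (default 0.01 percentage points).
#' @return Logical (vectorised).
#' @export
call_responder <- function(net, floor = 0.01) {
  if (floor < 0) abort("floor must be >= 0")
  net >= floor
}

#' Per-pool response magnitude across patients
#'
#' The cumulative response (magnitude) of a pool is the arithmetic mean of
#' net responses across all patients tested, computed per
#' (pool, subset, cytokine, timepoint). Missing patient cells are excluded
#' pairwise; the count used is reported.
#'
#' @param responses Response tibble (see [read_response_table()]).
#' @param floor Responder floor forwarded to the `responder` column.
#' @return Tibble with `timepoint`, `subset`, `cytokine`, `pool`,
#'   `magnitude` (mean net, percentage points), `n_patients`,
#'   `pct_responders`.
#' @export
response_magnitude <- function(responses, floor = 0.01) {
  x <- dplyr::mutate(responses,
                     net = net_response(.data$pct_stim, .data$pct_ns))
  x <- dplyr::filter(x, !is.na(.data$net))
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$timepoint, .data$subset, .data$cytokine,
                    .data$pool),
    magnitude = mean(.data$net),
    n_patients = dplyr::n_distinct(.data$patient_id),
    pct_responders = 100 * mean(call_responder(.data$net, floor)),
    .groups = "drop")
  if (!nrow(out)) warn("no non-missing responses; empty magnitude table")
  out
}

#' Responder fold change between treatment stages
#'
#' Ratio of the percentage of responders after the second treatment stage
#' (chemotherapy followed by anti-PD-1) to the percentage after chemotherapy
#' alone. Division edge cases are encoded as sentinels: positive/zero gives
#' `Inf`, zero/zero gives `NaN`.
#'
#' @param pct_responders_t2,pct_responders_t1 Responder percentages in
#'   `[0, 100]`.
#' @return Fold change (vectorised), with `Inf`/`NaN` sentinels.
#' @export
responder_fold_change <- function(pct_responders_t2, pct_responders_t1) {
  p <- c(pct_responders_t2, pct_responders_t1)
  if (any(p < 0 | p > 100, na.rm = TRUE)) {
    abort("percentages must lie in [0, 100]")
  }
  ifelse(pct_responders_t1 == 0 & pct_responders_t2 == 0, NaN,
         pct_responders_t2 / pct_responders_t1)
}

#' PD-1 kinetics within antigen-specific T cells
#'
#' Pairs, per timepoint (and subset), the mean percentage of PD-1-positive
#' cells within the specific population with the mean net specific response,
#' the series behind the rise-then-fall of PD-1 across chemotherapy and
#' checkpoint blockade while the specific response keeps increasing.
#'
#' @param responses Response tibble containing a `pct_pd1` column.
#' @return Tibble with `timepoint`, `subset`, `mean_pd1`, `mean_net`, `n`.
#' @export
pd1_kinetics <- function(responses) {
  if (!"pct_pd1" %in% names(responses) || all(is.na(responses$pct_pd1))) {
    warn("no PD-1 measurements present")
    return(tibble::tibble(timepoint = character(), subset = character(),
                          mean_pd1 = double(), mean_net = double(),
                          n = integer()))
  }
  x <- dplyr::mutate(responses,
                     net = net_response(.data$pct_stim, .data$pct_ns))
  x <- dplyr::filter(x, !is.na(.data$pct_pd1))
  dplyr::summarise(
    dplyr::group_by(x, .data$timepoint, .data$subset),
    mean_pd1 = mean(.data$pct_pd1),
    mean_net = mean(.data$net, na.rm = TRUE),
    n = dplyr::n(),
    .groups = "drop")
}

#' Two-sample t comparison
#'
#' Classical two-sample t statistic with two-sided p-value; pooled variance
#' by default, Welch by flag. Degenerate inputs are encoded as sentinels
#' rather than errors: zero pooled variance gives t = 0, p = 1 when the
#' means agree and t = +/-Inf, p = 0 when they differ.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param var_equal Pooled-variance t (default `TRUE`); `FALSE` for Welch.
#' @return List with `t`, `df`, `p`.
#' @export
compare_groups <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) abort("each sample needs n >= 2")
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  if (pooled_var == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2,
                                        p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' One-way ANOVA F statistic
#'
#' Thin supporting wrapper for comparing overall response across groups
#' (e.g. healthy donors, naive patients, T0/T1/T2).
#'
#' @param values Numeric response values.
#' @param groups Group labels, same length.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort("need at least two groups")
  fit <- aov(values ~ groups)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], df1 = s[["Df"]][1], df2 = s[["Df"]][2],
       p = s[["Pr(>F)"]][1])
}
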