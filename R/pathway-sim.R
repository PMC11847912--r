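#' Staffing model for triage workload accounting
#'
#' Captures the workload arithmetic of remote triage: each clinician review
#' of a response takes `minutes_per_clinical_review` (2 min by default)
#' while automated assessment is real-time (0 min); a full-time equivalent
#' (FTE) is 37.5 h/week, 1950 h/year. Annual FTE is reported per
#' `caseload_scale` patients: study staff-hours are annualised by
#' `annualization` (default 12/9, a nine-month study window) and scaled
#' from `study_patients` (default 200) to the caseload.
#'
#' @param minutes_per_clinical_review minutes per clinician review.
#' @param minutes_per_automated minutes per automated assessment.
#' @param weekly_fte_hours weekly full-time hours.
#' @param caseload_scale patient caseload FTEs are reported per.
#' @param study_patients number of patients generating the study's
#'   responses.
#' @param annualization factor converting study-period hours to a full
#'   year.
#' @return Object of class `staffing_model`; `annual_fte_hours` is always
#'   `weekly_fte_hours * 52`.
#' @examples
#' sm <- staffing_model()
#' staffing(1545, sm, baseline_reviewed = 1545)  # 51.5 h, FTE 0.176
#' @export
staffing_model <- function(minutes_per_clinical_review = 2,
                           minutes_per_automated = 0,
                           weekly_fte_hours = 37.5,
                           caseload_scale = 1000,
                           study_patients = 200,
                           annualization = 12 / 9) {
  stopifnot(minutes_per_clinical_review >= 0, minutes_per_automated >= 0,
            weekly_fte_hours > 0, caseload_scale > 0, study_patients > 0,
            annualization > 0)
  structure(list(
    minutes_per_clinical_review = minutes_per_clinical_review,
    minutes_per_automated = minutes_per_automated,
    weekly_fte_hours = weekly_fte_hours,
    annual_fte_hours = weekly_fte_hours * 52,
    caseload_scale = caseload_scale,
    study_patients = study_patients,
    annualization = annualization
  ), class = "staffing_model")
}

#' Define an implementation strategy
#'
#' @param kind `"full_clinical"` (every response triaged by a clinician),
#'   `"hybrid"` (model rules out responses with predicted risk at or below
#'   the threshold; clinicians triage the remainder) or `"full_auto"`
#'   (routing purely by the model threshold, no clinician reviews).
#' @param threshold rule-out probability cut-off; "low risk" means
#'   predicted probability \eqn{\le} threshold. Required for `hybrid` and
#'   `full_auto`.
#' @return Object of class `triage_strategy`.
#' @export
triage_strategy <- function(kind = c("full_clinical", "hybrid", "full_auto"),
                            threshold = NULL) {
  kind <- match.arg(kind)
  if (kind != "full_clinical") {
    if (is.null(threshold)) {
      stop(sprintf("strategy `%s` requires a probability threshold", kind),
           call. = FALSE)
    }
    stop_if_not_prob(threshold, "threshold")
  }
  structure(list(kind = kind, threshold = threshold),
            class = "triage_strategy")
}

#' Route responses under an implementation strategy
#'
#' Converts model predictions and clinician triage labels into per-response
#' decisions. Under `full_clinical` every response is clinician-reviewed
#' and the decision follows the recorded triage label (moderate/high risk
#' means in-person review). Under `hybrid`, responses with fused risk at or
#' below the threshold are ruled out automatically (no clinician sees
#' them); the remainder are clinician-reviewed and decided by their triage
#' label. Under `full_auto` the threshold alone decides and no response is
#' clinician-reviewed.
#'
#' @param responses data frame with `response_id` and `triage_label`
#'   (`low`/`moderate`/`high`; label may be absent/NA only for
#'   `full_auto`).
#' @param predictions named vector of fused probabilities (names =
#'   response ids) or a data frame with `response_id` and `p_fused`.
#' @param strategy a [triage_strategy()].
#' @return Data frame: `response_id`, `decision`
#'   (`"low_risk"`/`"in_person_review"`), `clinician_reviewed` (logical).
#' @export
route <- function(responses, predictions, strategy) {
  stopifnot(inherits(strategy, "triage_strategy"))
  if (is.data.frame(predictions)) {
    predictions <- setNames(predictions$p_fused, predictions$response_id)
  }
  p <- if (is.null(predictions)) rep(NA_real_, nrow(responses))
       else unname(predictions[responses$response_id])
  if (strategy$kind != "full_clinical" && anyNA(p)) {
    stop("missing prediction for response(s): ",
         paste(head(responses$response_id[is.na(p)], 3), collapse = ", "),
         call. = FALSE)
  }
  lab <- responses$triage_label
  needs_label <- switch(strategy$kind,
                        full_clinical = rep(TRUE, nrow(responses)),
                        hybrid = p > strategy$threshold,
                        full_auto = rep(FALSE, nrow(responses)))
  if (any(needs_label & (is.na(lab) | !lab %in% c("low", "moderate", "high")))) {
    stop("clinician triage label required but missing/invalid under ",
         "strategy ", strategy$kind, call. = FALSE)
  }
  suspicious <- lab %in% c("moderate", "high")
  out <- switch(strategy$kind,
    full_clinical = data.frame(
      decision = ifelse(suspicious, "in_person_review", "low_risk"),
      clinician_reviewed = TRUE),
    hybrid = data.frame(
      decision = ifelse(p <= strategy$threshold, "low_risk",
                        ifelse(suspicious, "in_person_review", "low_risk")),
      clinician_reviewed = p > strategy$threshold),
    full_auto = data.frame(
      decision = ifelse(p <= strategy$threshold, "low_risk",
                        "in_person_review"),
      clinician_reviewed = FALSE))
  cbind(response_id = responses$response_id, out,
        stringsAsFactors = FALSE)
}

#' Tally routing decisions against confirmed SSI
#'
#' "Positive" is routing to in-person review; truth is confirmed SSI within
#' 48 h of the response.
#'
#' @param decisions character vector (`"low_risk"`/`"in_person_review"`) or
#'   the data frame returned by [route()].
#' @param ssi48 binary outcome vector, aligned with `decisions`.
#' @return Object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_counts <- function(decisions, ssi48) {
  if (is.data.frame(decisions)) decisions <- decisions$decision
  if (length(decisions) != length(ssi48)) {
    stop("`decisions` and `ssi48` lengths differ", call. = FALSE)
  }
  stopifnot(all(decisions %in% c("low_risk", "in_person_review")),
            all(ssi48 %in% c(0, 1)))
  pos <- decisions == "in_person_review"
  structure(list(tp = sum(pos & ssi48 == 1),
                 fp = sum(pos & ssi48 == 0),
                 tn = sum(!pos & ssi48 == 0),
                 fn = sum(!pos & ssi48 == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: tp %d, fp %d, tn %d, fn %d (n = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

metric_or_na <- function(num, den) if (den == 0) NA_real_ else num / den

#' Diagnostic-accuracy metrics with confidence intervals
#'
#' Sensitivity, specificity, PPV, NPV and the failure rate (the proportion
#' of responses stratified low risk that are diagnosed with SSI within
#' 48 h, identically 1 - NPV). A metric with a zero denominator is
#' returned as `NA` and flagged in `undefined` rather than silently zero.
#'
#' @param counts a `confusion_counts` object.
#' @param ci_method `"wilson"` (default) or `"wald"`; clinical reports
#'   often print Wald intervals.
#' @param level confidence level.
#' @return Object of class `diagnostic_metrics`: per-metric `estimate` and
#'   `ci`.
#' @export
diagnostics <- function(counts, ci_method = c("wilson", "wald"),
                        level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  ci_method <- match.arg(ci_method)
  defs <- list(
    sensitivity = c(counts$tp, counts$tp + counts$fn),
    specificity = c(counts$tn, counts$tn + counts$fp),
    ppv = c(counts$tp, counts$tp + counts$fp),
    npv = c(counts$tn, counts$tn + counts$fn),
    failure_rate = c(counts$fn, counts$tn + counts$fn))
  metrics <- lapply(defs, function(d) {
    list(estimate = metric_or_na(d[1], d[2]),
         ci = prop_ci(d[1], d[2], level, ci_method))
  })
  # the failure rate is *identically* 1 - NPV
  metrics$failure_rate$estimate <- 1 - metrics$npv$estimate
  undefined <- names(defs)[vapply(defs, function(d) d[2] == 0, logical(1))]
  structure(list(metrics = metrics, counts = counts,
                 ci_method = ci_method, level = level,
                 undefined = undefined),
            class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  for (m in names(x$metrics)) {
    e <- x$metrics[[m]]
    if (is.na(e$estimate)) {
      cat(sprintf("  %-12s undefined (zero denominator)\n", m))
    } else if (m == "failure_rate") {
      cat(sprintf("  %-12s %.1f%% (%.1f-%.1f)\n", m, 100 * e$estimate,
                  100 * e$ci[1], 100 * e$ci[2]))
    } else {
      cat(sprintf("  %-12s %.3f (%.3f-%.3f)\n", m, e$estimate,
                  e$ci[1], e$ci[2]))
    }
  }
  invisible(x)
}

#' Staff-hours, percentage reduction and annual FTE
#'
#' @param n_clinician_reviewed number of responses reviewed by clinicians.
#' @param sm a [staffing_model()].
#' @param baseline_reviewed review count of the comparator pathway (full
#'   clinical assessment) for the percentage reduction.
#' @return List: `staff_hours`, `reduction_pct` (negative = fewer hours
#'   than baseline), `fte_per_caseload`.
#' @export
staffing <- function(n_clinician_reviewed, sm = staffing_model(),
                     baseline_reviewed = n_clinician_reviewed) {
  stopifnot(inherits(sm, "staffing_model"), n_clinician_reviewed >= 0)
  if (baseline_reviewed == 0 && n_clinician_reviewed > 0) {
    stop("baseline review count is zero but the strategy reviews responses",
         call. = FALSE)
  }
  hours <- n_clinician_reviewed * sm$minutes_per_clinical_review / 60
  reduction <- if (baseline_reviewed == 0) 0 else
    -100 * (1 - n_clinician_reviewed / baseline_reviewed)
  fte <- hours * sm$annualization *
    (sm$caseload_scale / sm$study_patients) / sm$annual_fte_hours
  list(staff_hours = hours, reduction_pct = reduction,
       fte_per_caseload = fte)
}

#' Simulate one implementation strategy end to end
#'
#' Routes every response, tallies the confusion counts against confirmed
#' SSI within 48 h, computes diagnostic accuracy and workload.
#'
#' @inheritParams route
#' @param sm a [staffing_model()].
#' @param baseline_reviewed clinician review count of the full-clinical
#'   comparator (defaults to the number of responses, i.e. everyone
#'   reviewed).
#' @param ci_method passed to [diagnostics()].
#' @return Object of class `pathway_outcome`.
#' @export
pathway_outcome <- function(responses, predictions, strategy,
                            sm = staffing_model(),
                            baseline_reviewed = nrow(responses),
                            ci_method = "wilson") {
  routed <- route(responses, predictions, strategy)
  counts <- confusion_counts(routed$decision, responses$ssi48)
  diag <- diagnostics(counts, ci_method)
  n_rev <- sum(routed$clinician_reviewed)
  work <- staffing(n_rev, sm, baseline_reviewed)
  structure(list(strategy = strategy,
                 n_responses = nrow(responses),
                 n_clinician_reviewed = n_rev,
                 n_in_person = counts$tp + counts$fp,
                 counts = counts, diagnostics = diag,
                 staff_hours = work$staff_hours,
                 staff_hours_reduction = work$reduction_pct,
                 fte_per_caseload = work$fte_per_caseload),
            class = "pathway_outcome")
}

#' @export
print.pathway_outcome <- function(x, ...) {
  thr <- if (is.null(x$strategy$threshold)) "-" else
    sprintf("%.2f", x$strategy$threshold)
  cat(sprintf("strategy: %s (threshold %s)\n", x$strategy$kind, thr))
  cat(sprintf("  responses %d; clinician-reviewed %d (%.1f%%); in-person review %d (%.1f%%)\n",
              x$n_responses, x$n_clinician_reviewed,
              100 * x$n_clinician_reviewed / x$n_responses,
              x$n_in_person, 100 * x$n_in_person / x$n_responses))
  print(x$diagnostics)
  cat(sprintf("  staff-hours %.1f (%.1f%%); annual FTE / caseload %.3f\n",
              x$staff_hours, x$staff_hours_reduction, x$fte_per_caseload))
  invisible(x)
}

#' Threshold sensitivity analysis
#'
#' Re-simulates a strategy over a grid of rule-out thresholds, reporting
#' diagnostic accuracy, failure rate, staff-hours and annual FTE at each.
#'
#' @inheritParams pathway_outcome
#' @param strategy_kind `"hybrid"` or `"full_auto"`.
#' @param grid sorted vector of thresholds in \[0, 1\].
#' @return Data frame with one row per threshold.
#' @export
threshold_sweep <- function(responses, predictions, strategy_kind, grid,
                            sm = staffing_model(),
                            baseline_reviewed = nrow(responses)) {
  if (length(grid) == 0) stop("threshold grid is empty", call. = FALSE)
  stop_if_not_prob(grid, "grid")
  if (is.unsorted(grid)) stop("threshold grid must be sorted", call. = FALSE)
  rows <- lapply(grid, function(thr) {
    po <- pathway_outcome(responses, predictions,
                          triage_strategy(strategy_kind, thr), sm,
                          baseline_reviewed)
    est <- function(m) po$diagnostics$metrics[[m]]$estimate
    data.frame(threshold = thr, strategy = strategy_kind,
               n_clinician_reviewed = po$n_clinician_reviewed,
               n_in_person = po$n_in_person,
               sensitivity = est("sensitivity"),
               specificity = est("specificity"),
               ppv = est("ppv"), npv = est("npv"),
               failure_rate = est("failure_rate"),
               staff_hours = po$staff_hours,
               staff_hours_reduction = po$staff_hours_reduction,
               fte_per_caseload = po$fte_per_caseload)
  })
  do.call(rbind, rows)
}

#' Plot a threshold sweep
#'
#' Failure rate and annual FTE per caseload against the rule-out
#' threshold, mirroring the sensitivity-analysis figures of triage
#' simulation studies. Requires ggplot2.
#'
#' @param sweep data frame from [threshold_sweep()] (possibly several
#'   strategies row-bound together).
#' @return A ggplot object.
#' @export
plot_threshold_sweep <- function(sweep) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_threshold_sweep requires ggplot2", call. = FALSE)
  }
  long <- rbind(
    data.frame(threshold = sweep$threshold, strategy = sweep$strategy,
               panel = "failure rate (1 - NPV)", value = sweep$failure_rate),
    data.frame(threshold = sweep$threshold, strategy = sweep$strategy,
               panel = "annual FTE / 1000 caseload",
               value = sweep$fte_per_caseload))
  ggplot2::ggplot(long, ggplot2::aes(x = threshold, y = value,
                                     colour = strategy)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "rule-out threshold for P(SSI)", y = NULL) +
    ggplot2::theme_minimal()
}
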