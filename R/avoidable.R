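# Avoidable adverse events: converting a per-year GMTE risk difference plus
# carrier exposure into avoided-case counts and percentage reductions — the
# genotype-guided-prescribing illustration.

#' Avoidable adverse-event arithmetic
#'
#' Multiplies a per-year risk difference by the carrier patient-years of
#' exposure to obtain the number of cases that would have been avoided had
#' carriers experienced the non-carrier event rate, then expresses it as
#' absolute and percentage reductions. Rounding is to the nearest integer,
#' half away from zero; percentages are reported to one decimal place (plus a
#' rounded-integer form).
#'
#' @param risk_diff_per_year Per-year risk difference attributable to the
#'   genotype under treatment (fraction per year, e.g. 0.0008 for 0.08%).
#' @param carrier_patient_years Carrier patient-years of statin exposure.
#' @param cases_total Observed cases, all statin users.
#' @param cases_carriers Observed cases among carriers.
#' @return Object of class `avoidable_events_report`: list with
#'   `risk_diff_per_year`, `carrier_patient_years`, `avoided_cases`,
#'   `cases_total_before/after`, `cases_carriers_before/after`,
#'   `pct_reduction_all`, `pct_reduction_carriers` (1 decimal) and
#'   `pct_reduction_all_int`, `pct_reduction_carriers_int` (rounded integer),
#'   plus a `capped` flag.
#' @export
avoidable_events <- function(risk_diff_per_year, carrier_patient_years,
                             cases_total, cases_carriers) {
  args <- c(risk_diff_per_year, carrier_patient_years, cases_total,
            cases_carriers)
  if (any(!is.finite(args)) || any(args < 0)) {
    stop("all inputs must be non-negative numbers", call. = FALSE)
  }
  if (cases_carriers > cases_total) {
    stop("cases_carriers cannot exceed cases_total", call. = FALSE)
  }
  avoided <- round_half_away(risk_diff_per_year * carrier_patient_years)
  capped <- FALSE
  if (avoided > cases_carriers) {
    warning("predicted avoided cases exceed observed carrier cases; capped")
    avoided <- cases_carriers
    capped <- TRUE
  }
  pct <- function(num, den) if (den > 0) 100 * num / den else 0
  structure(list(
    risk_diff_per_year = risk_diff_per_year,
    carrier_patient_years = carrier_patient_years,
    avoided_cases = as.integer(avoided),
    cases_total_before = as.integer(cases_total),
    cases_total_after = as.integer(cases_total - avoided),
    cases_carriers_before = as.integer(cases_carriers),
    cases_carriers_after = as.integer(cases_carriers - avoided),
    pct_reduction_all = round_half_away(pct(avoided, cases_total), 1),
    pct_reduction_carriers = round_half_away(pct(avoided, cases_carriers), 1),
    pct_reduction_all_int = as.integer(round_half_away(pct(avoided, cases_total))),
    pct_reduction_carriers_int = as.integer(round_half_away(pct(avoided, cases_carriers))),
    capped = capped
  ), class = "avoidable_events_report")
}

#' @export
print.avoidable_events_report <- function(x, ...) {
  cat(sprintf(
    paste0("Avoidable events at %.4g/yr over %s carrier patient-years:\n",
           "  avoided %d cases (all users %d -> %d, carriers %d -> %d)\n",
           "  reduction: %.1f%% of all cases, %.1f%% of carrier cases\n"),
    x$risk_diff_per_year, format(x$carrier_patient_years, big.mark = ","),
    x$avoided_cases, x$cases_total_before, x$cases_total_after,
    x$cases_carriers_before, x$cases_carriers_after,
    x$pct_reduction_all, x$pct_reduction_carriers))
  invisible(x)
}

#' Wire a triangulation report into the avoidable-events illustration
#'
#' Takes a [triangulate()] result on the per-year risk-difference scale and a
#' cohort summary of exposures/cases, and produces the avoidable-events
#' report with provenance. If the Q-gate refused the combination, no report
#' is produced and the refusal is explained.
#'
#' @param triangulation A [triangulate()] result
#'   (`scale = "per_year_risk_difference"`).
#' @param cohort_summary List with `carrier_patient_years`, `cases_total`,
#'   `cases_carriers` (e.g. from [cohort_event_summary()]).
#' @return An `avoidable_events_report` with a `provenance` element, or an
#'   object of class `avoidable_events_refusal` when the Q-gate failed.
#' @export
pipeline_illustration <- function(triangulation, cohort_summary) {
  stopifnot(inherits(triangulation, "gmte_triangulation"))
  if (!identical(triangulation$scale, "per_year_risk_difference")) {
    stop("triangulation must be on the per_year_risk_difference scale",
         call. = FALSE)
  }
  need <- c("carrier_patient_years", "cases_total", "cases_carriers")
  if (!all(need %in% names(cohort_summary))) {
    stop("cohort_summary needs: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (cohort_summary$carrier_patient_years <= 0) {
    stop("carrier stratum is empty (zero carrier patient-years)", call. = FALSE)
  }
  if (is.null(triangulation$combined)) {
    return(structure(list(
      reason = "heterogeneity gate refused the combined estimate",
      het = triangulation$het), class = "avoidable_events_refusal"))
  }
  report <- avoidable_events(max(triangulation$combined$estimate, 0),
                             cohort_summary$carrier_patient_years,
                             cohort_summary$cases_total,
                             cohort_summary$cases_carriers)
  report$provenance <- list(estimators = triangulation$combine,
                            q_stat = triangulation$het$q_stat,
                            q_p = triangulation$het$p)
  report
}

#' @export
print.avoidable_events_refusal <- function(x, ...) {
  cat("No avoidable-events report:", x$reason, "\n")
  cat(sprintf("  Q = %.3f (df %d), p = %.3g\n", x$het$q_stat, x$het$df,
              x$het$p))
  invisible(x)
}

#' Summarise carrier exposure and events for the illustration
#'
#' @param cohort Cohort data frame with `<outcome>_event`, `<outcome>_time`
#'   and `treated` columns.
#' @param carrier Carrier vector aligned with `cohort` rows.
#' @param outcome Event outcome prefix (default `"muscle"`).
#' @return List with `carrier_patient_years` (treated carriers),
#'   `cases_total` (treated), `cases_carriers` (treated carriers).
#' @export
cohort_event_summary <- function(cohort, carrier, outcome = "muscle") {
  g <- as.numeric(carrier) > 0
  ev <- cohort[[paste0(outcome, "_event")]]
  py <- cohort[[paste0(outcome, "_time")]]
  tr <- cohort$treated
  list(carrier_patient_years = sum(py[tr & g], na.rm = TRUE),
       cases_total = sum(ev[tr], na.rm = TRUE),
       cases_carriers = sum(ev[tr & g], na.rm = TRUE))
}

#' Genotype composition of adverse-event cases
#'
#' Expresses per-genotype case counts as percentages of all cases (one
#' decimal place), e.g. the share of statin-associated muscle symptom (SAMS)
#' cases that are homozygous for a given star allele.
#'
#' @param n_cases_by_group Named integer vector of case counts per genotype
#'   group.
#' @param n_cases_total Total number of cases.
#' @return Data frame `group, n, pct` with `pct` rounded to one decimal.
#' @export
sams_composition <- function(n_cases_by_group, n_cases_total) {
  if (n_cases_total <= 0) stop("total case count must be positive", call. = FALSE)
  if (any(n_cases_by_group < 0) || any(n_cases_by_group > n_cases_total)) {
    stop("group counts must lie in [0, total]", call. = FALSE)
  }
  data.frame(group = names(n_cases_by_group) %||%
               as.character(seq_along(n_cases_by_group)),
             n = as.integer(n_cases_by_group),
             pct = round_half_away(100 * n_cases_by_group / n_cases_total, 1),
             stringsAsFactors = FALSE)
}
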