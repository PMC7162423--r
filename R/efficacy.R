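# Treatment-efficacy summaries: tumor volumetry from per-slice contour
# areas, baseline normalization, Kaplan-Meier survival and overall-survival
# comparisons.

#' Tumor volume from per-slice contour areas
#'
#' Sum of contiguous per-slice tumor areas multiplied by the slice
#' thickness. The thickness is a required acquisition parameter; no default
#' is assumed.
#'
#' @param areas_mm2 per-slice tumor areas in mm^2 (possibly empty).
#' @param slice_thickness_mm slice thickness in mm (> 0).
#' @return volume in mm^3.
#' @export
tumor_volume <- function(areas_mm2, slice_thickness_mm) {
  if (slice_thickness_mm <= 0) stop("slice thickness must be positive")
  if (any(areas_mm2 < 0)) stop("areas must be non-negative")
  sum(areas_mm2) * slice_thickness_mm
}

#' Normalize a per-day series to its baseline day
#'
#' @param values measurements (e.g. tumor volumes).
#' @param days study day of each measurement.
#' @param baseline_day the day whose value becomes 1.
#' @return named vector of ratios value/baseline, names = days.
#' @export
normalize_to_baseline <- function(values, days, baseline_day) {
  i <- which(days == baseline_day)
  if (length(i) != 1) stop("baseline day must appear exactly once")
  if (values[i] <= 0) stop("baseline value must be positive")
  stats::setNames(values / values[i], days)
}

#' Kaplan-Meier survival curve and median
#'
#' Product-limit estimator with right censoring (delegated to the survival
#' package). The median is the first time at which the survival function
#' drops to 0.5 or below; if the curve never reaches 0.5 the median is not
#' reached and `NA` is returned.
#'
#' @param time event/censoring times (> 0).
#' @param event 1/TRUE for event (death/endpoint), 0/FALSE for censored.
#' @return list with `time`, `surv`, `n_risk`, `n_event` (the step
#'   function), `median`, and `n`.
#' @export
km_curve <- function(time, event) {
  if (length(time) == 0) stop("need at least one record")
  if (any(time <= 0)) stop("times must be positive")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- if (any(sf$surv <= 0.5)) sf$time[which(sf$surv <= 0.5)[1]] else NA_real_
  list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
       n_event = sf$n.event, median = med, n = length(time))
}

#' Percent increase in overall survival
#'
#' `100 * (mean_test - mean_reference) / mean_reference`.
#'
#' @param mean_test mean survival of the test arm (days).
#' @param mean_reference mean survival of the reference arm (days, > 0).
#' @return percent change.
#' @export
percent_os_increase <- function(mean_test, mean_reference) {
  if (mean_reference <= 0) stop("reference mean must be positive")
  100 * (mean_test - mean_reference) / mean_reference
}

#' Per-group survival summary
#'
#' Mean and SD of survival time per group (the primary summary), plus the
#' Kaplan-Meier median.
#'
#' @param records data frame with columns `group`, `time_days`, `event`.
#' @return data frame with one row per group: `group`, `n`, `mean_days`,
#'   `sd_days`, `km_median_days`.
#' @export
survival_summary <- function(records) {
  if (!all(c("group", "time_days", "event") %in% names(records))) {
    stop("records must have columns group, time_days, event")
  }
  do.call(rbind, lapply(split(records, records$group), function(g) {
    km <- km_curve(g$time_days, g$event)
    data.frame(group = g$group[1], n = nrow(g),
               mean_days = mean(g$time_days), sd_days = stats::sd(g$time_days),
               km_median_days = km$median, stringsAsFactors = FALSE)
  }))
}
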