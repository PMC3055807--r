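#' Delta Hb: mean absolute consecutive difference
#'
#' Intra-patient haemoglobin variability metric: the average of the absolute
#' value of the differences between consecutive values. Unlike the standard
#' deviation it is sensitive to the ordering of the series, so it picks up
#' week-to-week cycling that the SD is blind to.
#'
#' @param series Ordered haemoglobin values (g/dL), length >= 2.
#' @return Delta Hb in g/dL.
#' @examples
#' delta_hb(c(11, 12, 11))  # 1.0
#' @export
delta_hb <- function(series) {
  if (length(series) < 2L) {
    stop("insufficient-data error: delta Hb needs >= 2 values", call. = FALSE)
  }
  mean(abs(diff(series)))
}

#' Ability score
#'
#' Prescription-quality index over a haemoglobin series. Each value below
#' `target_low` or above `target_high` counts one error point; a value above
#' the safety threshold counts a second point (double error). The score is
#' `2 - E/N`: 2 when every value is in target, 1 when 100% of values are
#' outside target (none above the safety threshold), and below 1 when
#' values exceed the safety threshold.
#'
#' @param series Haemoglobin values (g/dL), length >= 1.
#' @param constants An [esa_constants()] object.
#' @return Dimensionless score.
#' @examples
#' ability_score(c(10, 10, 13.5, 11.5))  # E = 1+1+2+0 = 4 -> 2 - 4/4 = 1
#' @export
ability_score <- function(series, constants = esa_constants()) {
  if (length(series) < 1L) {
    stop("insufficient-data error: ability score needs >= 1 value", call. = FALSE)
  }
  e <- sum(series < constants$target_low) +
    sum(series > constants$target_high) +
    sum(series > constants$safety_threshold)
  2 - e / length(series)
}

#' Target-range occupancy percentages
#'
#' Percentage of values below target, in target, above target and above the
#' safety threshold. Boundary values (exactly `target_low` or `target_high`)
#' count as in-target; the first three percentages partition 100 and the
#' above-safety percentage is a subset of above-target.
#'
#' @param series Haemoglobin values (g/dL), length >= 1.
#' @param constants An [esa_constants()] object.
#' @return Named numeric vector `c(pct_below, pct_in, pct_above,
#'   pct_above_safety)` in percent.
#' @export
target_percentages <- function(series, constants = esa_constants()) {
  n <- length(series)
  if (n < 1L) {
    stop("insufficient-data error: percentages need >= 1 value", call. = FALSE)
  }
  c(pct_below = 100 * sum(series < constants$target_low) / n,
    pct_in = 100 * sum(series >= constants$target_low &
                         series <= constants$target_high) / n,
    pct_above = 100 * sum(series > constants$target_high) / n,
    pct_above_safety = 100 * sum(series > constants$safety_threshold) / n)
}

#' Number of dose adjustments
#'
#' Counts how often the entered dose differs from the previous one over the
#' dosing opportunities; the first dose is not counted as a change.
#'
#' @param doses Dose sequence (U) at the dosing opportunities, length >= 1;
#'   `NA` entries (opportunities with no entry) are dropped.
#' @return Integer count.
#' @export
count_dose_changes <- function(doses) {
  doses <- doses[!is.na(doses)]
  if (length(doses) < 1L) {
    stop("insufficient-data error: need >= 1 dose", call. = FALSE)
  }
  sum(diff(doses) != 0)
}

#' Trapezoidal area under a haemoglobin curve
#'
#' Composite trapezoid rule on `series - baseline` over a uniform weekly
#' grid, used to compare haemoglobin profiles as a function of time.
#'
#' @param series Weekly haemoglobin values (g/dL), length >= 2.
#' @param baseline Baseline (g/dL) subtracted before integration; default 0.
#' @return Area in g/dL * weeks.
#' @export
trapezoid_auc <- function(series, baseline = 0) {
  if (length(series) < 2L) {
    stop("insufficient-data error: AUC needs >= 2 values", call. = FALSE)
  }
  pracma::trapz(seq_along(series) - 1, series - baseline)
}

#' Summarise a session into its statistics window
#'
#' Computes the running-statistics panel of the simulator for a session
#' record: mean haemoglobin with SD, delta Hb, target-occupancy percentages,
#' ability score, mean (and SD of) turnover RBC lifespan, number of dose
#' adjustments and trapezoidal AUC, on a chosen phase and sampling grid.
#'
#' @param record An `esa_session` from [run_session()] (or a compatible data
#'   frame with the same columns).
#' @param phase `"all"`, `"equilibration"` or `"maintenance"`.
#' @param sampling `"weekly"` (every logged week) or `"visible"` (only the
#'   weeks visible to the prescriber in the session's arm).
#' @param values Which haemoglobin series to analyse: `"true"` (default,
#'   the noise-free model output) or `"observed"`.
#' @param constants Constants; default taken from the record's config.
#' @return A `session_stats` list with fields `n`, `mean_hb`, `sd_hb`,
#'   `delta_hb`, `pct_below`, `pct_in`, `pct_above`, `pct_above_safety`,
#'   `ability_score`, `mean_rbc_lifespan`, `sd_rbc_lifespan`,
#'   `n_dose_changes`, `auc`.
#' @export
summarize_session <- function(record,
                              phase = c("all", "equilibration", "maintenance"),
                              sampling = c("weekly", "visible"),
                              values = c("true", "observed"),
                              constants = NULL) {
  phase <- match.arg(phase)
  sampling <- match.arg(sampling)
  values <- match.arg(values)
  if (is.null(constants)) {
    cfg <- attr(record, "config")
    constants <- if (!is.null(cfg)) cfg$constants else esa_constants()
  }
  rows <- rep(TRUE, nrow(record))
  if (phase != "all") rows <- rows & record$phase == phase
  if (sampling == "visible") rows <- rows & record$visible
  sel <- record[rows, , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop("insufficient-data error: empty phase/sampling selection", call. = FALSE)
  }
  hb <- if (values == "true") sel$true_hb else sel$observed_hb
  pct <- target_percentages(hb, constants)
  doses <- sel$dose[!is.na(sel$dose)]
  structure(
    list(
      n = nrow(sel),
      mean_hb = mean(hb),
      sd_hb = if (nrow(sel) > 1L) stats::sd(hb) else 0,
      delta_hb = if (nrow(sel) > 1L) delta_hb(hb) else NA_real_,
      pct_below = unname(pct["pct_below"]),
      pct_in = unname(pct["pct_in"]),
      pct_above = unname(pct["pct_above"]),
      pct_above_safety = unname(pct["pct_above_safety"]),
      ability_score = ability_score(hb, constants),
      mean_rbc_lifespan = mean(sel$rbc_lifespan),
      sd_rbc_lifespan = if (nrow(sel) > 1L) stats::sd(sel$rbc_lifespan) else 0,
      n_dose_changes = if (length(doses) >= 1L) count_dose_changes(doses) else 0L,
      auc = if (nrow(sel) > 1L) trapezoid_auc(hb) else NA_real_
    ),
    class = "session_stats"
  )
}

#' @export
print.session_stats <- function(x, ...) {
  cat("Session statistics\n")
  cat(sprintf("  n = %d weeks; mean Hb %.2f g/dL (SD %.2f), delta Hb %.2f\n",
              x$n, x$mean_hb, x$sd_hb, x$delta_hb))
  cat(sprintf("  Hb <target %.1f%%, in target %.1f%%, >target %.1f%%, >safety %.1f%%\n",
              x$pct_below, x$pct_in, x$pct_above, x$pct_above_safety))
  cat(sprintf("  ability score %.2f; mean RBC lifespan %.2f d (SD %.2f)\n",
              x$ability_score, x$mean_rbc_lifespan, x$sd_rbc_lifespan))
  cat(sprintf("  dose adjustments %d; AUC %.1f g/dL*weeks\n",
              x$n_dose_changes, x$auc))
  invisible(x)
}
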