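#' Scripted prescriber policies
#'
#' Policies stand in for the human prescriber: a rule mapping the visible
#' haemoglobin history and the current dose to the next dose. They see only
#' the observations visible in the session's arm (monthly arms hide
#' intermediate weeks), exactly as a simulator user would.
#'
#' `policy_proportional()` titrates multiplicatively toward the mid-target
#' haemoglobin: the next dose is
#' `clip(current * (target / latest_observed)^alpha, bounds)`, left
#' unchanged when the latest observation is within `deadband` g/dL of the
#' target. `policy_constant()` always doses the same amount, and
#' `policy_zero()` never doses (useful for steady-state checks).
#'
#' @param initial First dose (U).
#' @param alpha Reactivity gain (>= 0); 0 means constant dosing forever.
#' @param target Haemoglobin set point (g/dL); default mid-target 11.5.
#' @param deadband Half-width (g/dL) of the no-adjustment band around the
#'   target.
#' @param dose_min,dose_max Dose bounds (U).
#' @param name Policy label used in experiment tables.
#' @return An `esa_policy` object.
#' @examples
#' pol <- policy_proportional(initial = 4000, alpha = 1)
#' next_dose(pol, data.frame(week = 1, observed_hb = 9.2, dose = 4000), 4000)
#' @export
policy_proportional <- function(initial = 6000, alpha = 1, target = 11.5,
                                deadband = 0, dose_min = 0, dose_max = 60000,
                                name = "proportional") {
  stopifnot(initial >= 0, alpha >= 0, deadband >= 0,
            dose_min >= 0, dose_max >= dose_min)
  structure(
    list(name = name, initial = initial, alpha = alpha, target = target,
         deadband = deadband, dose_min = dose_min, dose_max = dose_max),
    class = c("esa_policy_proportional", "esa_policy")
  )
}

#' @rdname policy_proportional
#' @param dose Constant dose (U) for `policy_constant()`.
#' @export
policy_constant <- function(dose = 6000, name = "constant") {
  stopifnot(dose >= 0)
  structure(list(name = name, dose = dose),
            class = c("esa_policy_constant", "esa_policy"))
}

#' @rdname policy_proportional
#' @export
policy_zero <- function(name = "zero") {
  structure(list(name = name), class = c("esa_policy_zero", "esa_policy"))
}

#' Query a policy for the next dose
#'
#' @param policy An `esa_policy`.
#' @param history Data frame of the visible observations so far (columns
#'   `week`, `observed_hb`, `dose`), most recent last; at least one row.
#' @param current_dose Last entered dose (U), or `NA` before the first dose.
#' @return Next dose in U (>= 0).
#' @export
next_dose <- function(policy, history, current_dose) {
  UseMethod("next_dose")
}

#' @export
next_dose.esa_policy_zero <- function(policy, history, current_dose) 0

#' @export
next_dose.esa_policy_constant <- function(policy, history, current_dose) {
  policy$dose
}

#' @export
next_dose.esa_policy_proportional <- function(policy, history, current_dose) {
  if (is.null(history) || nrow(history) < 1L) {
    stop("policy error: no visible observation", call. = FALSE)
  }
  if (is.na(current_dose)) return(policy$initial)
  latest <- history$observed_hb[nrow(history)]
  if (abs(latest - policy$target) <= policy$deadband) return(current_dose)
  latest <- max(latest, 0.1)   # guard against non-positive observations
  min(max(current_dose * (policy$target / latest)^policy$alpha,
          policy$dose_min), policy$dose_max)
}

#' @export
print.esa_policy <- function(x, ...) {
  cat(sprintf("Prescriber policy '%s' (%s)\n", x$name,
              paste(class(x)[1], collapse = "")))
  invisible(x)
}

#' Target-titrated constant-dose policy
#'
#' A patient- and arm-specific scripted prescriber: it doses, at every
#' opportunity, the amount that holds the patient's noise-free cycle-mean
#' haemoglobin at the target for the session's half-life and interval (the
#' weekly need during the first 8 titration weeks, then the per-cycle need
#' of the arm's calendar; see [weekly_need()]). Because every arm is held
#' at the same haemoglobin level, residual fluctuation isolates the effect
#' of the dosing pattern itself — the harness used to compare
#' red-blood-cell lifespan dispersion across strategies.
#'
#' @param patient The `esa_patient` the session will run with.
#' @param half_life ESA half-life (hours) of the session arm.
#' @param interval `"weekly"` or `"monthly"`.
#' @param constants An [esa_constants()] object.
#' @param target Haemoglobin set point (g/dL); default mid-target.
#' @return An `esa_policy`.
#' @export
policy_titrated <- function(patient, half_life,
                            interval = c("weekly", "monthly"),
                            constants = esa_constants(),
                            target = target_mid(constants)) {
  interval <- match.arg(interval)
  cyc <- if (interval == "weekly") 7 else 28
  structure(
    list(name = "titrated",
         weekly_dose = weekly_need(patient, constants, half_life, target,
                                   cycle_days = 7),
         cycle_dose = weekly_need(patient, constants, half_life, target,
                                  cycle_days = cyc)),
    class = c("esa_policy_titrated", "esa_policy")
  )
}

#' @export
next_dose.esa_policy_titrated <- function(policy, history, current_dose) {
  w <- history$week[nrow(history)]
  if (w <= 8) policy$weekly_dose else policy$cycle_dose
}
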