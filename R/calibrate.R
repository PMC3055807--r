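#' Weekly epoetin need of one patient
#'
#' The constant weekly dose that holds the patient's noise-free
#' cycle-averaged haemoglobin at the target set point under the reference
#' titration protocol (24 h half-life, weekly dosing). Uses the daily-grid
#' steady state of the dosing cycle: with a constant weekly dose `D` the
#' concentration at day `t` of the cycle is `D * r^t / (1 - r^7)` with
#' `r = 2^(-24/half_life)`, and the cycle-mean production times the mean
#' lifespan gives the steady-state haemoglobin. Solved by root finding;
#' monotone in `D`.
#'
#' @param patient An `esa_patient`.
#' @param constants An [esa_constants()] object.
#' @param half_life Titration half-life in hours (default 24, the reference
#'   protocol).
#' @param target Haemoglobin set point (g/dL); default mid-target.
#' @param cycle_days Dosing cycle length in days (7 = weekly, 28 = monthly);
#'   the returned dose is per administration, i.e. per cycle.
#' @return Dose in U per cycle (per week by default). Zero if the starting
#'   haemoglobin already meets the target.
#' @export
weekly_need <- function(patient, constants = esa_constants(),
                        half_life = 24, target = target_mid(constants),
                        cycle_days = 7) {
  kl <- constants$hb_per_mass * constants$mean_lifespan
  # required cycle-mean saturation fraction of the Emax stimulus
  frac_req <- (target - patient$starting_hb) /
    (kl * patient$sensitivity * constants$emax)
  if (frac_req <= 0) return(0)
  if (frac_req >= 1) {
    stop("calibration error: target unreachable at this sensitivity/Emax",
         call. = FALSE)
  }
  r <- 2^(-24 / half_life)
  # concentration per unit dose over the daily grid of the dosing cycle
  shape <- r^(0:(cycle_days - 1)) / (1 - r^cycle_days)
  f <- function(d) mean(d * shape / (d * shape + constants$c50)) - frac_req
  # mean saturation is monotone increasing in d from 0 toward 1
  upper <- constants$c50
  while (f(upper) < 0 && upper < 1e12) upper <- upper * 10
  if (f(upper) < 0) {
    stop("calibration error: weekly need exceeds search bound", call. = FALSE)
  }
  stats::uniroot(f, c(0, upper), tol = 1e-9 * upper)$root
}

#' Calibrate the dose-response scale to the population anchor
#'
#' Adjusts the half-saturation concentration `c50` so that the population
#' mean weekly epoetin need — each patient titrated, noise-free, to hold
#' haemoglobin at mid-target with a 24 h half-life and weekly dosing —
#' matches `mean_weekly_need` (approximately 6000 U/week) within `tol`.
#' The patient sample is drawn once from `seed`, after which the search is
#' a deterministic root find over `log(c50)` (mean need is monotone
#' increasing in `c50`).
#'
#' @param constants An [esa_constants()] object (its `c50` is replaced).
#' @param n_patients Number of virtual patients in the calibration sample
#'   (>= 100).
#' @param seed RNG seed for the patient sample.
#' @param tol Relative tolerance on the population mean need (default 0.02).
#' @return The input constants with the calibrated `c50`, plus attributes
#'   `mean_need` (achieved population mean) and `n_patients`.
#' @export
calibrate_dose_response <- function(constants = esa_constants(),
                                    n_patients = 500, seed = 1L, tol = 0.02) {
  validate_constants(constants)
  if (n_patients < 100) {
    stop("calibration error: n_patients must be >= 100", call. = FALSE)
  }
  pseeds <- derive_seeds(seed, n_patients)
  patients <- lapply(pseeds, generate_patient, constants = constants)

  mean_need <- function(log_c50) {
    cst <- constants
    cst$c50 <- exp(log_c50)
    mean(vapply(patients, weekly_need, numeric(1), constants = cst))
  }
  f <- function(lc) mean_need(lc) - constants$mean_weekly_need
  lo <- log(1e-2); hi <- log(1e8)
  if (f(lo) > 0 || f(hi) < 0) {
    stop("calibration error: anchor outside the c50 search bracket", call. = FALSE)
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  achieved <- mean_need(root)
  if (abs(achieved - constants$mean_weekly_need) >
      tol * constants$mean_weekly_need) {
    stop("calibration error: did not converge to the population anchor",
         call. = FALSE)
  }
  constants$c50 <- exp(root)
  attr(constants, "mean_need") <- achieved
  attr(constants, "n_patients") <- n_patients
  constants
}
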