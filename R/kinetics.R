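#' Epoetin concentration from a dose history
#'
#' Mono-exponential (one-compartment) decay with superposition: every past
#' dose contributes `amount * 2^(-24 * (t - day) / half_life)` at time `t`
#' (days). Concentration is expressed in dose-unit equivalents: no absolute
#' volume of distribution is modelled, so only the product of sensitivity
#' and the dose-response stimulus is observable.
#'
#' @param dose_days Integer vector of dose days (>= 0).
#' @param dose_amounts Numeric vector of dose amounts (U, >= 0), parallel to
#'   `dose_days`.
#' @param half_life ESA half-life in hours (> 0).
#' @param t Time(s) in days (>= 0) at which to evaluate the concentration.
#' @return Numeric vector of concentrations, one per element of `t`.
#' @examples
#' epo_concentration(0, 4000, half_life = 24, t = 1)  # one half-life: 2000
#' @export
epo_concentration <- function(dose_days, dose_amounts, half_life, t) {
  if (length(dose_days) != length(dose_amounts)) {
    stop("domain error: dose_days and dose_amounts must be parallel", call. = FALSE)
  }
  if (any(t < 0)) stop("domain error: t must be >= 0", call. = FALSE)
  if (any(dose_amounts < 0)) stop("domain error: dose amounts must be >= 0", call. = FALSE)
  if (any(dose_days < 0)) stop("domain error: dose days must be >= 0", call. = FALSE)
  if (!is.numeric(half_life) || half_life <= 0) {
    stop("domain error: half_life must be positive", call. = FALSE)
  }
  if (length(dose_days) == 0L) return(rep(0, length(t)))
  hl_days <- half_life / 24
  vapply(t, function(tt) {
    past <- dose_days <= tt
    if (!any(past)) return(0)
    sum(dose_amounts[past] * 2^(-(tt - dose_days[past]) / hl_days))
  }, numeric(1))
}

#' Epoetin production stimulus
#'
#' Saturating Emax dose-response linking drug concentration to marrow RBC
#' output: `P0 + s * Emax * C / (C + C50)`. Monotone non-decreasing in `C`
#' and equal to the endogenous baseline at `C = 0`.
#'
#' @param concentration Epoetin concentration(s), dose-unit equivalents (>= 0).
#' @param patient An `esa_patient` (supplies `baseline_production` and
#'   `sensitivity`).
#' @param constants An [esa_constants()] object (supplies `emax`, `c50`).
#' @return Production rate(s) in RBC mass units/day.
#' @export
production_stimulus <- function(concentration, patient, constants = esa_constants()) {
  if (any(concentration < 0)) {
    stop("domain error: concentration must be >= 0", call. = FALSE)
  }
  patient$baseline_production +
    patient$sensitivity * constants$emax *
      concentration / (concentration + constants$c50)
}

# --- cohort survival ---------------------------------------------------------
#
# Cell lifespans within a daily birth cohort follow the uniform law on
# [mean - spread, mean + spread]. The ledger tracks each cohort's birth mass;
# the mass still circulating "during day a of life" is the cell-averaged
# survival  w(a) = F(a+1) - F(a)  with  F(x) = integral_0^x S(u) du  and
# S(u) = P(lifespan > u). Cell averaging makes sum_a w(a) equal the mean
# lifespan exactly for any spread, which pins the turnover read-out to
# mean_lifespan at the pre-treatment steady state.
survival_integral <- function(x, mean_lifespan, spread) {
  x <- pmax(x, 0)
  if (spread == 0) return(pmin(x, mean_lifespan))
  x1 <- mean_lifespan - spread
  x2 <- mean_lifespan + spread
  ifelse(x <= x1, x,
         ifelse(x >= x2, mean_lifespan,
                x1 + ((2 * spread)^2 - (x2 - x)^2) / (4 * spread)))
}

cohort_survival <- function(age, constants) {
  survival_integral(age + 1, constants$mean_lifespan, constants$lifespan_spread) -
    survival_integral(age, constants$mean_lifespan, constants$lifespan_spread)
}

# oldest age (exclusive) with any surviving mass
max_cohort_age <- function(constants) {
  ceiling(constants$mean_lifespan + constants$lifespan_spread)
}

# --- state -------------------------------------------------------------------

#' Initialise the erythropoiesis state at the pre-treatment steady state
#'
#' Builds the cohort ledger of an ESA-naive patient: one cohort per day of
#' age, each born with the endogenous baseline production mass, so that the
#' total circulating mass equals `P0 * mean_lifespan` and the noise-free
#' haemoglobin equals the starting haemoglobin exactly. With zero dosing the
#' state is stationary under [step_day()].
#'
#' @param patient An `esa_patient`.
#' @param half_life ESA half-life (hours) for the session; must be one of
#'   `constants$allowed_half_lives`.
#' @param constants An [esa_constants()] object.
#' @return An `erythro_state` object.
#' @export
init_state <- function(patient, half_life, constants = esa_constants()) {
  validate_constants(constants)
  if (!half_life %in% constants$allowed_half_lives) {
    stop("configuration error: half_life must be one of {",
         paste(constants$allowed_half_lives, collapse = ", "), "} hours",
         call. = FALSE)
  }
  amax <- max_cohort_age(constants)
  structure(
    list(
      day = 0L,
      birth_day = 0L - (0:(amax - 1L)),   # ages 0 .. amax-1 at day 0
      birth_mass = rep(patient$baseline_production, amax),
      dose_day = integer(0),
      dose_amount = numeric(0),
      half_life = half_life,
      patient = patient,
      constants = constants
    ),
    class = "erythro_state"
  )
}

total_mass <- function(state) {
  sum(state$birth_mass * cohort_survival(state$day - state$birth_day, state$constants))
}

#' True haemoglobin of a state
#'
#' Linear read-out `Hb = hb_per_mass * total circulating RBC mass`.
#'
#' @param state An `erythro_state`.
#' @param constants Constants; defaults to those stored in the state.
#' @return Haemoglobin in g/dL.
#' @export
hb_true <- function(state, constants = state$constants) {
  constants$hb_per_mass * total_mass(state)
}

#' Turnover mean RBC lifespan
#'
#' Total circulating mass divided by the current expected daily senescence
#' loss, the latter smoothed over a 7-day forward window. At the
#' pre-treatment steady state this equals `mean_lifespan` exactly (mass
#' `P0 * mean_lifespan`, loss `P0`) and it fluctuates with the erythrocyte
#' age distribution otherwise.
#'
#' @param state An `erythro_state` with positive circulating mass.
#' @param window Smoothing window in days for the senescence loss (default 7).
#' @return Mean RBC lifespan in days.
#' @export
mean_rbc_lifespan <- function(state, window = 7L) {
  cst <- state$constants
  age <- state$day - state$birth_day
  mass <- sum(state$birth_mass * cohort_survival(age, cst))
  if (length(state$birth_mass) == 0L || mass <= 0) {
    stop("undefined-state error: no circulating RBC mass", call. = FALSE)
  }
  lost <- sum(state$birth_mass *
                (cohort_survival(age, cst) - cohort_survival(age + window, cst))) / window
  if (lost <= 0) {
    stop("undefined-state error: zero senescence loss", call. = FALSE)
  }
  mass / lost
}

#' Advance the erythropoiesis state by one day
#'
#' Appends today's doses to the history, evaluates the epoetin concentration
#' `maturation_delay` days in the past (the stimulus felt then matures into
#' circulation now), creates one new cohort carrying one day of production,
#' removes fully senesced cohorts, and advances the clock by one day.
#'
#' @param state An `erythro_state`.
#' @param dose_days,dose_amounts New doses, all dated `state$day` (may be
#'   empty).
#' @return The advanced `erythro_state`.
#' @export
step_day <- function(state, dose_days = integer(0), dose_amounts = numeric(0)) {
  cst <- state$constants
  if (length(dose_days) != length(dose_amounts)) {
    stop("scheduling error: dose days and amounts must be parallel", call. = FALSE)
  }
  if (length(dose_days) > 0L) {
    if (any(dose_days != state$day)) {
      stop("scheduling error: new doses must be dated today (day ",
           state$day, ")", call. = FALSE)
    }
    if (any(!is.finite(dose_amounts)) || any(dose_amounts < 0)) {
      stop("scheduling error: dose amounts must be finite and >= 0", call. = FALSE)
    }
    state$dose_day <- c(state$dose_day, as.integer(dose_days))
    state$dose_amount <- c(state$dose_amount, dose_amounts)
  }
  t_stim <- state$day - cst$maturation_delay
  conc <- if (t_stim < 0) 0 else {
    epo_concentration(state$dose_day, state$dose_amount, state$half_life, t_stim)
  }
  prod <- production_stimulus(conc, state$patient, cst)

  state$day <- state$day + 1L
  state$birth_day <- c(state$birth_day, state$day)
  state$birth_mass <- c(state$birth_mass, prod)
  alive <- (state$day - state$birth_day) < max_cohort_age(cst)
  state$birth_day <- state$birth_day[alive]
  state$birth_mass <- state$birth_mass[alive]
  state
}

#' Apply an acute bleeding episode
#'
#' Instantaneous proportional removal: every cohort's mass is multiplied by
#' `(1 - fraction)`, so the total circulating mass scales exactly by the
#' same factor and the normalized age distribution is unchanged.
#'
#' @param state An `erythro_state`.
#' @param fraction Fraction of blood volume lost, in
#'   `[0, bleed_max_fraction]`.
#' @return The bled `erythro_state`.
#' @export
apply_bleed <- function(state, fraction) {
  fmax <- state$constants$bleed_max_fraction
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > fmax) {
    stop(sprintf("domain error: bleed fraction must lie in [0, %.2f]", fmax),
         call. = FALSE)
  }
  state$birth_mass <- state$birth_mass * (1 - fraction)
  state
}

#' @export
print.erythro_state <- function(x, ...) {
  cat(sprintf(
    "Erythropoiesis state: day %d, %d cohorts, Hb %.3f g/dL, turnover lifespan %.2f d\n",
    x$day, length(x$birth_mass), hb_true(x), mean_rbc_lifespan(x)))
  invisible(x)
}
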