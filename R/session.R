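#' Session configuration
#'
#' Bundles the arm (half-life and administration interval), the study mode
#' (A: one random bleeding episode between the configured weeks; B: none),
#' the master RNG seed, and the model constants.
#'
#' @param half_life ESA half-life in hours, one of the allowed set
#'   (24, 48, 138 by default).
#' @param interval Administration interval, `"weekly"` or `"monthly"`.
#' @param mode Study mode, `"A"` (random bleed) or `"B"` (no bleed).
#' @param seed Master RNG seed; observation-noise and bleeding streams are
#'   derived from it independently.
#' @param constants An [esa_constants()] object.
#' @return A `session_config` object.
#' @export
session_config <- function(half_life = 24, interval = c("weekly", "monthly"),
                           mode = c("B", "A"), seed = 1L,
                           constants = esa_constants()) {
  interval <- match.arg(interval)
  mode <- match.arg(mode)
  validate_constants(constants)
  if (!half_life %in% constants$allowed_half_lives) {
    stop("configuration error: half_life must be one of {",
         paste(constants$allowed_half_lives, collapse = ", "), "} hours",
         call. = FALSE)
  }
  structure(
    list(half_life = half_life, interval = interval, mode = mode,
         seed = as.integer(seed), constants = constants),
    class = "session_config"
  )
}

#' Dosing calendar
#'
#' Weeks on which a dose may be entered. During the first 8 weeks titration
#' is weekly in both arms (policies remain free to dose every second week);
#' from week 9 the weekly arm doses every week and the monthly arm every
#' 4th week (weeks 9, 13, 17, 21, 25, 29).
#'
#' @param interval `"weekly"` or `"monthly"`.
#' @param constants An [esa_constants()] object.
#' @return Integer vector of dosing week indices within 1..32.
#' @export
dosing_weeks <- function(interval = c("weekly", "monthly"),
                         constants = esa_constants()) {
  interval <- match.arg(interval)
  n_weeks <- constants$equilibration_weeks + constants$maintenance_weeks
  if (interval == "weekly") {
    seq_len(n_weeks)
  } else {
    c(1:8, seq(9L, n_weeks, by = 4L))
  }
}

#' Haemoglobin visibility
#'
#' Whether the haemoglobin value of a given week is shown to the prescriber.
#' The weekly arm sees every week; the monthly arm sees only its dosing
#' calendar (weekly during the first 8 titration weeks, then every 4th
#' week). True haemoglobin is always logged for analysis regardless.
#'
#' @param interval `"weekly"` or `"monthly"`.
#' @param week Week index (vectorised), within 1..32.
#' @param constants An [esa_constants()] object.
#' @return Logical vector.
#' @export
visible <- function(interval = c("weekly", "monthly"), week,
                    constants = esa_constants()) {
  interval <- match.arg(interval)
  n_weeks <- constants$equilibration_weeks + constants$maintenance_weeks
  if (any(week < 1L | week > n_weeks)) {
    stop("domain error: week out of range 1..", n_weeks, call. = FALSE)
  }
  if (interval == "weekly") rep(TRUE, length(week))
  else week %in% dosing_weeks("monthly", constants)
}

#' Observe haemoglobin with incidental fluctuation
#'
#' Adds a uniform incidental fluctuation on
#' `[-noise_amplitude, +noise_amplitude]` g/dL to the true haemoglobin and
#' reports the result to 0.1 g/dL, as a laboratory would. Both the truth
#' and the fluctuation are quantized to the 0.1 g/dL instrument resolution
#' before summing, so the reported value never departs from the (0.1-rounded)
#' true haemoglobin by more than the noise amplitude. The noise is
#' observation-level only: it never feeds back into the mass balance. Draws
#' from the current RNG stream (seed before calling for reproducibility).
#'
#' @param true_hb True haemoglobin value(s), g/dL (>= 0).
#' @param constants An [esa_constants()] object.
#' @return Observed haemoglobin, g/dL, rounded to 0.1.
#' @export
observe_hb <- function(true_hb, constants = esa_constants()) {
  if (any(true_hb < 0)) stop("domain error: true_hb must be >= 0", call. = FALSE)
  amp <- constants$noise_amplitude
  noise <- if (amp > 0) stats::runif(length(true_hb), -amp, amp) else 0
  round(true_hb, 1) + round(noise, 1)
}

#' Schedule a random bleeding episode
#'
#' Mode B returns no event. Mode A draws the week uniformly over the
#' configured window (weeks 18-24 by default) and the lost blood-volume
#' fraction uniformly over `[0, bleed_max_fraction]`, deterministically for
#' a given seed.
#'
#' @param mode `"A"` or `"B"`.
#' @param seed RNG seed for the bleeding stream.
#' @param constants An [esa_constants()] object.
#' @return `NULL` (mode B) or a list with `week` and `fraction`.
#' @export
schedule_bleed <- function(mode = c("B", "A"), seed = 1L,
                           constants = esa_constants()) {
  mode <- match.arg(mode)
  if (mode == "B") return(NULL)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  bw <- constants$bleed_window
  list(week = sample(bw[1]:bw[2], 1L),
       fraction = stats::runif(1L, 0, constants$bleed_max_fraction))
}

#' Run a 32-week prescription session
#'
#' Simulates the full session (224 daily steps) from the pre-treatment
#' steady state. Each week the state is observed (with incidental
#' fluctuation); on dosing weeks the policy is queried with only the
#' observations visible in the session's arm and its dose is injected the
#' same day; in mode A the scheduled bleeding episode is applied at the
#' start of its week, before that week's observation. The run is
#' deterministic given `(config$seed, patient, policy)` for a deterministic
#' policy.
#'
#' @param config A [session_config()].
#' @param patient An `esa_patient`; defaults to a fresh patient generated
#'   from a seed derived from `config$seed`.
#' @param policy An `esa_policy` (see [policy_proportional()]).
#' @return An `esa_session` data frame with one row per week: `week`,
#'   `phase`, `visible`, `true_hb`, `observed_hb`, `dose` (NA outside dosing
#'   weeks or when the policy declined), `bleed_fraction` (NA unless a bleed
#'   occurred that week) and `rbc_lifespan`; the patient, config and final
#'   state are attached as attributes.
#' @export
run_session <- function(config, patient = NULL, policy = policy_zero()) {
  stopifnot(inherits(config, "session_config"))
  cst <- config$constants
  seeds <- derive_seeds(config$seed, 3L)   # patient, noise, bleed
  if (is.null(patient)) patient <- generate_patient(seeds[1], cst)
  stopifnot(inherits(patient, "esa_patient"))

  n_weeks <- cst$equilibration_weeks + cst$maintenance_weeks
  bleed <- schedule_bleed(config$mode, seed = seeds[3], constants = cst)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seeds[2])
  # pre-drawn so that dose decisions cannot perturb the noise stream
  noise <- if (cst$noise_amplitude > 0) {
    stats::runif(n_weeks, -cst$noise_amplitude, cst$noise_amplitude)
  } else {
    rep(0, n_weeks)
  }

  state <- init_state(patient, config$half_life, cst)
  dose_cal <- dosing_weeks(config$interval, cst)
  vis <- visible(config$interval, seq_len(n_weeks), cst)

  rec <- data.frame(
    week = seq_len(n_weeks),
    phase = ifelse(seq_len(n_weeks) <= cst$equilibration_weeks,
                   "equilibration", "maintenance"),
    visible = vis,
    true_hb = NA_real_, observed_hb = NA_real_,
    dose = NA_real_, bleed_fraction = NA_real_,
    rbc_lifespan = NA_real_,
    stringsAsFactors = FALSE
  )

  current_dose <- NA_real_
  for (w in seq_len(n_weeks)) {
    day0 <- (w - 1L) * 7L
    stopifnot(state$day == day0)
    if (!is.null(bleed) && bleed$week == w) {
      state <- apply_bleed(state, bleed$fraction)
      rec$bleed_fraction[w] <- bleed$fraction
    }
    th <- hb_true(state)
    rec$true_hb[w] <- th
    rec$observed_hb[w] <- round(th, 1) + round(noise[w], 1)
    rec$rbc_lifespan[w] <- mean_rbc_lifespan(state)

    dose_w <- NA_real_
    if (w %in% dose_cal && !is.null(policy)) {
      hist <- rec[rec$week <= w & rec$visible,
                  c("week", "observed_hb", "dose"), drop = FALSE]
      dose_w <- next_dose(policy, hist, current_dose)
      if (!is.null(dose_w) && !is.na(dose_w)) {
        if (!is.finite(dose_w) || dose_w < 0) {
          stop("policy error: policy returned an invalid dose", call. = FALSE)
        }
        current_dose <- dose_w
      }
    }
    rec$dose[w] <- if (is.null(dose_w)) NA_real_ else dose_w

    for (d in seq_len(7L)) {
      if (d == 1L && !is.na(rec$dose[w]) && rec$dose[w] > 0) {
        state <- step_day(state, day0, rec$dose[w])
      } else {
        state <- step_day(state)
      }
    }
  }

  structure(rec,
            class = c("esa_session", "data.frame"),
            patient = patient, config = config, bleed = bleed,
            final_state = state)
}

#' @export
print.esa_session <- function(x, ...) {
  cfg <- attr(x, "config")
  pat <- attr(x, "patient")
  cat(sprintf("ESA prescription session: %g h half-life, %s dosing, mode %s, seed %d\n",
              cfg$half_life, cfg$interval, cfg$mode, cfg$seed))
  cat(sprintf("  patient: starting Hb %.1f g/dL, sensitivity %.3f\n",
              pat$starting_hb, pat$sensitivity))
  print.data.frame(utils::head(as.data.frame(x), 8), row.names = FALSE)
  cat(sprintf("  ... %d weeks total\n", nrow(x)))
  invisible(x)
}
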