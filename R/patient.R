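#' Generate a randomized virtual patient
#'
#' Draws an ESA-naive virtual haemodialysis patient: a starting haemoglobin
#' uniform over the grid 7.0, 7.1, ..., 8.0 g/dL, a log-normal epoetin
#' sensitivity with median 1, and the endogenous baseline RBC production
#' rate that sustains the starting haemoglobin at the pre-treatment steady
#' state with zero dosing. Generation is a pure function of `(seed,
#' constants)`.
#'
#' @param seed Integer RNG seed; the same seed reproduces the same patient.
#' @param constants An [esa_constants()] object.
#' @return An `esa_patient` object: a list with `starting_hb` (g/dL),
#'   `sensitivity` (dimensionless multiplier), `baseline_production`
#'   (RBC mass units/day) and `seed`.
#' @examples
#' p <- generate_patient(seed = 1)
#' p$starting_hb
#' @export
generate_patient <- function(seed, constants = esa_constants()) {
  validate_constants(constants)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  # 11 grid points 7.0..8.0; integer tenths avoid 0.1 float accumulation
  starting_hb <- sample(70:80, 1L) / 10
  sensitivity <- stats::rlnorm(1L, meanlog = 0, sdlog = constants$sensitivity_sdlog)
  structure(
    list(
      starting_hb = starting_hb,
      sensitivity = sensitivity,
      baseline_production = baseline_production(starting_hb, constants),
      seed = as.integer(seed)
    ),
    class = "esa_patient"
  )
}

#' Baseline RBC production sustaining a given haemoglobin
#'
#' Returns the endogenous production rate P0 (RBC mass units/day) such that
#' `hb_per_mass * P0 * mean_lifespan = starting_hb`: with zero dosing, the
#' patient's noise-free steady-state haemoglobin equals the starting value.
#'
#' @param starting_hb Haemoglobin (g/dL), non-negative.
#' @param constants An [esa_constants()] object.
#' @return Production rate in RBC mass units/day.
#' @export
baseline_production <- function(starting_hb, constants = esa_constants()) {
  if (!is.numeric(starting_hb) || any(starting_hb < 0)) {
    stop("domain error: starting_hb must be non-negative", call. = FALSE)
  }
  starting_hb / (constants$hb_per_mass * constants$mean_lifespan)
}

#' @export
print.esa_patient <- function(x, ...) {
  cat(sprintf(
    "Virtual patient (seed %d): starting Hb %.1f g/dL, sensitivity %.3f, P0 %.5f mass/d\n",
    x$seed, x$starting_hb, x$sensitivity, x$baseline_production))
  invisible(x)
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Derive k independent sub-seeds (< 2^31) from a master seed: one RNG
# stream per concern so toggling one feature does not shift another's draws.
derive_seeds <- function(seed, k) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, k)
}
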