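#' Model constants for the ESA prescription simulator
#'
#' Bundles every fixed quantity of the simulation: the haemoglobin target
#' range and safety threshold, the red-blood-cell (RBC) lifespan law, the
#' maturation delay between epoetin stimulus and circulating cells, the
#' dose-response parameters, observation-noise amplitude, the allowed drug
#' half-lives, the session calendar, and the bleeding-event bounds.
#'
#' Units follow clinical convention: haemoglobin in g/dL, times in days
#' (half-lives in hours, as printed on ESA labels), doses in units (U) of
#' epoetin. RBC mass is tracked in "mass units" chosen so that 1 mass unit
#' of circulating RBC corresponds to `hb_per_mass` g/dL of haemoglobin.
#'
#' @param target_low,target_high Haemoglobin target range bounds (g/dL).
#' @param safety_threshold Haemoglobin safety threshold (g/dL); values above
#'   it count as a double prescription error in the ability score.
#' @param mean_lifespan Mean RBC lifespan (days) of the uniform lifespan law.
#' @param lifespan_spread Half-width (days) of the uniform lifespan law;
#'   cell lifespans range over `mean_lifespan +/- lifespan_spread`.
#' @param maturation_delay Lag (days) between the epoetin stimulus acting on
#'   marrow precursors and the release of the resulting cells into
#'   circulation.
#' @param hb_per_mass Calibration constant kappa: g/dL of haemoglobin per
#'   circulating RBC mass unit.
#' @param emax Maximum epoetin-driven production stimulus
#'   (RBC mass units/day) for a patient of sensitivity 1.
#' @param c50 Half-saturation epoetin concentration (dose-unit equivalents)
#'   of the saturating dose-response. The default is calibrated so that the
#'   population mean weekly epoetin need to hold haemoglobin at mid-target
#'   is approximately `mean_weekly_need` (see
#'   [calibrate_dose_response()]).
#' @param sensitivity_sdlog Log-scale standard deviation of the log-normal
#'   patient sensitivity law (median 1).
#' @param noise_amplitude Half-width (g/dL) of the uniform incidental
#'   haemoglobin fluctuation added to observations.
#' @param allowed_half_lives Permitted ESA half-lives (hours).
#' @param equilibration_weeks,maintenance_weeks Session phase lengths (weeks).
#' @param bleed_window Two integers, the first and last week (inclusive) in
#'   which a random bleeding episode may occur in study mode A.
#' @param bleed_max_fraction Maximum fraction of blood volume lost in a
#'   bleeding episode.
#' @param mean_weekly_need Population calibration anchor: mean weekly epoetin
#'   need (U/week) to reach and hold the haemoglobin target.
#'
#' @return An object of class `esa_constants` (a validated named list).
#' @examples
#' cst <- esa_constants()
#' cst$mean_lifespan
#' @export
esa_constants <- function(target_low = 11.0,
                          target_high = 12.0,
                          safety_threshold = 13.0,
                          mean_lifespan = 61.2,
                          lifespan_spread = 15.0,
                          maturation_delay = 7.0,
                          hb_per_mass = 1.0,
                          emax = 0.60,
                          c50 = 11001.3866258167,
                          sensitivity_sdlog = 0.3,
                          noise_amplitude = 0.5,
                          allowed_half_lives = c(24, 48, 138),
                          equilibration_weeks = 12L,
                          maintenance_weeks = 20L,
                          bleed_window = c(18L, 24L),
                          bleed_max_fraction = 0.30,
                          mean_weekly_need = 6000) {
  cst <- structure(
    list(
      target_low = target_low,
      target_high = target_high,
      safety_threshold = safety_threshold,
      mean_lifespan = mean_lifespan,
      lifespan_spread = lifespan_spread,
      maturation_delay = maturation_delay,
      hb_per_mass = hb_per_mass,
      emax = emax,
      c50 = c50,
      sensitivity_sdlog = sensitivity_sdlog,
      noise_amplitude = noise_amplitude,
      allowed_half_lives = allowed_half_lives,
      equilibration_weeks = as.integer(equilibration_weeks),
      maintenance_weeks = as.integer(maintenance_weeks),
      bleed_window = as.integer(bleed_window),
      bleed_max_fraction = bleed_max_fraction,
      mean_weekly_need = mean_weekly_need
    ),
    class = "esa_constants"
  )
  validate_constants(cst)
}

#' Validate a set of model constants
#'
#' Checks the structural invariants of the model configuration and returns
#' the constants invisibly touched-up (integer calendar fields). Invalid
#' configurations raise a configuration error.
#'
#' @param cst An `esa_constants` object (or a named list with its fields).
#' @return The validated `esa_constants` object.
#' @export
validate_constants <- function(cst) {
  stopifnot(is.list(cst))
  need <- names(formals(esa_constants))
  missing <- setdiff(need, names(cst))
  if (length(missing) > 0) {
    stop("configuration error: missing constants: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  with(cst, {
    if (!(target_low < target_high && target_high < safety_threshold)) {
      stop("configuration error: need target_low < target_high < safety_threshold",
           call. = FALSE)
    }
    if (!(mean_lifespan > 0)) {
      stop("configuration error: mean_lifespan must be positive", call. = FALSE)
    }
    if (!(lifespan_spread >= 0 && lifespan_spread < mean_lifespan)) {
      stop("configuration error: need 0 <= lifespan_spread < mean_lifespan",
           call. = FALSE)
    }
    if (!(noise_amplitude >= 0)) {
      stop("configuration error: noise_amplitude must be >= 0", call. = FALSE)
    }
    if (!(bleed_max_fraction > 0 && bleed_max_fraction <= 1)) {
      stop("configuration error: need 0 < bleed_max_fraction <= 1", call. = FALSE)
    }
    if (equilibration_weeks + maintenance_weeks != 32L) {
      stop("configuration error: equilibration_weeks + maintenance_weeks must be 32",
           call. = FALSE)
    }
    if (length(bleed_window) != 2L || bleed_window[1] > bleed_window[2]) {
      stop("configuration error: bleed_window must be two ordered week indices",
           call. = FALSE)
    }
    if (any(allowed_half_lives <= 0)) {
      stop("configuration error: half-lives must be positive", call. = FALSE)
    }
    if (hb_per_mass <= 0 || emax <= 0 || c50 <= 0) {
      stop("configuration error: hb_per_mass, emax and c50 must be positive",
           call. = FALSE)
    }
    if (mean_weekly_need <= 0 || sensitivity_sdlog < 0) {
      stop("configuration error: mean_weekly_need > 0 and sensitivity_sdlog >= 0 required",
           call. = FALSE)
    }
  })
  cst
}

#' @export
print.esa_constants <- function(x, ...) {
  cat("ESA simulator constants\n")
  cat(sprintf("  Hb target %.1f-%.1f g/dL, safety threshold %.1f g/dL\n",
              x$target_low, x$target_high, x$safety_threshold))
  cat(sprintf("  RBC lifespan %.1f +/- %.1f d, maturation delay %.1f d\n",
              x$mean_lifespan, x$lifespan_spread, x$maturation_delay))
  cat(sprintf("  dose-response: Emax %.3g mass/d, C50 %.6g U-eq\n", x$emax, x$c50))
  cat(sprintf("  half-lives {%s} h; session %d + %d weeks\n",
              paste(x$allowed_half_lives, collapse = ", "),
              x$equilibration_weeks, x$maintenance_weeks))
  cat(sprintf("  observation noise +/- %.1f g/dL; bleed <= %.0f%% in weeks %d-%d\n",
              x$noise_amplitude, 100 * x$bleed_max_fraction,
              x$bleed_window[1], x$bleed_window[2]))
  invisible(x)
}

# Mid-target haemoglobin, the titration set point used by policies and
# calibration.
target_mid <- function(cst) (cst$target_low + cst$target_high) / 2
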