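#' Running statistics on the visible haemoglobin history
#'
#' The statistics panel shown to the prescriber during an interactive
#' session, computed incrementally on the visible observed values from the
#' first week: mean with SD, delta Hb, target-occupancy percentages and the
#' ability score. By construction these match [summarize_session()] applied
#' to the visible grid of the weeks seen so far.
#'
#' @param observed Visible observed haemoglobin values so far (g/dL).
#' @param constants An [esa_constants()] object.
#' @return Named list `mean_hb`, `sd_hb`, `delta_hb`, `pct_below`,
#'   `pct_in`, `pct_above`, `pct_above_safety`, `ability_score`.
#' @export
running_stats <- function(observed, constants = esa_constants()) {
  pct <- target_percentages(observed, constants)
  list(
    mean_hb = mean(observed),
    sd_hb = if (length(observed) > 1L) stats::sd(observed) else 0,
    delta_hb = if (length(observed) > 1L) delta_hb(observed) else NA_real_,
    pct_below = unname(pct["pct_below"]),
    pct_in = unname(pct["pct_in"]),
    pct_above = unname(pct["pct_above"]),
    pct_above_safety = unname(pct["pct_above_safety"]),
    ability_score = ability_score(observed, constants)
  )
}

# interactive "policy": prompts on every dosing opportunity, printing only
# the visible history and the running statistics
policy_interactive <- function(config, input, output) {
  structure(
    list(name = "interactive", config = config, input = input, output = output),
    class = c("esa_policy_interactive", "esa_policy")
  )
}

#' @export
next_dose.esa_policy_interactive <- function(policy, history, current_dose) {
  cfg <- policy$config
  out <- policy$output
  w <- history$week[nrow(history)]
  writeLines(sprintf("-- week %d | half-life %g h | %s dosing --",
                     w, cfg$half_life, cfg$interval), out)
  writeLines(sprintf("   visible Hb history: %s g/dL",
                     paste(sprintf("w%d=%.1f", history$week, history$observed_hb),
                           collapse = " ")), out)
  rs <- running_stats(history$observed_hb, cfg$constants)
  writeLines(sprintf(
    "   stats: mean %.2f (SD %.2f) | delta Hb %s | in target %.0f%% | score %.2f",
    rs$mean_hb, rs$sd_hb,
    if (is.na(rs$delta_hb)) "-" else sprintf("%.2f", rs$delta_hb),
    rs$pct_in, rs$ability_score), out)
  repeat {
    writeLines(sprintf("   dose [U] (current %s): ",
                       if (is.na(current_dose)) "none"
                       else sprintf("%.0f", current_dose)), out)
    line <- readLines(policy$input, n = 1L)
    if (length(line) == 0L) {
      stop(structure(
        class = c("eposim_session_aborted", "error", "condition"),
        list(message = "partial-record error: interactive session aborted (EOF)",
             call = NULL)))
    }
    dose <- suppressWarnings(as.numeric(trimws(line)))
    if (length(dose) == 1L && !is.na(dose) && is.finite(dose) && dose >= 0) {
      return(dose)
    }
    writeLines("   invalid entry; please enter a non-negative number", out)
  }
}

#' Play an interactive prescription session
#'
#' Runs one session with doses entered on a console (or any readable
#' connection). Every dosing opportunity shows the half-life and interval,
#' the visible haemoglobin history, and the running statistics from the
#' first week, then prompts for a dose; hidden weeks of the monthly arm are
#' never shown. The final statistics panel is printed when the 32 weeks are
#' complete. Feeding a scripted connection reproduces exactly the record of
#' the equivalent scripted policy.
#'
#' @param config A [session_config()].
#' @param patient Optional `esa_patient` (default: derived from the config
#'   seed, as in [run_session()]).
#' @param input Connection to read doses from (default stdin).
#' @param output Connection for the prompts (default stdout).
#' @return The completed `esa_session` record, invisibly.
#' @export
play_interactive <- function(config, patient = NULL,
                             input = stdin(), output = stdout()) {
  rec <- run_session(config, patient = patient,
                     policy = policy_interactive(config, input, output))
  writeLines("== session complete ==", output)
  stats <- summarize_session(rec, sampling = "visible", values = "observed")
  writeLines(utils::capture.output(print(stats)), output)
  invisible(rec)
}
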