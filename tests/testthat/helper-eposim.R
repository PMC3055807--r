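# shared fixtures built in code

noise_free <- function(...) esa_constants(noise_amplitude = 0, ...)

# a session with everything deterministic: zero noise, zero dosing, mode B
flat_session <- function(seed = 1, half_life = 24, interval = "weekly") {
  cfg <- session_config(half_life, interval, "B", seed = seed,
                        constants = noise_free())
  run_session(cfg, policy = policy_zero())
}

# patient with a hand-set sensitivity, for algebraic checks
fixed_patient <- function(starting_hb = 7.5, sensitivity = 1,
                          constants = esa_constants()) {
  structure(
    list(starting_hb = starting_hb, sensitivity = sensitivity,
         baseline_production = baseline_production(starting_hb, constants),
         seed = 0L),
    class = "esa_patient"
  )
}

# brute-force superposition oracle: sum of independent single-dose curves
oracle_concentration <- function(dose_days, dose_amounts, half_life, t) {
  contrib <- sapply(seq_along(dose_days), function(i) {
    epo_concentration(dose_days[i], dose_amounts[i], half_life, t)
  })
  if (is.matrix(contrib)) rowSums(contrib) else sum(contrib)
}
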