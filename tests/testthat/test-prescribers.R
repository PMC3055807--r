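cst <- esa_constants()

test_that("the proportional policy titrates multiplicatively toward target", {
  pol <- policy_proportional(initial = 4000, alpha = 1)
  h <- data.frame(week = 1, observed_hb = 9.2, dose = 4000)
  expect_equal(next_dose(pol, h, 4000), 4000 * (11.5 / 9.2))
  expect_equal(next_dose(pol, h, 4000), 5000)
  # first dose is the configured initial
  expect_equal(next_dose(pol, h, NA_real_), 4000)
  # fixed point at target, zero gain freezes the dose, deadband holds
  h2 <- data.frame(week = 2, observed_hb = 11.5, dose = 4000)
  expect_equal(next_dose(pol, h2, 4000), 4000)
  expect_equal(next_dose(policy_proportional(alpha = 0), h, 7000), 7000)
  hd <- data.frame(week = 3, observed_hb = 11.2, dose = 5000)
  expect_equal(next_dose(policy_proportional(deadband = 0.4), hd, 5000), 5000)
  expect_error(next_dose(pol, h[0, ], 4000), "policy error")
  # bounds clip
  expect_lte(next_dose(policy_proportional(dose_max = 4500, alpha = 1), h, 4000),
             4500)
})

test_that("calibration pins the population mean weekly need to the anchor", {
  cal <- calibrate_dose_response(cst, n_patients = 300, seed = 99, tol = 0.02)
  expect_lt(abs(attr(cal, "mean_need") - cst$mean_weekly_need),
            0.02 * cst$mean_weekly_need)
  # fresh patients land near the anchor too
  needs <- vapply(5000 + 1:500,
                  function(s) weekly_need(generate_patient(s, cal), cal),
                  numeric(1))
  expect_lt(abs(mean(needs) - cst$mean_weekly_need),
            0.05 * cst$mean_weekly_need)
  # the default constants are already calibrated
  needs0 <- vapply(9000 + 1:500,
                   function(s) weekly_need(generate_patient(s, cst), cst),
                   numeric(1))
  expect_lt(abs(mean(needs0) - cst$mean_weekly_need),
            0.05 * cst$mean_weekly_need)
  expect_error(calibrate_dose_response(cst, n_patients = 10), "calibration error")
})

test_that("a median-sensitivity patient needs a central dose; need falls with sensitivity", {
  needs <- vapply(300 + 1:400,
                  function(s) weekly_need(generate_patient(s, cst), cst),
                  numeric(1))
  med <- weekly_need(fixed_patient(7.5, 1, cst), cst)
  expect_gt(med, stats::quantile(needs, 0.10))
  expect_lt(med, stats::quantile(needs, 0.90))
  # doubling sensitivity halves the need, approximately, in the linear regime
  ratio <- weekly_need(fixed_patient(7.5, 2, cst), cst) / med
  expect_lt(abs(ratio - 0.5), 0.1)
  # monotone: more sensitive patients need less
  ss <- c(0.5, 0.8, 1, 1.5, 2.5)
  nn <- vapply(ss, function(s) weekly_need(fixed_patient(7.5, s, cst), cst),
               numeric(1))
  expect_true(all(diff(nn) < 0))
})

test_that("the experiment grid is deterministic bookkeeping over arms", {
  g1 <- experiment_grid(n_per_arm = 2, mode = "B", seed = 5, constants = cst,
                        policy = policy_proportional(alpha = 0.6, deadband = 0.25),
                        phases = "all")
  expect_equal(nrow(g1), 6 * 2)
  expect_equal(sort(unique(g1$half_life)), c(24, 48, 138))
  g2 <- experiment_grid(n_per_arm = 2, mode = "B", seed = 5, constants = cst,
                        policy = policy_proportional(alpha = 0.6, deadband = 0.25),
                        phases = "all")
  expect_identical(g1, g2)
  # calendar bound: monthly arms have at most 14 opportunities, 13 changes
  expect_true(all(g1$n_dose_changes[g1$interval == "monthly"] <= 13))
})

test_that("monthly dosing produces fewer dose adjustments than weekly (matched policy)", {
  pol <- policy_proportional(alpha = 0.6, deadband = 0.25)
  wins <- vapply(1:20, function(s) {
    nw <- summarize_session(run_session(
      session_config(48, "weekly", "B", seed = s, constants = cst),
      policy = pol))$n_dose_changes
    nm <- summarize_session(run_session(
      session_config(48, "monthly", "B", seed = s, constants = cst),
      policy = pol))$n_dose_changes
    nm < nw
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("dose adjustments correlate positively with maintenance haemoglobin variability", {
  alphas <- rep(seq(0.2, 1.6, length.out = 12), each = 5)
  res <- t(mapply(function(al, i) {
    rec <- run_session(
      session_config(24, "weekly", "B", seed = 1000 + i, constants = cst),
      policy = policy_proportional(alpha = al, deadband = 0.25))
    st <- summarize_session(rec, phase = "maintenance")
    c(st$n_dose_changes, st$delta_hb)
  }, alphas, seq_along(alphas)))
  ct <- suppressWarnings(stats::cor.test(res[, 1], res[, 2], method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("an aggressive first dose overshoots more with 138 h + monthly than 24 h + weekly", {
  aggressive <- policy_proportional(initial = 30000, alpha = 1, deadband = 0.25)
  over <- t(vapply(1:12, function(s) {
    o138 <- summarize_session(run_session(
      session_config(138, "monthly", "B", seed = s, constants = cst),
      policy = aggressive))$pct_above_safety
    o24 <- summarize_session(run_session(
      session_config(24, "weekly", "B", seed = s, constants = cst),
      policy = aggressive))$pct_above_safety
    c(o138, o24)
  }, numeric(2)))
  expect_gt(mean(over[, 1] - over[, 2]), 0)
  expect_gte(mean(over[, 1] > over[, 2]), 0.75)
})

test_that("RBC lifespan dispersion: monthly pulsatile dosing exceeds weekly, and longer half-lives damp it", {
  # target-titrated constant dosing isolates the dosing-pattern effect
  sd_life <- function(hl, iv, s) {
    pat <- generate_patient(s, cst)
    pol <- policy_titrated(pat, hl, iv, cst)
    rec <- run_session(session_config(hl, iv, "B", seed = s, constants = cst),
                       patient = pat, policy = pol)
    stats::sd(rec$rbc_lifespan[rec$week >= 17])
  }
  arm <- function(hl, iv) mean(vapply(1:6, function(s) sd_life(hl, iv, s),
                                      numeric(1)))
  for (hl in c(24, 48, 138)) {
    expect_lt(arm(hl, "weekly"), arm(hl, "monthly"))
  }
  # within the pulsatile monthly arm, dispersion falls as half-life grows
  m <- vapply(c(24, 48, 138), arm, numeric(1), iv = "monthly")
  expect_true(all(diff(m) < 0))
})
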