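# eposim

An erythropoietin prescription simulator for haemodialysis patients, as a
scriptable R library plus a small command-line wrapper.

Anaemia management with erythropoietin stimulating agents (ESAs) is hard to
learn from the bedside alone: red blood cells live about two months, so the
haemoglobin consequences of a dose arrive weeks after it is given, and
long-lived compounds (half-lives up to ~138 h, dosed monthly) accumulate in
ways that invite overshoot. `eposim` provides a virtual ESA-naive patient
for training and for batch experiments on dose-titration strategies:
prescribers — interactive users or scripted policies — dose over a 32-week
session (12 weeks of equilibration from a starting haemoglobin of 7–8 g/dL
toward the 11–12 g/dL target, then 20 weeks of maintenance) and are scored
on target occupancy and haemoglobin stability.

## The model in brief

* **Kinetics** — one-compartment mono-exponential decay with superposition:
  `C(t) = Σᵢ Aᵢ · 2^(−24(t−dᵢ)/t½)`, half-life `t½ ∈ {24, 48, 138}` h,
  dosed weekly or monthly.
* **Dose–response** — saturating Emax stimulus on marrow output,
  `P = P₀ + s·Emax·C/(C + C₅₀)`, with patient sensitivity `s` log-normal
  (median 1) and `C₅₀` calibrated so the population's mean weekly need to
  hold mid-target is ≈ 6,000 U.
* **Red-cell population** — daily birth cohorts with a 7-day maturation lag
  and a uniform lifespan law (61.2 ± 15 d) applied as a deterministic
  within-cohort survival schedule; haemoglobin is linear in circulating
  mass; the mean RBC lifespan read-out is turnover-based (mass ÷ daily
  senescence loss) and equals 61.2 d exactly at the pre-treatment steady
  state.
* **Sessions** — weekly observations with ±0.5 g/dL incidental fluctuation;
  in the monthly arm only dosing weeks are visible to the prescriber; study
  mode A injects one random bleed (0–30 % of blood volume, weeks 18–24),
  mode B none.
* **Statistics** — mean ± SD haemoglobin, delta Hb (mean |consecutive
  difference|), % of values < 11 / > 12 / > 13 g/dL, the ability score
  `2 − E/N` (out-of-target values score one error point, values > 13 a
  second), turnover RBC lifespan, dose-adjustment counts, trapezoidal AUC.

See `vignettes/esa-simulation-methods.Rmd` for assumptions, parameter
choices and limitations.

## Worked example

```r
library(eposim)

patient <- generate_patient(seed = 42)
patient
#> Virtual patient (seed 42): starting Hb 7.0 g/dL, sensitivity 1.583, P0 0.11438 mass/d

cfg <- session_config(half_life = 24, interval = "weekly", mode = "B", seed = 42)
rec <- run_session(cfg, patient = patient,
                   policy = policy_proportional(initial = 4000, alpha = 0.6,
                                                deadband = 0.25))
summarize_session(rec, phase = "maintenance")
#> Session statistics
#>   n = 20 weeks; mean Hb 11.85 g/dL (SD 2.25), delta Hb 0.37
#>   Hb <target 55.0%, in target 10.0%, >target 35.0%, >safety 30.0%
#>   ability score 0.80; mean RBC lifespan 56.09 d (SD 6.04)
#>   dose adjustments 18; AUC 223.7 g/dL*weeks
```

The maintenance-phase panel reads: over weeks 13–32 this (rather sensitive,
`s = 1.58`) patient averaged 11.85 g/dL but with wide swings — the simple
multiplicative policy overshot past the 13 g/dL safety threshold in 30 % of
weeks before settling, which the ability score of 0.80 (< 1 because values
above 13 count double) punishes. Delta Hb of 0.37 g/dL per week quantifies
the residual cycling. Running the *same* patient and policy in the
138 h + monthly arm shows the long-half-life hazard directionally:

```r
s138 <- summarize_session(run_session(
  session_config(138, "monthly", "B", seed = 42), patient = patient,
  policy = policy_proportional(initial = 4000, alpha = 0.6, deadband = 0.25)))
c(pct_above_13 = s138$pct_above_safety, dose_changes = s138$n_dose_changes)
#> pct_above_13 dose_changes
#>       40.625       13.000
```

— more overshoot (40.6 % vs 31.2 % of weeks above 13 g/dL over the full
session) with fewer dose adjustments (13 vs 29), because each monthly dose
of the accumulating compound commits a month of exposure sight-unseen.

Batch comparisons across all six half-life × interval arms:

```r
grid <- experiment_grid(mode = "B", n_per_arm = 25,
                        policy = policy_proportional(alpha = 0.6, deadband = 0.25),
                        seed = 1)
```

## Command line

A thin wrapper is installed at `exec/eposim` inside the package:

```sh
eposim play --half-life 138 --interval monthly --mode A --seed 7   # interactive session
eposim run  --half-life 24 --interval weekly --seed 3 --policy proportional --out log.csv
eposim stats --in log.csv --phase maintenance --out stats.json
eposim calibrate --n 500 --seed 1 --out constants.yaml
eposim grid --n 25 --mode B --seed 1 --out results.csv
```

All commands accept `--config FILE` (YAML overrides of the model constants)
and record their seeds in the output headers.

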