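---
title: "Simulating ESA prescription: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating ESA prescription: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eposim)
set.seed(1)
```

## The problem

Erythropoietin stimulating agents (ESAs) span a wide range of half-lives —
roughly 24 h for epoetin, 48 h for darbepoetin, and about 138 h for
continuous erythropoietin receptor activators dosed monthly. The
haemoglobin response of a haemodialysis patient integrates each dose over
the two-month lifespan of the red cells it recruits, so the consequences of
a prescription are felt weeks later and overshooting is easy. `eposim`
implements a virtual patient for studying and training dose-titration
strategies: a prescriber (human at the console, or a scripted policy) doses
an ESA over a 32-week session — a 12-week equilibration phase raising
haemoglobin from 7–8 g/dL toward the 11–12 g/dL target, then a 20-week
maintenance phase holding it there — and is scored on target occupancy and
haemoglobin stability.

## The model

The engine advances in 1-day steps; observations and prescriptions happen
on a weekly grid. A daily internal step is the coarsest that honours a 24 h
drug half-life — a weekly step would alias the concentration profile of the
short-lived compounds.

**Drug kinetics.** Epoetin concentration follows one-compartment
mono-exponential decay with superposition over the dose history:

$$C(t) = \sum_{d_i \le t} A_i \, 2^{-24 (t - d_i)/t_{1/2}}$$

with doses $A_i$ (U) on days $d_i$ and the half-life $t_{1/2}$ in hours
(24, 48 or 138). Concentration carries dose-unit equivalents: no absolute
volume of distribution is modelled, because only the product of patient
sensitivity and the dose–response stimulus is observable.

**Dose–response.** Marrow output is a saturating Emax law,

$$P(t) = P_0 + s \cdot E_{\max} \frac{C}{C + C_{50}},$$

where $P_0$ is the endogenous baseline production, $s$ the patient's
log-normal sensitivity (median 1, $\sigma_{\log} = 0.3$), $E_{\max} = 0.6$
RBC mass units/day and $C_{50}$ the half-saturation concentration. $E_{\max}$
was chosen so that therapeutic doses sit in the responsive, moderately
saturated regime: at mid-target the typical patient works at ~10–20% of
$E_{\max}$, which keeps the weekly-need distribution across the population
from developing a heavy saturation tail. Given $E_{\max}$, $C_{50}$ is not a
free parameter: `calibrate_dose_response()` pins it so that the population
mean weekly epoetin need to hold haemoglobin at mid-target (11.5 g/dL,
24 h half-life, weekly dosing) is ~6,000 U. The packaged default
($C_{50} = 11001.39$ dose-unit equivalents) is the result of that
calibration at $n = 500$ patients.

**Maturation delay.** Pre-erythrocyte kinetics are collapsed to a fixed
7-day lag: the stimulus felt by precursors on day $t - \tau$ matures into a
circulating cohort on day $t$. A distributed precursor chain would smear
this lag, but with weekly observation the difference is second-order.

**The red-cell ledger.** Each day one cohort is born carrying one day of
production. Cell lifespans within a cohort follow the uniform law on
$[\bar{L} - \sigma_L, \bar{L} + \sigma_L]$ with $\bar{L} = 61.2$ d and
$\sigma_L = 15$ d, applied as a deterministic within-cohort survival
schedule: the mass of a cohort alive during day $a$ of life is its birth
mass times the day-averaged survival $w(a) = \int_a^{a+1} S(u)\,du$. We
deliberately use the expected survival rather than sampling one lifespan
per cohort: cells born the same day do not all die on the same day, the
ledger stays free of sampling noise, and two identities become exact —
the pre-treatment steady state (cohorts of ages $0 \dots \lceil \bar{L} +
\sigma_L \rceil - 1$, each born with mass $P_0$, give total mass exactly
$P_0\bar{L}$ because $\sum_a w(a) = \bar{L}$ for *any* spread), and the
turnover lifespan below.

**Read-outs.** True haemoglobin is linear in circulating mass,
$Hb = \kappa \cdot M$ with $\kappa = 1$ g/dL per mass unit, and
$P_0 = Hb_0 / (\kappa \bar{L})$ ties the endogenous production to the
starting haemoglobin so that an undosed, noise-free patient is exactly
stationary. The *mean RBC lifespan* read-out uses the turnover definition:
circulating mass divided by the expected daily senescence loss, the loss
smoothed over a 7-day forward window. At steady state mass $= P_0\bar{L}$
and loss $= P_0$, so the read-out is exactly 61.2 d at initialisation, and
it fluctuates with the age distribution during the session. (The identity
requires the minimum lifespan to exceed the 7-day smoothing window, i.e.
$\sigma_L \le \bar{L} - 7$; the default is far inside.)

**Bleeding.** A bleed of fraction $f$ multiplies every cohort by $1-f$:
instantaneous proportional removal with immediate plasma-volume refill, so
the haemoglobin drop equals the volume fraction and the normalized age
distribution is unchanged. In study mode A one bleed is drawn per session,
week uniform on 18–24 and fraction uniform on $[0, 0.30]$; mode B has none.

**Observation.** Incidental haemoglobin fluctuation is observation-level
uniform noise on $\pm 0.5$ g/dL; it never feeds back into the mass balance,
which keeps the conservation invariants exact and testable. Both the truth
and the noise are quantized to the 0.1 g/dL instrument grid before summing,
so a reported value never departs from the (0.1-rounded) truth by more than
0.5 g/dL — rounding the *sum* instead could leak up to 0.05 g/dL past the
bound. A consequence worth noting: because noise does not touch the state,
a patient's weekly epoetin *need* (the dose holding true haemoglobin at
target) is the same with noise on or off, and the population calibration is
therefore run noise-free without loss.

## Sessions, calendars and visibility

A session is 32 weeks = 224 daily steps. Weeks 1–12 are the equilibration
phase and 13–32 maintenance; the boundary is fixed at week 13 whether or
not the target was reached. Dosing opportunities are every week in the
weekly arm; in the monthly arm, weekly during the 8 titration weeks, then
weeks 9, 13, 17, 21, 25, 29 (14 opportunities). "Biweekly" titration is
supported simply by a policy declining alternate opportunities. The
prescriber sees haemoglobin only on its arm's calendar — every week in the
weekly arm, only the dosing weeks in the monthly arm — while the true
weekly series is always logged for analysis. Policies receive exactly the
visible rows, so information hiding is structural, not advisory.

Doses are non-negative real numbers of units with no granularity
constraint; the CLI merely rounds the display. All randomness flows from
named seeds, one independent stream per concern (patient, observation
noise, bleeding), so toggling one feature does not shift another's draws
and every record is bit-reproducible from its seeds.

## Statistics

On a chosen phase and sampling grid (`summarize_session()`): mean and SD of
haemoglobin; *delta Hb*, the mean absolute difference between consecutive
values — sensitive to week-to-week cycling where the SD is blind (an
alternating 11/12 series and its sorted copy have equal SD but very
different delta Hb); percentages below 11, in 11–12 (boundaries in-target),
above 12 and above 13 g/dL; the *ability score* $2 - E/N$ where each
out-of-target value adds one error point and each value above 13 g/dL a
second one — 2 when all values are in target, 1 when all are out (none past
13), below 1 with overshoot; the turnover RBC lifespan (mean and SD across
the session); the number of dose adjustments (first dose not counted); and
the trapezoidal AUC of the haemoglobin profile. The score normalization
$2 - E/N$ is the simplest form consistent with its two anchors (all-out
$\to$ 1; double error above 13); the default variability grid is the weekly
true series, with visible-only sampling available for arm comparisons.

## Scripted prescribers and calibration experiments

`policy_proportional()` titrates multiplicatively,
$D_{k+1} = D_k (Hb_{\mathrm{target}}/Hb_{\mathrm{obs}})^\alpha$ clipped to
bounds, with an optional deadband; it makes no attempt to model human
behaviour, so cross-arm comparisons are directional only.
`policy_titrated()` doses each arm at the patient's analytic steady-state
need for that half-life and interval, which holds every arm at the same
haemoglobin level and isolates the effect of the dosing *pattern*.
`experiment_grid()` crosses half-lives by intervals with shared patients
per replicate for paired comparisons.

Under these harnesses the package reproduces, directionally: fewer dose
adjustments with monthly than weekly dosing; a positive correlation between
adjustment counts and maintenance delta Hb across a policy-gain sweep; more
overshoot above 13 g/dL when an aggressive first dose meets the 138 h
half-life with monthly dosing than with 24 h weekly; larger RBC-lifespan
dispersion under monthly than weekly dosing at every half-life; and, within
the pulsatile monthly arm, lifespan dispersion falling as the half-life
grows (a single monthly dose of a short-lived compound generates cells in
bursts, a long-lived one smooths generation).

One related ordering does **not** emerge from this engine: within the
*weekly* arm, lifespan dispersion does not decrease with half-life. At a
target-titrated steady state the weekly production cycle is phase-locked to
the weekly observation grid, so the read-out is essentially constant for
every half-life; under feedback policies, dose-change transients scale with
the per-dose exposure (proportional to half-life) and dominate, reversing
the ordering. We report this as a limitation rather than tuning a harness
to force it.

## Numerical choices and degenerate inputs

Time step 1 day; all root finding (per-patient need, population $C_{50}$)
by bisection/Brent on monotone functions with generous brackets; lifespan
spread 0 is supported (all cells die at 61.2 d, with the boundary day
handled by the cell-averaged survival); an empty cohort ledger makes the
lifespan read-out an error, not a number; bleeding fractions outside
$[0, 0.30]$, negative times, amounts, or doses are domain errors; policies
returning negative or non-finite doses abort the session. Test and example
problem sizes (500-patient calibrations, grids of tens of sessions) were
chosen so the full suite exercises every property in well under a minute on
one core; sessions cost ~30 ms each, so users can scale batch experiments
up by orders of magnitude.

## What the generator does and does not emulate

The virtual patient reproduces the *structure* of the clinical problem —
slow integrating response, dose accumulation with long half-lives,
information loss under monthly monitoring, observation noise, acute blood
loss — with study conditions fixed at: starting haemoglobin uniform on the
7.0–8.0 g/dL grid, sensitivity log-normal (median 1, $\sigma_{\log}=0.3$),
mean RBC lifespan 61.2 d, ±0.5 g/dL incidental fluctuation, ~6,000 U mean
weekly need. It does not model iron availability, hepcidin or inflammation,
endogenous erythropoietin feedback, neocytolysis, administration-route
differences, or inter-individual variability in RBC lifespan or in
$\kappa$. Passing tests therefore demonstrate internal consistency and the
directional pharmacology above, not predictive validity for real patients;
the tool is for training and hypothesis exploration, not for prescribing.
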