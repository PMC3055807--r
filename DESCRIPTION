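Package: eposim
Title: Erythropoietin Prescription Simulator for Haemodialysis Patients
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable erythropoietin stimulating agent (ESA) prescription
    simulator: a virtual haemodialysis patient whose haemoglobin responds to
    epoetin doses through mono-exponential drug kinetics and an age-structured
    red-blood-cell cohort population. Provides randomized virtual patient
    generation, a daily-step erythropoiesis engine with maturation delay and
    bleeding events, 32-week prescription sessions (12-week equilibration plus
    20-week maintenance, haemoglobin target 11-12 g/dL) with weekly or monthly
    dosing calendars and interval-dependent haemoglobin visibility, the
    associated variability and prescription-quality statistics (delta Hb,
    target-range occupancy, ability score, turnover red-blood-cell lifespan,
    trapezoidal AUC), scripted dose-titration policies, population calibration
    of the dose-response scale, and a batch experiment grid for comparing
    half-life by administration-interval strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
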