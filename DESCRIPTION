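Package: cathflow
Title: Flow-Stop Detection and Crossover Analysis for Intermittent
    Catheterisation Pressure-Volume Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing urodynamic pressure-volume traces recorded
    during clean intermittent catheterisation and for the statistical
    analysis of two-period crossover device trials built on such traces.
    Provides flowrate estimation from cumulative drained-volume recordings,
    rule-based detection of flow-stop episodes (flowrate below 0.8 mL/s for
    at least two seconds) with terminal-episode discounting, derivation of
    per-catheterisation endpoints (flow-stop count, residual urine at the
    first flow-stop, peak suction pressure, dipstick haematuria), triplicate
    bladder-scan handling, linear and generalised linear mixed models with
    subject random intercepts and device/visit fixed effects, fixed-sequence
    gatekeeping of co-primary endpoints, a Wilcoxon signed-rank robustness
    check, and a block-randomised synthetic trial generator for end-to-end
    validation of the measurement-to-inference chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    lmerTest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
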