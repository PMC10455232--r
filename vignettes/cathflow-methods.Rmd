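---
title: "Methods: flow-stop detection and crossover analysis of catheterisation traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flow-stop detection and crossover analysis of catheterisation traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cathflow)
```

## The measurement problem

Clean intermittent catheterisation (CIC) empties the bladder through a
single-use catheter. With a conventional eyelet catheter (CEC, two drainage
eyelets at the tip), the bladder mucosa can be sucked into an eyelet as the
bladder collapses, blocking the flow: a *flow-stop*. Each flow-stop either
leaves residual urine in the bladder — a urinary-tract-infection risk
factor — or forces the user to reposition the catheter, which scrapes the
mucosa. A micro-hole zone catheter (MHZC, ~120 micro-holes of ~0.13 mm²
spread over a 60 mm zone) distributes the suction so that flow-stops should
essentially disappear.

In a two-visit crossover evaluation of the two designs, each
catheterisation is instrumented: drained urine mass is logged on a
precision scale and intra-catheter pressure by a fibre-optic sensor, both
at a nominal 2.5 Hz. From the cumulative pressure–volume trace, the
analysis chain must derive per-catheterisation endpoints and then compare
devices with models that respect the within-subject design. `cathflow`
implements that chain end to end, together with a synthetic generator that
makes every stage testable against known ground truth.

## Trace model and flowrate estimation

A trace is (t, v, p): time since insertion (s), cumulative drained volume
(mL, mass converted at 1 g = 1 mL since urine density is within a fraction
of a percent of water), and atmospheric-corrected intra-catheter pressure
(cmH2O, suction negative). Scale noise can make the cumulative reading dip
between samples; since drained volume is physically non-decreasing, the
constructor repairs it with a running maximum (idempotent, never decreases
a sample) and records the number of repaired points. Sampling gaps longer
than 2 s are flagged and never interpolated.

The flowrate at each sample is the slope of a local least-squares line over
the samples within ±0.6 s (about three samples at 2.5 Hz), clipped below at
zero. First differences were rejected: at 0.4 s spacing even modest scale
noise makes raw differences cross the detection threshold spuriously,
whereas the 3-point regression slope has roughly 1/√2 the noise and is
exact for linear segments.

## The flow-stop rule

A flow-stop episode is a maximal interval in which the flowrate stays below
0.8 mL/s for at least 2 s. The clinical workflow applies this threshold
automatically and then resolves borderline cases by manual inspection of
the pressure channel; a reproducible pipeline cannot contain a human step,
so `cathflow` replaces it with deterministic rules, all exposed in
`detector_config()`:

* **Flow onset.** Non-terminal detection starts at the first sample with
  flowrate ≥ 0.8 mL/s; otherwise the pre-drainage dead time (catheter
  handling before urine reaches the scale) would count as a spurious
  leading flow-stop.
* **Merge rule.** Above-threshold blips shorter than `merge_gap` (0.4 s)
  do not split an episode. At the nominal 2.5 Hz a gap is at least one
  0.4 s sample and is never merged; the rule only bites for oversampled
  traces.
* **Pressure support.** Instead of manual pressure reading, each episode
  carries the most negative pressure in a ±1 s padded window and a
  `pressure_supported` flag (peak suction below −5 cmH2O), so downstream
  users can filter on it.
* **Boundaries** are closed on the left, open on the right; an episode's
  end is the time of the first sample after its last sub-threshold sample.

The episode that extends to the end of the recording is *terminal*: the
last flow-stop is the end of the catheterisation and is discounted, so a
single-episode catheterisation counts as zero flow-stops.

## Endpoints

`derive_endpoints()` computes, per catheterisation: the total volume
V_total; the cumulative volume at onset of the *first* episode (terminal
or not); their difference, the residual urine at first flow-stop
(RV1 = V_total − V_first); the non-terminal episode count; the suction
peak around the first episode; and, from the clinical record, the binary
dipstick haematuria and the mean triplicate post-void scan. Taking the
first episode's *onset* (not offset) defines RV1 as the urine a user would
have left behind had they removed the catheter at the first stop; it also
makes RV1 strictly positive for zero-flow-stop catheterisations, which is
what the terminal dribble represents. RV1 + V_first = V_total holds by
construction and is asserted property-style in the tests.

Triplicate bladder scans are aggregated by arithmetic mean (the mean and
median differ negligibly for triplets, and the mean matches how scan
volumes are usually reported); eligibility requires all three pre-void
scans at or above 150 mL, not just the mean. The seven dipstick categories
dichotomise with the four 1+/2+/3+ levels positive and negative/trace
levels negative.

## Synthetic data generator

The generator has two layers.

`simulate_profile()` builds one trace from a phenomenological drainage
model: a gently tapering plateau flow (default 2.5 mL/s), optional
suction events during which flow drops to zero and pressure spikes
negative, a terminal cessation at a drawn residual, a slow sub-threshold
dribble (0.25 mL/s) and a zero-flow tail. Events are parameterised by the
drainable volume remaining at onset, so the true RV1 and event count are
known exactly and are returned as ground truth. Event onsets are kept at
least ~4 mL of drainage apart and away from the trace ends so ground truth
stays unambiguous for the detector-oracle tests. Scale noise is Gaussian
with SD 0.05 g per sample — the scale of a precision weighing instrument —
and is repaired by the running maximum exactly as real traces are. Suction
amplitudes are log-normal, truncated at the extreme observed magnitudes
per device (87.7 cmH2O for the MHZC, 423.2 cmH2O for the CEC), and
pressure is clipped to that range.

`simulate_trial()` draws a whole two-period crossover: sequences assigned
in blocks of four (two of each order per block, the final partial block as
balanced as the remainder allows), subject random intercepts per endpoint,
device and visit fixed effects on each endpoint's link scale, one expected
visit-2 dropout in 42. The first-stop residual is generated on the log
scale by default — the endpoint is non-negative and strongly right-skewed,
spanning below 10 mL to above 100 mL under the eyelet device — with a
Gaussian option for calibration studies where an additive effect must be
recovered on the raw scale. The flow-stop count is Poisson with log link
(the device effect is a rate ratio, default 0.16); haematuria is Bernoulli
with logit link (default odds ratio 0.26). Marginal CEC-arm levels are
matched to 39.4 mL, 1.09 stops and 29% positive by offsetting the
intercepts for the random-effect variance. All of these defaults are a
*synthetic calibration* chosen to reproduce the magnitude of published
device-level summaries; the true per-device event-rate and amplitude
distributions are not public, so nothing here is an estimate of them.

With `with_traces = TRUE` each row's trace is conditioned on that row's
drawn count and residual, coupling the signal-processing layer to the
statistical layer: detector-derived endpoints then agree in distribution
with fresh endpoint-level draws (checked by two-sample Kolmogorov–Smirnov
in the tests). What the generator does *not* emulate: irregular sampling
and dropouts, abdominal-pressure artefacts, slow drifts of the scale,
user repositioning mid-catheterisation, and any dependence between event
count and residual beyond the conditioning above. Passing tests therefore
validate the pipeline's logic, not the physiological realism of any
particular parameter value.

## Statistical analysis

Each endpoint is analysed on all available rows (likelihood-based, no
imputation of the missing visit):

* **Continuous endpoints** (first-stop residual, suction peak, post-void
  residual): `fit_lmm()` fits y ~ device + visit + (1 | subject) by REML.
  The device contrast is reported as CEC − MHZC with a t interval on the
  within-subject residual degrees of freedom
  (n_obs − n_fixed − (n_subjects − 1), the natural inner-stratum df for a
  two-period crossover); Satterthwaite df are available via lmerTest. A
  boundary fit (between-subject variance 0) is flagged, not failed: the
  model then collapses onto the fixed-effects fit, which the tests assert
  to 1e-4.
* **Flow-stop count**: `fit_count_glmm()` fits a Poisson log-link random
  intercept model by adaptive Gauss–Hermite quadrature (15 nodes by
  default; the count family is Poisson because the device effect is
  reported as a rate ratio, with negative binomial behind a flag for
  overdispersion). exp(device coefficient) is the MHZC:CEC rate ratio;
  100×(1−ratio) the percent reduction. If one arm has no events the Wald
  interval degenerates and a profile-likelihood interval over the device
  coefficient is substituted with a warning.
* **Haematuria**: `fit_binary_glmm()`, logit link, same structure; the
  subject's bladder-dysfunction history can enter as a fixed covariate
  (it is optional in every model but only used for haematuria by the
  pipeline, where microtrauma plausibly depends on history). On
  separation the reported fallback is a Firth-penalised fixed-effects
  logistic fit.
* **Gatekeeping**: the co-primary endpoints are tested in fixed order —
  first-stop residual, then flow-stop count — each at unadjusted α = 0.05;
  a failure stops testing. Because later hypotheses are reached only
  after earlier rejections, the family-wise error rate is α without any
  p-value adjustment; the tests verify ≈5% family-wise size over 2000
  simulated null trials of 42 subjects.
* **Robustness**: `wilcoxon_signed_rank()` on the per-subject
  within-subject differences checks the normality assumption behind the
  linear mixed model. Zeros are dropped, ties get average ranks, the
  exact distribution is used up to n = 25 untied differences (verified
  against full 2^n enumeration in the tests) and a tie- and
  continuity-corrected normal approximation above.

Ratios are oriented MHZC vs CEC (benefit < 1) and differences CEC − MHZC
(benefit > 0), matching how a device comparison table is usually read.

## Numerical and design choices

* Flowrate windows are computed with prefix sums, O(n) per trace, exact
  for the OLS slope; windows with fewer than two distinct time points
  return slope 0.
* The detector is checked against a naive per-sample brute-force scan on
  1000 seeded traces in the acceptance tests; the two must agree exactly.
* Quadrature uses 15 nodes by default; the repeated-fit calibration loops
  in tests and the acceptance script use 9 nodes, which changes estimates
  by far less than Monte-Carlo noise at 500 replicates.
* Simulation sizes — 1000 traces for the oracle comparison, 2000 trials
  for the null calibration, 500 for parameter recovery, 250
  catheterisations per arm for the distribution-consistency check — keep
  Monte-Carlo error small relative to every asserted tolerance while the
  whole suite runs in minutes on one CPU.
* Seeds: `simulate_trial()` takes an explicit seed; the pipeline stamps
  the seed and a config hash into every artifact, and identical seeds
  reproduce outputs byte for byte.

## Known limitations

* The phenomenological trace model has no mechanistic hydrodynamics; it
  cannot say anything about *why* micro-holes prevent suction, only
  emulate the measured consequences.
* The generator's per-device distributions are calibrated to published
  summary statistics, not fitted to subject-level data; absolute
  agreement of simulated summaries with any real trial is approximate by
  design.
* The merge rule and pressure-support flag replace, but cannot perfectly
  reproduce, expert manual inspection of borderline dips.
* Whether the first-stop volume should be read at episode onset or offset
  is a judgement call; onset is used throughout (see above).
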