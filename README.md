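# cathflow

Flow-stop detection and crossover analysis for intermittent
catheterisation pressure–volume traces.

## The problem

Users of clean intermittent catheterisation (CIC) empty the bladder
several times a day through a single-use catheter. With a conventional
eyelet catheter (CEC) the collapsing bladder mucosa gets sucked into the
drainage eyelets, interrupting the flow (a *flow-stop*); each interruption
either leaves residual urine — a urinary-tract-infection risk factor — or
forces a mucosa-scraping repositioning of the catheter. Micro-hole zone
catheters (MHZC) spread drainage over ~120 micro-holes to prevent mucosal
suction. Evaluating the two designs requires (i) deriving objective
endpoints from instrumented catheterisations — drained mass on a precision
scale and intra-catheter pressure at ~2.5 Hz — and (ii) comparing devices
within subjects in a randomised two-period crossover.

`cathflow` implements that full measurement-to-inference chain for
biostatisticians and device-evaluation teams:

* **Flow-stop rule.** The flowrate (local least-squares slope of the
  cumulative volume over ±0.6 s, clipped at 0) defines a flow-stop as a
  maximal interval below 0.8 mL/s lasting at least 2 s. The final episode
  is the end of the catheterisation and is discounted, so a
  single-episode catheterisation has zero counted flow-stops.
* **Endpoints.** Residual urine at the first flow-stop
  `RV1 = V_total − V_first-stop`, flow-stop count, suction-pressure peak,
  dichotomised dipstick haematuria, triplicate bladder-scan summaries.
* **Crossover models.** Per endpoint: linear or generalised linear mixed
  model with subject random intercept and device + visit fixed effects
  (`y ~ device + visit + (1 | subject)`), Poisson log link for counts
  (rate ratio), logit link for haematuria (odds ratio), fixed-sequence
  gatekeeping of the co-primary endpoints (RV1 first, then counts) and a
  Wilcoxon signed-rank robustness check with an exact small-sample null.
* **Synthetic generator.** A phenomenological catheterisation simulator
  with exact ground truth, plus a block-randomised trial simulator, so
  every stage is testable without clinical data.

## Worked example

Simulate one eyelet-catheter catheterisation with two injected suction
events and a true first-stop residual of 40 mL, then detect and derive:

```r
library(cathflow)
set.seed(7)
sim <- simulate_profile(device = "CEC", n_events = 2, first_stop_volume = 40)
eps <- detect_flow_stops(sim$trace)
derive_endpoints(sim$trace, eps)[, c("v_total", "v_first_stop", "rv1",
                                     "n_flow_stops", "peak_suction_first")]
#>    v_total v_first_stop      rv1 n_flow_stops peak_suction_first
#> 1 496.2293     456.6984 39.53089            2          -60.27423
```

The detector recovers both injected stops exactly and the 40 mL residual
to within half a sample's volume, from a noisy trace repaired by running
maximum (27 samples touched here).

A full pipeline run — simulate a 42-subject crossover with traces, detect
every flow-stop, fit the mixed models, gatekeep the co-primary endpoints:

```r
out <- run_pipeline(run_config(seed = 1, out_dir = tempfile()), quiet = TRUE)
out$summary[1:3, c("endpoint", "mhzc_mean", "cec_mean", "effect", "p_value")]
#>              endpoint mhzc_mean cec_mean  effect   p_value
#> 1                 rv1    4.4502  28.0116 23.5614 7.077e-07
#> 2        n_flow_stops    0.2757   0.7402  0.3725 2.305e-03
#> 3 haematuria_positive    0.0518   0.1810  0.2472 7.696e-02
out$gatekeeping
#> Fixed-sequence gatekeeping at alpha = 0.05
#>       endpoint   p_value decision
#> 1          rv1 7.077e-07 rejected
#> 2 n_flow_stops 2.305e-03 rejected
#> Overall: PASS
```

Reading the rows: the model-based first-stop residual means are 4.5 mL
(MHZC) vs 28.0 mL (CEC), a CEC−MHZC difference of 23.6 mL; flow-stops show
a rate ratio of 0.37 (63% fewer with the MHZC); the haematuria odds ratio
is 0.25 but not significant at this single simulated trial's size. Both
co-primary endpoints reject in order, so the hierarchical procedure
passes. Every artifact (`endpoints.csv`, `summary.csv`, `report.md`,
`endpoints.json`) is stamped with the seed and a config hash; the same
seed reproduces them byte for byte.

Clinical-record helpers follow the study conventions: dipstick categories
use the canonical strings `negative`, `non-haemolysed 10 (+/-)`,
`haemolysed 10 (+/-)`, `haemolysed 25 (1+)`, `haemolysed 80 (2+)`,
`non-haemolysed 80 (2+)`, `haemolysed 200 (3+)` (the last four are
positive); triplicate scans aggregate by mean with eligibility requiring
all three pre-void volumes ≥ 150 mL.

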