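# picusirs

Rule-based detection of the systemic inflammatory response syndrome (SIRS)
in pediatric intensive-care (PICU) time series, together with the full
diagnostic-accuracy machinery needed to evaluate such a detector — or a
bedside rater — against an adjudicated reference standard.

The package is aimed at clinical-informatics and biostatistics groups who
build or validate knowledge-based alerting systems on routine PICU data and
need the evaluation statistics to respect the clustered structure of that
data (repeated days and stays within patients).

## What it computes

**The detection rule.** Pediatric SIRS is present when at least two of the
four age-specific consensus (IPSCC) criteria are abnormal — core temperature,
leukocyte count, heart rate, respiratory rate — *one of which must be the
temperature or the leukocyte criterion*. Point measurements are extended by
sample-and-hold (default 4 h for vitals, 24 h for laboratory values), limits
are resolved per age band at every instant from an editable YAML threshold
table, and context rules apply: hypothermia does not fire during active
cooling, the heart-rate criterion is silent under a pacemaker, and during
mechanical ventilation measured respiratory rates are not compared at all —
the respiratory criterion instead fires on ventilated intervals flagged as
acute. The leukocyte criterion also fires on a left shift
(immature-neutrophil fraction above 10%).

**Timeline rules.** A SIRS episode ends only once criteria are unfulfilled
for ≥ 24 consecutive hours (the closing rule; the documented end is the last
instant criteria held), and a patient-day is SIRS-positive when it contains
at least one full hour of SIRS (cumulative by default, a contiguous-run mode
behind a flag).

**Accuracy statistics.** Stays are scored against the reference by ±4 h
episode-start matching into the six-case scheme {FP, TP, FN, TN, FN+FP,
FP+TP} (the combined cases contribute two assessment units); patient-days by
the plain four cells. Sensitivity and specificity are estimated by an
intercept-only logistic GEE with exchangeable working correlation and
clusters = patients: with cluster sizes `n_i`, correlation `α` and
`p = expit(β)`, the estimating equation collapses to

```
p = Σ_i w_i ȳ_i / Σ_i w_i ,   w_i = n_i / (1 + (n_i − 1) α)
```

with `α` re-estimated from Pearson residual cross-products and a robust
sandwich variance for `β̂`; 95% Wald intervals are logit-symmetric and
back-transformed. Secondary machinery: specificity among never-SIRS
patients, age subgroups (< / ≥ 12 months), a hypothermia-rule ablation,
best/worst-case bounds under day-level missingness, and the one-proportion
normal-approximation sample-size planner.

**Synthetic cohorts.** A seeded generator emulates the PDMS export schema
(patients, stays, observations, context intervals, reference episodes,
routine per-shift forms) with injected episodes whose driving variables are
pushed beyond the active thresholds, so every pipeline stage is testable
with known ground truth.

## Worked example

```r
library(picusirs)
gen    <- generate_cohort(cohort_scenario(seed = 42, n_patients = 15))
tabs   <- detection_tables(detect(gen$cohort))
report <- evaluate_accuracy(gen$cohort, tabs$episodes,
                            detected_days = tabs$day_labels)
print(report)
```

```
<sirs_evaluation>
-- stay level --
<contingency_table> level=stay
      ref+ ref- total
test+    9    0     9
test-    0    8     8
column totals: 9 / 8; grand total 17
sensitivity (gee): 1.000 [1.000, 1.000] [degenerate]  (n=9 units, 8 clusters)
specificity (gee): 1.000 [1.000, 1.000] [degenerate]  (n=8 units, 7 clusters)
-- day level --
<contingency_table> level=day
      ref+ ref- total
test+   35    0    35
test-    0  228   228
column totals: 35 / 228; grand total 263
sensitivity (gee): 1.000 [1.000, 1.000] [degenerate]  (n=35 units, 8 clusters)
specificity (gee): 1.000 [1.000, 1.000] [degenerate]  (n=228 units, 15 clusters)
```

This cohort is noise-free, so the detector reproduces its own ground truth
exactly: 9 stays with episodes all matched (plus 8 true-negative stays,
17 assessment units over 15 patients), and all 35 SIRS-positive patient-days
recovered. Estimates of exactly 0 or 1 have no binomial information for a
Wald interval, so they are flagged `[degenerate]` rather than given a fake
width. Noisy mode (`mode = "noisy"`, `borderline_rate > 0`) produces the
borderline false alarms that make the numbers interesting.

```r
cmd_samplesize(list())
#> $sensitivity  93      # alternative 98% vs null 90%
#> $specificity 137      # alternative 90% vs null 80%
```

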