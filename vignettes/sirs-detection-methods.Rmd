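---
title: "Detecting pediatric SIRS and evaluating detector accuracy on clustered data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pediatric SIRS and evaluating detector accuracy on clustered data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picusirs)
```

## The detection model

The systemic inflammatory response syndrome (SIRS) in children is defined by
the pediatric consensus criteria: at least two of four abnormalities — core
temperature, leukocyte count, heart rate, respiratory rate — of which at
least one must be the temperature or the leukocyte criterion. All four are
age-dependent; `picusirs` ships the consensus limits as an editable YAML
table (`inst/extdata/ipscc_thresholds.yaml`) whose six bands partition ages
0 to < 18 years in days. The engine treats the table purely as data: swap in
a different file to run with local limits.

The raw inputs are point measurements, so the engine first extends each
value forward by **sample-and-hold**: a value holds until the next
measurement or until a validity horizon expires, whichever comes first.
Defaults are 4 h for vitals and 24 h for laboratory values, reflecting
monitoring versus laboratory cadence in intensive care; both are parameters
of `detect_config()`. Wherever the held signal is unknown, a criterion
*cannot* fire and never counts toward the two-of-four rule — a deliberately
conservative reading: absence of data is not evidence of abnormality.

Three context rules modify the plain threshold comparisons:

* **Active cooling** suppresses the hypothermia (low-temperature) sub-rule
  for its duration; induced hypothermia is not an inflammatory sign. The
  whole hypothermia sub-rule can also be disabled
  (`detect_config(hypothermia = FALSE)`), which is the ablation arm of
  `sensitivity_analysis_exclude_hypothermia()`.
* **Pacemaker** intervals silence the heart-rate criterion entirely: a paced
  rate carries no diagnostic information in either direction.
* **Mechanical ventilation** removes measured respiratory rates from
  comparison altogether (a ventilated rate is set by the machine); instead
  the respiratory criterion fires on ventilated intervals exactly when the
  ventilation is flagged *acute*. Treating ventilation itself as the
  abnormality, rather than comparing machine-set rates against limits, is
  the behaviour the rule set intends.

Bradycardia counts only in the age bands flagged for it (the infant bands),
and the leukocyte criterion also fires on a left shift — an
immature-neutrophil fraction above the configured limit (default 0.10).

**Comparator convention.** Limits are exclusive: a value must be strictly
beyond the limit to fire. This makes boundary behaviour deterministic and
testable (38.5 °C does not fire, 38.51 °C does); the YAML flag
`limits_exclusive` switches to weak inequalities if a site reads its limits
inclusively.

**Validation flag.** Observations carry a `validated` boolean. By default
all observations are used; `detect_config(validated_only = TRUE)` drops
unvalidated rows, so both behaviours of a manual-validation workflow can be
compared.

## Timeline rules

The instantaneous rule state is turned into clinical objects by two
temporal conventions:

* **Episodes** (`build_episodes()`): raw SIRS intervals separated by less
  than 24 h of quiet belong to one episode; an episode ends only once
  criteria are unfulfilled for at least 24 consecutive hours, and the
  documented end is the *last instant criteria held*, not the end of the
  closing gap. A gap of exactly 24 h separates episodes. Episodes whose span
  falls short of 60 min are discarded — this aligns flicker suppression with
  the one-hour day rule below and can be set to 0 to see raw behaviour.
* **SIRS-positive days** (`label_days()`): a calendar day of a stay is
  positive when it contains at least one full hour of SIRS. "One full hour"
  is read **cumulatively** within the calendar date by default — the weaker,
  more sensitive reading of "suffered from SIRS for at least one hour" — with
  a contiguous-run mode (`day_rule = "contiguous"`) behind a flag, since a
  qualifying hour could be required to be uninterrupted. An episode
  straddling midnight with 45 min on each side yields two negative days
  under either reading; the flag matters only for interrupted SIRS time.
  Calendar days are midnight-to-midnight on the single, timezone-naive study
  clock; `day_offset_hours` moves the cut (e.g. to 06:00 shift changes).

Stays are half-open windows `[admit, discharge)`: a discharge exactly at
midnight does not add the discharge date to the patient-days. Open-ended
reference episodes (ongoing at discharge) are truncated at discharge for all
computations.

## Scoring against the reference standard

At **stay level**, detected and reference episodes are matched one-to-one
when their starts lie within ±4 h (inclusive). Matching is greedy in
reference order, taking the nearest admissible unmatched detected episode,
ties toward the earlier start. Greedy matching can be sub-maximal on
contrived overlapping layouts (two references at 0 h and 1 h, detections at
−3.5 h and +0.9 h: greedy pairs only one, an optimal assignment pairs both);
the test suite pins this instance down as a documented limitation. In
practice episodes are separated by the 24-h closing rule, which makes such
layouts rare.

Each stay then falls into one of six cases: FP, TP, FN, TN, FN+FP, FP+TP.
A stay with at least one matched episode contributes TP; unmatched detected
episodes contribute FP; FN arises only when reference episodes exist and
*none* matched. This **TP precedence** (a stay never contributes TP and FN
simultaneously — extra unmatched reference episodes are absorbed) is forced
by the six-case scheme itself, which contains no TP+FN combination. The
combined cases contribute two assessment units, so the assessment-unit total
exceeds the stay count by the number of case-5 and case-6 stays. At **day
level** only the four plain cells are used.

## The GEE estimator

Days and stays of one patient are correlated, so sensitivity and specificity
are estimated by an intercept-only logistic marginal model with exchangeable
working correlation, fitted by generalized estimating equations with
**clusters = patients** at both levels (a quarter of patients have multiple
stays, so clustering on stays would understate the dependence). For clusters
of size $n_i$ with mean $\bar y_i$, working correlation $\alpha$ and
$p = \mathrm{expit}(\beta)$, the estimating equation reduces to the weighted
mean

$$p = \frac{\sum_i w_i \bar y_i}{\sum_i w_i}, \qquad
  w_i = \frac{n_i}{1 + (n_i - 1)\alpha},$$

because the inverse exchangeable correlation matrix applied to a constant
vector is a scalar multiple of it. The fit alternates this closed form with
the moment estimator of $\alpha$ from Pearson-residual cross-products
(denominator: pair count minus the one mean parameter, clamped to the
positive-definite range) until both stabilize to $10^{-12}$; a final mean
update at the converged $\alpha$ makes the estimating-equation residual
exactly zero in floating point, and every fit records that residual. The
variance of $\hat\beta$ is the robust sandwich, which for this model
collapses to

$$\widehat{\mathrm{Var}}(\hat\beta) =
  \frac{\sum_i \left[ (S_i - n_i p) / (1 + (n_i-1)\alpha) \right]^2}
       {\left[ p(1-p) \sum_i w_i \right]^2},$$

with $S_i$ the cluster outcome sum. Two exact identities make useful tests
and sanity anchors: with all-singleton clusters the estimate and its
standard error equal the crude binomial ones, and with equal cluster sizes
the estimate is the pooled mean at any $\alpha$.

**Confidence intervals** are Wald intervals symmetric on the logit scale and
back-transformed, which keeps them inside $(0,1)$; a linear-scale variant is
available behind `ci_scale = "linear"` for comparison, since either reading
of "Wald interval" is defensible. When all outcomes are identical the
proportion is 0 or 1, the logit is infinite, and no Wald interval exists;
such estimates are returned with a zero-width interval and a `degenerate`
flag rather than an exception, because perfect detectors on clean data are a
legitimate and testable state. Hypothesis verdicts compare the CI lower
bound against the configured null proportions (defaults 0.90 for
sensitivity, 0.80 for specificity) and never reject through a degenerate
interval.

**Missing-data bounds** (`missingness_bounds()`) bracket the complete-case
estimates by the two extreme imputations (all missing days rated correctly
vs all incorrectly); bracketing holds by construction on the crude scale.
**Age subgroups** stratify at the stay level by age at that stay's
admission (cutoff 12 months = 365.25 days): each stay lands in exactly one
stratum, so stratum unit counts partition the full-cohort counts, at the
price that a patient readmitted across their first birthday appears in both
strata as a cluster. Multiple-testing adjustment is deliberately absent: the
two endpoints are co-primary, each compared to its own null.

**Sample-size planning** uses the one-sample normal-approximation
(chi-square-equivalent) formula without continuity correction,
$n = \lceil (z_{1-\alpha/2}\sqrt{p_0 q_0} + z_{\text{power}}\sqrt{p_1 q_1})^2
/ (p_1-p_0)^2 \rceil$. Exact binomial or continuity-corrected variants give
slightly larger $n$; the plain formula is implemented because it is the
analytically transparent one, and the planner's inputs make the choice easy
to revisit.

## The synthetic-cohort generator

`generate_cohort()` emulates the export of a patient data management system
at the structure level: per-patient demographics, stays (mean length 12
days, a quarter of patients readmitted), per-variable observation streams
(hourly vitals, daily labs), context intervals, and injected SIRS episodes
(about 0.9 per stay, mean duration 48 h, criterion involvement proportional
to a realistic alert mix, always honouring the mandatory-criterion rule — a
scenario requesting episodes driven only by heart and respiratory rate is
rejected). Age-band proportions follow a typical tertiary PICU case mix.
Episodes are injected by pushing the *held* values of the driving variables
beyond the active thresholds over the window, with exact boundary samples,
so the sample-and-hold semantics are genuinely exercised; respiratory-driven
episodes are sometimes realized through the acute-ventilation clause.
Context intervals that are not episode drivers are placed clear of injected
episodes so suppression rules cannot mask ground truth. In clean mode all
other values stay strictly within limits, which yields the key invariant
*detected state = injected windows exactly*; noisy mode crosses limits at a
configurable borderline rate. Baselines default to the midpoints of the
active threshold table, so generator and engine stay consistent if the
limits change.

All randomness derives from one mandatory seed through fixed-label
substreams (one per patient, episode set, observation block, context block),
so adding an operation never perturbs another's draws and identical
scenario + seed gives byte-identical cohorts.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: physiologic dynamics (values are threshold-relative
noise, not hemodynamics), drug effects, documentation artefacts, informative
missingness, or inter-rater adjudication. Clean-cohort perfection validates
the plumbing, not clinical performance.

The rater simulator (`simulate_rater()`) rates each truth day independently
with fixed sensitivity/specificity, optionally drawing per-stay accuracy
from a beta distribution with the stated marginal mean (`icc`), and files no
form on missing days; `inject_missingness()` masks exact rounded fractions
of each day stratum.

## Numerical conventions and test scale

All intervals are half-open `[start, end)` on numeric seconds; touching
intervals merge, and the episode closing rule merges gaps *strictly* below
24 h. Timestamps are ISO-8601 on one timezone-naive clock — the data come
from a single site, and a uniform clock avoids daylight-saving ambiguity in
day labelling. Unit conversion is out of scope (units are fixed per
variable in the schema); conversion belongs to the ETL layer.

The test suite checks the interval machinery against minute-grid pointwise
brute force (200 random stays for criterion evaluation, 200 for episode
building and day labelling), the combination rule against the exhaustive
16-subset table, the GEE against an independent root-find and direct matrix
algebra (50 random clustered datasets), rater recovery and CI coverage over
500 replicates of a study-sized cohort (~2,500 patient-days, 168 patients),
and end-to-end perfection on noise-free cohorts at the full default size.
These sizes were chosen to give stable Monte-Carlo assertions at interactive
runtimes.

## Known limitations

* Greedy episode matching is not a maximum-cardinality assignment (see
  above); the matching window specification alone does not determine the
  assignment, and greedy-nearest is the documented choice.
* The exchangeable working correlation is a working assumption; the
  sandwich variance protects the intervals against its misspecification but
  small numbers of clusters (< ~40) will undercover slightly.
* Debouncing of single-instant threshold crossings is handled only through
  the episode minimum-duration parameter, not inside the rule engine.
* Borderline-value behaviour, per-patient baselines and fuzzy boundaries
  are out of scope; the engine is deliberately a faithful, crisp reading of
  the consensus criteria.
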