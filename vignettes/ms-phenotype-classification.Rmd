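---
title: "Classifying the current MS phenotype from the latest EDSS score and age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the current MS phenotype from the latest EDSS score and age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msclassify)
```

## The problem

Most people with multiple sclerosis present with a relapsing–remitting (RR)
course and, typically after two decades or more, transition to a secondary
progressive (SP) phase of steady disability accrual.  The distinction
matters clinically — most disease-modifying therapies are indicated in the
RR phase — and methodologically, because research cohorts need comparable
phenotype definitions.  Yet the SP label is usually assigned
retrospectively by a neurologist, with well-known between-rater and
between-registry variability.

`msclassify` implements a transparent rule-based alternative: a nine-leaf
binary decision tree over just two inputs, the most recent EDSS score and
the age at that assessment, each leaf carrying a probability of SPMS.  The
package also contains the machinery to *rebuild* such a tree from labelled
data, a longitudinal confirmed-progression detector to compare against, the
usual diagnostic-accuracy and time-to-event comparisons, and a synthetic
registry simulator so all of it can be exercised without patient-level data
access (registry data of this kind are only available under data-transfer
agreements).

## The rule-table classifier

`classify_ms()` is a deterministic lookup into the table returned by
`sp_rules()`.  Three conventions deserve note:

* **Age bands are half-open.**  The printed bands "<56", "56–64" and "⩾64"
  are implemented as [0, 56), [56, 64) and [64, ∞) — the only reading under
  which they are disjoint; likewise "<45"/"⩾45" split exactly at 45.  Ages
  at exactly 56 or 64 therefore fall into the older band.  Because the
  source table does not state its convention, behaviour *at* these exact
  boundary ages should be treated as convention-dependent; everywhere else
  the mapping is unambiguous.
* **Ages are real-valued.**  Bands apply to the exact fractional age
  computed with a 365.25-day year.  `floor_age = TRUE` truncates to whole
  years first, for registries that store integer ages.
* **EDSS membership is exact.**  Leaves are defined by membership on the
  0.5-point grid (no interpolation); 0.5 itself is rejected because the
  scale has no such step (a permissive flag exists for foreign registries).

The label is SP exactly when the leaf probability exceeds 0.5, which holds
row-by-row in the table.  The test suite sweeps all 21 valid EDSS values ×
ages 0–100 and checks that exactly one rule fires and that probabilities are
monotone in both inputs.

## The CART trainer

`fit_sp_tree()` re-implements the methodology behind the rule table rather
than wrapping an existing tree package (the independent `rpart`
implementation is used as a cross-check oracle in the tests, never as the
engine).  Design choices:

* **Impurity: Gini**, the standard default for binary classification trees.
  Splits are greedy; candidate thresholds are midpoints between consecutive
  distinct sorted feature values; records with missing features are
  rejected rather than routed through surrogate splits (the intended data
  are complete-case registry extracts).
* **Stopping:** nodes smaller than `min_node_size` (default 20) are not
  split, children smaller than `min_bucket` (default `round(min_node_size/3)`,
  i.e. 7 — matching the rpart convention, which matters for the oracle
  comparison) are not created, and growth stops at purity or depth 30.
  Zero-improvement splits *are* admitted during growth: a split can be
  uninformative on its own yet enable informative children (checkerboard
  patterns); pruning removes such splits unless their subtree pays for
  itself.
* **Pruning:** weakest-link cost-complexity pruning on the impurity risk.
  The complexity parameter is expressed relative to the root impurity, so a
  split survives `cp` only if its (subtree-adjusted) improvement exceeds
  `cp` × root risk.  Pruned trees are nested in `cp`; `cp = 0` keeps the
  full tree and `cp = 1` always collapses to the root.
* **Choosing `cp`:** with `cp = "auto"`, stratified k-fold cross-validation
  (default 10 folds) is run over the pruning sequence of the full-data tree;
  candidate values are geometric means of consecutive collapse thresholds
  (thinned to at most 64 for very large trees).  The selected `cp` minimises
  the mean cross-validated misclassification error, with exact ties broken
  toward the larger `cp` — the simpler tree.  Both routes used in practice
  are exposed: `cp = "auto"` and a fixed small value such as `cp = 1e-4`.
  Note that minimum-CV-error selection, unlike the one-standard-error rule
  (deliberately not implemented), retains a modest chance of keeping a few
  spurious splits on pure-noise data; on signal-bearing data the two agree
  for all practical purposes.
* **Determinism:** tie-breaks are fixed (larger improvement, then smaller
  threshold, then feature order) and the fold assignment derives from an
  explicit seed, so identical inputs give identical trees and CV tables.

On cohorts of 10,000 simulated patients labelled by the rule table plus 5%
label noise, the cross-validated trainer recovers the rule partition: age
thresholds within ±2 years of 45, 56 and 64, EDSS cuts in each of the
intervals (3, 3.5], (3.5, 4], (4, 4.5] and (6, 6.5], ≥95% agreement with
the noiseless rule labels, and EDSS importance exceeding age importance.
This parameter-recovery simulation is the package's stand-in for the
original registry accuracies, which cannot be reproduced without the
registry data.

## The longitudinal MSBase-style detector

`detect_conversion()` scans a patient's visit sequence for confirmed EDSS
progression: an increase from baseline of at least 1.0 point (0.5 when the
baseline EDSS is 6 or more), reaching at least EDSS 4, at a relapse-free
visit, confirmed by a later relapse-free visit at least 91 days (three
months) after the event with all intervening relapse-free visits staying at
or above the progressed level.  Decisions taken where the published
description is silent:

* **Roving baseline** (default): the reference EDSS is the lowest score at
  any relapse-free visit so far, so remissions re-anchor the comparison; a
  fixed first-visit baseline is available (`baseline = "fixed"`).
* **Band selection uses the baseline EDSS** ("patients with an EDSS < 6" is
  ambiguous between baseline and event level; baseline was chosen and the
  alternative can be emulated by adjusting thresholds).
* **Relapse-free** means no relapse within 30 days before or after the
  visit (no window is stated in the source; configurable).
* **The conversion date is the event date**, not the confirmation date —
  the detector's purpose is earlier identification.
* **The pyramidal FS criterion is skipped** (treated as satisfied) by
  default, since most registries lack FS sub-scores.  With
  `require_pyramidal_fs = TRUE` and no FS column present, a loud warning is
  emitted and no patient can convert.

Patients with fewer than two visits carry no longitudinal information and
are labelled RR with an explicit `no_longitudinal_data` flag.

## Evaluation conventions

`confusion_metrics()` uses RR as the default positive class (the convention
of the benchmark comparisons this package mirrors; a flag flips it — and
flipping exactly swaps sensitivity↔specificity and PPV↔NPV).  Binomial 95%
confidence intervals use the Wilson score interval by default (better
small-sample behaviour than the Wald interval, which is available for
comparison).  Metrics with empty denominators are reported as missing with
a reason rather than as 0/0.

Kaplan–Meier estimation (`km_curve()`) delegates to the `survival` package:
product-limit estimates, Greenwood variance with log-transformed confidence
bands, and the median with its Brookmeyer–Crowley-style interval.  The
median is the first time the curve reaches 0.5 or below, reported as
missing ("not reached") when it never does.

`compare_time_to_sp()` compares the time to SP — from birth (age at
conversion) and from symptom onset — across three labellers: the clinical
labels (SP transition dates), the MSBase detector (event dates), and the
cross-sectional tree.  The tree outputs a status, not a date; its event
date is taken as the earliest visit at which the classifier returns SP.
That convention is a package choice (the source analysis does not state
one) and tends to time tree conversions earlier than confirmed-progression
definitions.  Non-converters are censored at their last visit.

## The synthetic registry simulator

`simulate_cohort()` generates the study conditions every other module is
tested under.  Its defaults are calibrated once to the marginal structure
of a large national MS registry and are not meant to be tuned per analysis:

* **Demographics:** 71.4% female; onset age normal with mean 32.4 and SD
  10.2 years, truncated to 5–70.  Truncation would bias the mean upward by
  about 0.1 years, so the generator solves for the location parameter whose
  *truncated* mean equals the configured target — the configured value is
  the true population mean.
* **Follow-up:** disease duration at the last visit is log-normal with
  median 14 years (sdlog 0.6, truncated 1–50); visits occur at
  exponential-gap intervals with mean 1 year (floored at one month).
* **Left truncation:** the observed record starts at registry entry,
  uniform on [0, 0.75] of the disease duration.  This is a deliberate and
  load-bearing realism feature: patients enrolled mid-disease contribute
  visit histories that begin at an already-elevated EDSS, which is exactly
  the stratum a cross-sectional classifier can call SP but a
  confirmed-progression detector cannot (no observable increase), and the
  reason longitudinal definitions miss SP patients whose progression
  predates their record.
* **SP transition:** latent time from onset is log-normal with median 25
  years (sdlog 0.7; `Inf` disables transitions).  A patient is clinically
  SP exactly when the transition precedes the last visit; the transition
  date is the clinical `sp_date`.
* **EDSS process:** during the RR phase, an Ornstein–Uhlenbeck walk (exact
  discretisation; reversion 0.25/year, diffusion 0.2 points/√year) around a
  per-patient attractor.  The attractor is 1.75 times a log-normal severity
  factor (sdlog 0.55) — between-patient severity heterogeneity that yields
  the stable minority of high-disability RR patients seen in registries —
  and is raised permanently by relapse residuals (exponential, mean 0.15
  points per relapse).  After the SP transition the process drifts upward
  at 0.35 points/year with a soft ratchet.  Scores are snapped to the valid
  EDSS grid and capped at 10; visits within 30 days after a relapse carry a
  transient +1.0 elevation.
* **Relapses:** an inhomogeneous Poisson process during the RR phase, rate
  0.35/year at onset decaying with an 8-year e-folding time; only relapses
  inside the observed record are "registered".

With these defaults the simulated Table-of-characteristics matches the
calibration targets where they are targeted (onset age, sex ratio, median
duration, RR-median EDSS 1.5 with IQR 1.0–3.0) and is qualitatively right
elsewhere (SP fraction ≈ 27% versus 32%, SP-median EDSS ≈ 5 versus 6.5).
What the simulator does **not** emulate: treatment effects, secular/era
differences between registries, registry missingness and measurement-error
patterns, onset-age–dependent transition hazards (the joint dependence is
not identifiable from published marginals and is chosen for plausibility),
and FS sub-scores.  Passing tests on simulated cohorts therefore
demonstrate the *internal* correctness and the qualitative behaviour of the
methods, not their accuracy on any real registry.

## Problem sizes and numerical choices

The test suite exercises the exhaustive rule sweep (21 EDSS values × 101
ages), oracle comparisons on instances of ≤ 200 records, parameter recovery
and simulator calibration on one shared cohort of 10,000 patients, the KM
median recovery on the same cohort, and 1,000-replicate brute-force checks
of the confusion metrics — sizes chosen to give sampling error well inside
the asserted tolerances while keeping a full run in the low minutes.
Floating-point comparisons use small absolute tolerances (1e-10 scale) for
split improvements and collapse thresholds; EDSS values are compared via
integer half-points to avoid grid round-off.

## Known limitations

* The classifier is cross-sectional by design; its errors concentrate in
  stable long-duration RR patients with high EDSS and in recently
  transitioned SP patients with low EDSS — visible in
  `misclassification_profile()` on simulated cohorts.
* Boundary ages 56 and 64 are convention-dependent (above).
* The trainer handles exactly two classes and complete cases; no surrogate
  splits, no one-standard-error pruning rule.
* The simulator's defaults encode one plausible generative story matching
  published marginals; conclusions sensitive to its joint structure should
  be re-checked under perturbed configurations.
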