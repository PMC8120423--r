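---
title: "Predicting sustained hypoglycemia from CGM traces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting sustained hypoglycemia from CGM traces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hypoalert)
```

## The problem

Continuous glucose monitors (CGM) sample interstitial glucose roughly every
5 minutes. Predictive low-glucose alerts warn the wearer some minutes before
glucose falls below the hypoglycemic threshold of 70 mg/dL, but naive
predictors suffer crippling false-alert rates: hypoglycemic readings are rare
(a few percent of all readings), so even a specific model issues far more
false than true alarms, and alarm fatigue erodes trust.

`hypoalert` implements a pipeline built around one idea: alert on *sustained*
hypoglycemia — at least 15 minutes (three consecutive 5-minute readings)
below 70 mg/dL — rather than on every sub-threshold dip. Short transient
dips of one or two readings often reflect sensor noise or a self-correcting
wobble; they carry little clinical urgency and, being noise-like, are close
to unpredictable. Focusing the positive class on sustained events gives the
model a stable pattern to learn and cuts the false-alert rate.

## Event model

A *hypoglycemic event* is a maximal run of consecutive readings strictly
below the threshold, ended by a reading at or above it. "Consecutive" is
taken on the 5-minute grid: a sensor gap terminates a run, because the event
definition cannot span unobserved time (the original analyses did not state
how gap-interrupted events were handled; terminating at the gap is this
package's documented choice). Events of at least 15 minutes are `sustained`,
shorter ones `transient`. A reading of exactly 70 mg/dL is never part of an
event.

## Prediction methods

Both methods consume the same predictor rows, built at every observed grid
point from the trailing 4 hours of CGM data plus calendar context
(`extract_features()`): current and lagged glucose (5-240 min), short-window
first differences, rolling mean/sd/min/max (30/60/240 min), "snowball"
statistics of the current monotone run (length and cumulative change of
consecutive same-sign differences), two interaction terms (glucose x 15-min
slope, 60-min rolling sd x 15-min slope), hour of day as a sine/cosine pair,
and ordinal day of week. Optional demographics (age, HbA1c, diabetes
duration) are off by default: the headline model uses only CGM history and
calendar context. Rows whose 4-hour window touches a gap are dropped — a
feature that depends on an unobserved reading is never imputed.

**Method 1 — direct classification.** A probability random forest
(`ranger`) is trained on labeled decision instances; an alert is issued when
the positive-class probability reaches `prob_threshold` (ties alert).

**Method 2 — multistep quantile-forest forecasting.** One quantile
regression forest per 5-minute step of the prediction horizon (6 forests for
30 min, 12 for 60 min; direct strategy, not recursive, so errors do not
compound and each step is independently testable). An alert is issued when
at least `min_consecutive = 3` consecutive predicted values fall below
70 mg/dL — the forecast-space mirror of the sustained-event definition.

### Labeling

A decision instance at time `t` (current glucose at or above threshold;
alerts during an ongoing event are not predictive and those instances are
excluded) is positive when a sustained event starts within
`(t, t + PH - (min_consecutive - 1) * 5]` minutes. The shortened window is
deliberate: for an onset in the last two grid steps of the horizon, fewer
than three of the event's sub-70 readings fall inside the horizon, so even a
perfect forecaster cannot satisfy the consecutive-prediction rule — such
instances would be unconditionally unwinnable and would only obscure the
measurement. With `min_consecutive = 1` (the all-events target) the window
reduces to the plain `(t, t + PH]`.

### Operating quantile

The package default is the lower quartile (`quantile = 0.25`) of each step's
conditional distribution, not the median. Two reasons. First, the alert rule
requires several *consecutive* sub-threshold step quantiles; marginal
quantiles ignore the positive dependence between neighboring steps, and
under onset-timing uncertainty the median systematically misses the earliest
detectable instances (the forecast crosses the threshold one step late).
Second, for a low-glucose alarm the lower tail of predicted glucose is the
clinically relevant statistic — quantile forests are used precisely because
accuracy near the hypoglycemic range matters more than average accuracy.
`quantile` is a plain argument; `sweep_operating_points()` evaluates
alternatives (quantile, glucose cutoff, or probability threshold) along a
sweep with the expected monotone trade-off.

### Forest settings

200 trees per forest and a minimum node size of 5 throughout; `mtry`
follows the classic conventions — a third of the predictors for the
regression (QRF) forests, the square root for the classifier. Training
subsamples at most `max_train_rows = 20000` rows (seed-derived draw) so
fitting time stays flat in cohort size; forests saturate well below that.
Fitting is bit-reproducible for a fixed seed (sub-seeds are derived
deterministically per step/replication, and the R RNG is re-seeded before
each forest because `ranger` draws from it in the quantile-regression path).

## Evaluation

All four confusion cells are counted at the level of 5-minute decision
instances. False positives are split by what the alert's horizon actually
contained: a transient onset (`fp_transient`) or no hypoglycemic onset at
all (`fp_nonhypo`). The false alert rate — the share of issued alerts not
followed by the targeted event class — is reported in both accountings:
variant A, `100 * fp / (tp + fp)`, and variant B,
`100 * fp_nonhypo / (tp + fp_nonhypo)`; variant B can never exceed variant
A. Zero denominators yield `NA`, never 0. Event-level results appear only in
the lead-time summary: an event counts as detected when at least one
true-positive instance targets it, and its lead time is the interval from
the earliest such decision time to onset (alerts at or after onset do not
count). No alert debouncing is applied by default — every instance is
evaluated — since no merging rule is part of the reference procedure.

## Validation strategies

*Patient-based*: `n_train` patients are drawn uniformly for training and the
rest validate, replicated (default 5 times) with independent derived seeds;
reported as mean and sample (n-1) SD per metric, replications without
positive validation instances excluded from the SD. This probes
generalization to new people. *Time-based*: per patient, the first 70% of
readings train and the last 30% validate; validation instances are pooled
across patients (a per-patient breakdown is also emitted) — "average
performance over all patients" is ambiguous between pooling and
mean-of-patients, and pooling was chosen; the per-patient table lets a
reader do the other. A validation row may use pre-boundary readings as
backward lags (as deployment would), but no training row's label window or
forecast target may cross the boundary — training rows closer than one
horizon to the boundary are excluded, and a leakage audit (patient
disjointness, strict chronology) runs on every call.

## The synthetic cohort generator

No patient data ship with the package; `simulate_cohort()` generates the
study conditions end to end. Ambient glucose is a mean-reverting
(Ornstein-Uhlenbeck) deviation around a circadian baseline (default mean
140 mg/dL, amplitude 25, nadir near 04:00; reversion 0.003/min and
volatility 3.1 mg/dL per sqrt-minute give a stationary SD of ~40 mg/dL and
5-minute increments of ~7 mg/dL — realistic autocorrelation, not metabolic
fidelity). Sensor noise (SD 2 mg/dL) is added and values are rounded to
whole mg/dL, clamped to [40, 450].

Hypoglycemic excursions are planted at `events_per_day` (default 1), with
durations drawn from the reference mix (`table2_duration_proportions()`:
22.76% of events at 1-2 readings, 77.24% at 3+; `sustained_fraction`
reweights the two blocks when a different taxonomy share is wanted). Onsets
keep a 2-hour clearance, so the configured rate is a target intensity and
the realized count falls below it when the clearance binds. Sustained
events are preceded by a *deterministic* signature: the same linear descent
from 132 mg/dL to 72 mg/dL over 30 minutes, making the impending event
identifiable from lag features — this is the study condition the recovery
tests measure against. Transient events are deliberately signature-free
noise dips (62-68 mg/dL for 1-2 readings). Ambient (non-excursion) glucose
is floored at 80 mg/dL so that, without sensor noise and gaps, every sub-70
reading belongs to a planted event and detection recovers the ground truth
exactly. Random gaps (rate 0.5/day, geometric length, mean 6 readings)
avoid planted event windows.

What this generator does *not* emulate: meal and insulin excursions,
variable descent shapes, descents that abort above the threshold,
device-specific noise spectra, or circadian event clustering. Passing the
recovery tests therefore shows the pipeline recovers a learnable planted
signal under realistic autocorrelation, noise and gaps — it does not show
field performance on real CGM data. One consequence is worth stating
plainly: because transient dips here are pure noise, a pipeline retargeted
at *all* hypoglycemic events simply misses them (losing sensitivity) rather
than chasing them (losing precision), so the false-alert-rate gap between
an all-events model and the sustained-focus model is much smaller in this
synthetic world than on real data, where shallow and aborted descents
attract false alerts that the consecutive-prediction rule suppresses.

## Numerical conventions and degenerate inputs

Reported percentages are rounded half away from zero to two decimals
(`round_half_up()`); internal arithmetic is unrounded. Timestamps are
UTC; raw CSV timestamps snap to the per-patient 5-minute lattice within a
±90 s jitter tolerance, farther-off readings are aligned to the nearest
whole grid step (keeping the grid invariant) and counted in the ingest log,
and grid collisions keep the earlier reading. Empty traces yield empty
event lists; zero-event statistics report `NA` percentages; single-class
training sets and sub-minimum training sizes are errors naming the problem;
forecasts shorter than `min_consecutive` are errors. The probability-
threshold tie rule is "alert at equality".

## Problem sizes used in the checks

The test suite exercises the full pipeline at 20 patients x 30 days
(~170,000 readings, ~600 planted events) for the recovery checks, and
smaller cohorts (3-6 patients, 6-10 days) elsewhere; oracle-equivalence
suites run 1,000 random traces for event detection, 2,000 instances for
confusion accounting and 10,000 vectors for the alert rule. These sizes
were chosen so the whole suite runs comfortably on a single CPU while
keeping hundreds of events in the recovery measurement.
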