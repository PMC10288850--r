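---
title: "Detecting delirium from bilateral wrist actigraphy: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting delirium from bilateral wrist actigraphy: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`actidel` turns bilateral minute-epoch actigraphy from hemiparetic stroke
patients into day-level delirium predictions. This vignette explains the
underlying models, every tunable parameter that matters, what the
synthetic cohort generator does and does not emulate, and the design
choices made where the problem was genuinely open.

## The analysis day and its parts

Delirium is rated once per day, so the unit of analysis is the patient-day.
Days are anchored at **13:00** and run to the next 13:00 (half-open), which
aligns a day's end with the afternoon assessment rating it. Within the
anchored day the chronological day parts are afternoon/evening
`[13:00, 22:00)` (540 epochs), night `[22:00, 06:00)` (480) and morning
`[06:00, 13:00)` (420); boundaries are half-open, so the 06:00 epoch is
morning and the 22:00 epoch is night. Nothing canonical fixes the order of
parts within an anchored day; the package uses the chronological order
just given and records segment membership per epoch, so downstream code
never re-derives it.

Partial data from the enrollment day is discarded
(`truncate_enrollment_day()`): device strap-on produces a large artifact
and an incomplete day, so recording effectively begins at the first 13:00
anchor at or after enrollment. Patients left without a single complete day
are flagged and excluded.

## Features

**Minutes at rest** is the fraction of *worn* epochs with PIM exactly 0 in
a window. Zeros are semantically meaningful (worn and motionless), which
drives two contracts: device-off epochs are `NA` and never imputed as 0,
and every normalization method must map 0 to 0 so the feature is
normalization-invariant.

**DTW control features.** For each day part, the paretic-arm series is
aligned against a within-patient control by dynamic time warping: local
cost is the squared difference, steps are diagonal/vertical/horizontal
with matched boundaries, and the reported distance is the square root of
the minimal accumulated cost — a minimal Euclidean distance over warpings.
Two control schemes:

* `non_paretic_arm`: the same day part of the same day's non-paretic
  series. Shared (externally mediated) movement aligns cheaply; genuinely
  unilateral patient-initiated movement does not.
* `reference_day`: the same day part of the paretic arm on the patient's
  first non-delirious day; consistently delirious patients fall back to
  their first day of data (`select_reference()`, a pure function of the
  label sequence).

Numerical choices, all recorded in function documentation: no global
warping window by default (a Sakoe–Chiba band is available via
`dtw_window`, widened automatically so the end-corner stays reachable);
tie-breaks among equal-cost predecessors prefer diagonal, then vertical,
then horizontal, which affects only the reported path length, not the
distance; distances are divided by the optimal path's step count so
windows with different missing-data loads are comparable. Missing epochs
are dropped and the series compressed before warping — deletion is the
kind of timing distortion warping tolerates. The dynamic program is
verified in the test suite against exhaustive enumeration of all monotone
boundary-matched warping paths for short sequences.

**Outlier filter** (off by default, mirroring a post-hoc sensitivity
analysis): paretic-arm epochs with PIM at or above
`median + 10 * SD` are marked missing, with both statistics computed once
per patient over all present paretic epochs and frozen before removal, so
the filter is a single deterministic pass. A constant series has zero
spread and nothing is removed.

**Clinical covariates** are age (years), sex, admission NIHSS (0–42), ICH
volume (cc), two *non-exclusive* location indicators (lobar, deep — mixed
hematomas set both), intraventricular hemorrhage, ICH score (0–6,
droppable via `include_ich_score = FALSE` since covariate lists differ on
whether to include it), and the one dynamic covariate, daily mechanical
ventilation. NIHSS enters as the raw score, unbinned.

Open points the package resolves explicitly: which channels are
normalized (both PIM and ZCM, per patient per arm; the method is a config
switch among `per_patient_max`, `per_patient_z_nonneg` — scaling by the SD
without centering, so zeros survive — and `none`, because published
descriptions of such pipelines rarely pin this down); and days without an
assessment (weekends/holidays) carry `assessed = 0` and are excluded from
the feature table by default.

A day is retained only if **every** day part has at least 80% of its
epochs present (`presence_floor = 0.8`); features that cannot be computed
stay `NA` — gradient boosting handles missingness natively.

## Classifier and evaluation protocol

The default classifier is a gradient-boosted tree ensemble with learning
rate 0.03, maximum depth 5, minimum child weight 1, subsample fraction
0.8 and column fraction 0.8; `n_estimators = 200` with no early stopping
is a package default (ensemble size is rarely reported for this kind of
pipeline and the metrics are insensitive to it in a wide range). Random
forest and SVM alternatives sit behind the same `train_classifier()`
interface with median imputation for their missing-value handling; they
are provided for comparison, not tuned.

Evaluation is repeated random subsampling: each of `n_boot` iterations
draws `floor(0.8 * n)` patients for training and holds out the rest, so
no patient contributes days to both sides (identity leakage is the main
failure mode of day-level evaluation). Per-iteration accuracy, balanced
accuracy, F1 (delirium = positive) and ROC-AUC are aggregated as
mean ± SD over iterations in which they are defined; iterations whose
training fold has a single class are skipped and counted. Iteration `k`
is seeded `seed + k`, so any single split is reproducible in isolation.
ROC-AUC is probability-ranked by default; a hard-label mode
(`auc_mode = "label"`) is also provided, under which the AUC collapses to
the balanced accuracy — a coincidence worth knowing when comparing
reports.

`run_ablation()` evaluates the seven canonical feature-set configurations
(clinical only, plus each combination of minutes at rest and the two DTW
schemes, through the full set) on **identical** split plans, so
`compare_featuresets()` can run a two-sided paired test (t by default,
Wilcoxon signed-rank as alternative) on per-iteration differences.
Caveat, by design: bootstrap iterations share patients and are not
independent samples; these p-values are descriptive, not inferential.
Feature importance is the per-feature fraction of total information gain,
averaged across iterations, with never-used features at 0.

## The synthetic cohort generator

Real bedside actigraphy of this population is not publicly available, so
the generator (`generate_cohort()`) supplies cohorts whose statistical
structure matches what the analysis needs, with defaults emulating the
published cohort summary: 39 patients; complete-day counts drawn
negative-binomial (`size 1.2, mu 7`, minimum 1 — median ≈ 5 days with a
long tail); day-level delirium prevalence 0.71; 15/39 of patients
delirious throughout, 6/39 never; the remainder fluctuate with a day
probability solved from the prevalence target (fluctuating patients with
two or more days are forced to show both labels — that is what
fluctuating means — with group counts rounded to the nearest integer).

Activity is a two-state rest/wake Markov chain per patient, shared by
both arms: by day, rest→wake 0.10/min and wake→rest 0.12/min (bouts of
~8–10 min, wake fraction ~0.45); by night (22:00–06:00), rest→wake
0.015/min and wake→rest 0.25/min (consolidated sleep, ~6% night wake).
Wake epochs draw lognormal PIM bursts (`meanlog log 120, sdlog 0.6`);
rest epochs are exactly 0. The delirium effect is **night-time sleep
fragmentation**: on labeled days the night rest→wake rate is multiplied
by `1 + 2 * effect_size` and wake→rest divided by `1 + effect_size`
(default `effect_size = 1` roughly quadruples night wake time). This
placement mirrors where nocturnal delirium symptoms live; it also means
the generator's signal is night-confined by construction, which the
importance-localization test exploits. Paretic-arm patient-initiated
bursts are multiplied by `paresis_attenuation` (default 0.3). Care events
recur every `1/care_event_rate` hours (default 0.5/h) with Gaussian
timing jitter (SD 10 min), last 4 minutes and add large unattenuated
lognormal bursts to **both** arms — the externally mediated artifact the
DTW controls are meant to cancel. Device-removal (MRI) gaps hit a day
with probability 0.15, last 60 min and make both arms missing. ZCM is
Poisson with rate `0.2 * PIM` — movement-frequency and movement-intensity
channels are strongly related in practice and no published coupling
exists to copy. All randomness flows from `rng_seed`; identical
configurations reproduce identical cohorts bit for bit.

What the generator does **not** emulate: hypoactive delirium phenotypes
(the effect only raises night activity), medication and sedation
dynamics, inter-patient differences in circadian phase, postural
artifacts, device non-linearity, or any coupling between clinical
covariates and delirium risk (covariates are drawn independently of the
label trajectory, deliberately, so evaluation-machinery calibration can
be tested). Passing tests therefore demonstrate that the pipeline
recovers a night-concentrated activity signal under realistic artifact
structure — not that real-world delirium is this separable. On real
patients the published analogue of this analysis reports day-level
accuracies near 0.74; on the default synthetic cohort the full feature
set scores far higher because the simulated effect is cleaner than
clinical reality.

## Known limitations

**The reference-day scheme is label-aware.** Its reference is chosen
using the patient's own labels during feature extraction, before any
train/test split, and the reference day's DTW features are identically 0
by self-alignment while that day is non-delirious by construction
(or day 0 under fallback). A classifier can therefore read label
information straight off the `dtw_refday_*` columns. The test suite
measures this: with the delirium effect switched off entirely, feature
sets without reference-day DTW sit within sampling error of balanced
accuracy 0.5, while the full set (including reference-day DTW) sits
above chance. Users comparing the two DTW schemes should weigh this
built-in advantage of the reference-day scheme; a leakage-free variant
would need to select references from training labels only, which is
incompatible with per-patient feature extraction preceding the split.

**Scale of the shipped checks.** The test suite and the reproduction
script run cohorts of 39–40 patients with 100–200 bootstrap iterations
and 150-iteration ablations — sizes chosen to exercise the full pipeline
at study scale while keeping a complete run in minutes on one CPU.
Conclusions about variance of the aggregate metrics at 500 iterations
scale straightforwardly but are not themselves asserted.

**Other simplifications.** Timestamps are timezone-naive local clock
time (daylight-saving transitions are out of scope); proprietary
count-derivation from raw acceleration is out of scope (ZCM/PIM are
taken as given); sleep scoring, bandpass/Savitzky–Golay filtering and
deep-learning models are deliberately excluded.
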