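# actidel

Day-level delirium detection from bilateral wrist actigraphy in
hemiparetic stroke patients.

Delirium — an acute, fluctuating disturbance of attention and awareness —
is common after intracerebral hemorrhage (ICH), but bedside screening
tools perform poorly in patients with severe neurologic deficits.
Continuous motor-activity monitoring offers an unobtrusive alternative:
wrist actigraphs record per-minute activity counts (PIM, area under the
acceleration curve; ZCM, near-zero threshold crossings) around the clock,
and psychomotor change and sleep-wake disruption are core features of
delirium. The catch on a neurocritical-care unit is that much of the
recorded movement is externally mediated (nursing care, repositioning).
`actidel` implements a within-patient-control strategy for hemiparetic
patients: the paretic arm moves little by the patient's own initiative,
so comparing it against the patient's own control streams isolates
patient-state changes from care artifact.

## The method

Each monitoring day is anchored 13:00 → 13:00 and partitioned into
afternoon/evening `[13:00, 22:00)`, night `[22:00, 06:00)` and morning
`[06:00, 13:00)`. For every patient-day the pipeline computes:

* **Minutes at rest** — the fraction of worn epochs with PIM = 0, per
  day part and arm; a proxy for psychomotor slowing and sleep-wake
  disturbance.
* **Within-patient DTW distances** — the minimal Euclidean distance
  between day-part series under dynamic time warping,

  `DTW(x, y) = sqrt( min over monotone boundary-matched paths P of
  sum over (i,j) in P of (x_i − y_j)^2 )`,

  path-length normalized. Two control schemes: the same-day *non-paretic
  arm* (whole-body versus patient-initiated movement) and the *reference
  day* — the paretic arm on the patient's first non-delirious day
  (first day of data for always-delirious patients). DTW tolerates care
  routines that recur at slightly different times each day.
* **Clinical covariates** — age, sex, admission NIHSS, ICH volume,
  location flags, intraventricular hemorrhage, ICH score, plus daily
  mechanical-ventilation status.

A gradient-boosted tree classifier (learning rate 0.03, depth 5,
min child weight 1, subsample 0.8, column fraction 0.8) predicts the
daily delirium label. Evaluation uses patient-disjoint bootstrap
iterations: each iteration holds out 20% of patients entirely, and
accuracy, balanced accuracy, F1 and ROC-AUC are reported as mean ± SD
across iterations. Seven feature-set configurations (clinical only
through the full combination) are evaluated on identical splits so the
comparisons are paired.

No epoch-level dataset of this kind is public, so the package includes a
synthetic cohort generator with the structure the analysis relies on:
circadian rest/wake alternation, paretic-arm suppression of
patient-initiated movement, care-event bursts shared by both arms,
night-time sleep fragmentation on delirium days, device-removal gaps,
and partial enrollment-day data.

## Worked example

```r
library(actidel)

cfg     <- cohort_config(n_patients = 12, rng_seed = 7)
cohort  <- generate_cohort(cfg)
cohort
#> <actidel_cohort> 12 patients, 100 complete days (61% delirious)
#>   groups: 5 always / 2 never / 5 fluctuating

features <- build_feature_table(cohort)          # 25 feature columns
result   <- bootstrap_evaluate(features, n_boot = 50, seed = 8)
result
#> <bootstrap_result> xgboost, 50 iterations (0 degenerate)
#>   accuracy           0.983 +/- 0.020
#>   balanced_accuracy  0.976 +/- 0.037
#>   f1                 0.984 +/- 0.024
#>   roc_auc            1.000 +/- 0.001

head(feature_importance(result), 3)
#> # A tibble: 3 x 2
#>   feature                  gain
#>   <chr>                   <dbl>
#> 1 rest_paretic_night     0.790
#> 2 rest_nonparetic_night  0.160
#> 3 rest_paretic_full_day  0.0294
```

The held-out metrics say the day-level label is recoverable from the
actigraph features in this synthetic cohort, and the importance ranking
localizes the signal where the generator puts it: night-time rest
fractions dominate. Absolute numbers are higher than one should expect
on real patients — the simulated delirium effect is cleaner than
clinical reality (see the methods vignette).

`run_ablation(features)` evaluates all seven feature-set configurations
on shared splits; `compare_featuresets()` tests paired metric
differences.

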