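# eareeg

Quantitative assessment of **stress and mental workload from single-channel
in-ear EEG**, as a tested, reusable R pipeline.

Wearable in-ear EEG devices record one channel at 500 Hz from electrodes in
the ear canal. They make everyday cognitive-state monitoring practical, but
analysing their data requires a chain of steps whose details matter: segment
quality control at device-specific amplitude thresholds, a compact feature
bank that works on 3 s windows, classifiers evaluated so that no subject
leaks between training and validation, and attribution methods to see which
EEG features carry the signal. `eareeg` implements that chain end to end,
together with a synthetic-data generator that emulates the recording and
protocol structure of a stress / mental-workload study, so every stage is
testable without access to human recordings.

## What it computes

* **Synthetic studies** — `generate_stress_study()` (meditation / eyes-open
  rest / cold pressor, 120 s blocks, subjective ratings 1–9) and
  `generate_workload_study()` (4 tasks x 3 difficulty levels x 5 sessions x
  10 trials of 2.5 s), with per-subject random effects, condition-dependent
  band-power shifts, artifacts, and fully seeded determinism.
* **Preprocessing** — zero-phase 1 Hz high-pass, 49 Hz low-pass and 50 Hz
  notch filtering; 3 s (or per-trial) segmentation; QC with the saturation
  (> 80 uV range), flat (< 1 uV range) and artifact (|x| > 20 uV) rules;
  class balancing by seeded downsampling.
* **Features** — the 35-feature bank: statistical moments, Hjorth
  activity/mobility/complexity, absolute/relative band powers and band RMS
  for delta–gamma, spectral edge frequencies, spectral centroid, band
  ratios (`feature_roster()` lists all names).
* **Models** — a natively implemented 35-20-10-5 rectifier network with
  sigmoid/softmax/linear heads (Adam, cross-entropy or MSE), plus logistic,
  SVM and random-forest baselines; subject-grouped 3-fold cross-validation
  (`cross_validate()`), within-subject regression
  (`subject_regressions()`), exact binomial tests against chance.
* **Attribution** — the Shapley value
  `phi_j = sum_S |S|! (p-|S|-1)!/p! (val(S u j) - val(S))` with background
  marginalization: exact enumeration for small models, a permutation
  estimator with standard errors for the 35-feature models
  (`exact_shapley()`, `sampled_shapley()`, `explain_model()`), mean-|phi|
  ranking, critical-feature selection, beeswarm data export.
* **Statistics** — Mann–Whitney U with Bonferroni tiers, Wilcoxon
  signed-rank, one-way repeated-measures ANOVA on ratings.

Results are tibbles; fitted CV objects support `tidy()`, `glance()` and
`autoplot()`.

## Worked example

```r
library(eareeg)
library(dplyr)

study <- generate_stress_study(n_subjects = 8, seed = 42)
feats <- study |>
  apply_filters() |>
  segment_recordings() |>
  qc_segments() |>
  compute_features()

lab <- assign_labels(feats, "stress_binary_med_vs_cp")
cv  <- cross_validate(lab, ann_architecture(), training_config(seed = 7),
                      cv_plan(seed = 7))
glance(cv)
#>   accuracy_mean accuracy_sd precision_mean ...
#> 1         0.898      0.0605          0.909 ...
```

The mean cross-validated accuracy of 0.90 (SD 0.06 across the three
subject-grouped folds) says that a network trained on five subjects'
meditation and cold-pressor segments classifies the held-out subjects'
segments correctly about nine times in ten — unsurprising given this
synthetic study's strong injected alpha/gamma condition effects. Feature
attribution on the first fold's model:

```r
model <- cv$models[[1]]
set.seed(1)
bg   <- lab[sample(nrow(lab), 80), ]
inst <- lab[sample(nrow(lab), 15), ]
att  <- explain_model(model, inst, bg, n_permutations = 30, seed = 3)
head(rank_features(att), 3)
#>   feature                              mean_abs_phi  rank
#> 1 Root-mean-square value, gamma band          0.146     1
#> 2 Mobility, overall signal                    0.114     2
#> 3 Root-mean-square value, theta band          0.0644    3
```

Gamma-band RMS ranks first because the cold-pressor condition raises gamma
power (with EMG-like bursts) in the generator, and mobility tracks the
resulting shift of spectral mass toward higher frequencies. The subjective
ratings separate as the protocol intends:

```r
rating_statistics(distinct(study, subject_id, condition, rating))$anova$p_value
#> 8.3e-04   (repeated-measures ANOVA across the three conditions, 8 subjects)
```

`run_pipeline(run_config(n_subjects = 8, seed = 1), "out/")` executes the
whole chain (simulate, preprocess, featurize, label, cross-validate,
explain, test) and writes QC, metric, attribution and statistics tables
plus a manifest carrying the config hash.

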