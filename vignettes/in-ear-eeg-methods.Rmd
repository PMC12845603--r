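---
title: "Methods: stress and mental-workload assessment from single-channel in-ear EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stress and mental-workload assessment from single-channel in-ear EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`eareeg` implements a complete analysis chain for quantifying stress and
mental workload from a single-channel in-ear EEG signal sampled at 500 Hz:
synthetic protocol-structured data generation, zero-phase filtering and
threshold-based quality control, a 35-feature bank, cross-subject
classification and within-subject regression under subject-grouped
cross-validation, Shapley-value feature attribution, and the protocol-level
rank and repeated-measures statistics. This vignette describes the models
and the numerical choices behind each stage.

## The synthetic data generator

Because in-ear EEG recordings of stress/workload protocols are not bundled
with the package, every stage is exercised on a generative model whose
spectral structure is controlled exactly.

**Signal model.** A recording is a sum of independent band-limited Gaussian
processes — white noise shaped by a hard frequency-domain mask over each of
the five canonical bands (delta 0.1–4, theta 4–8, alpha 8–12, beta 12–32,
gamma 32–45 Hz) — superimposed on a `1/f^0.7` pink background (0.5–48 Hz,
1.5 uV² total variance). Each band component is rescaled so that the
realized in-band variance, background included, equals
`baseline_band_power[band] * band_multipliers[band]`. This gives exact
control of the quantity the feature bank estimates; the fidelity test checks
that Welch estimates on 60 s signals recover the specified variances within
15%.

**Population and conditions.** Per-subject baseline band powers are
log-normal random effects (sdlog 0.25) around population defaults of
(5, 3, 4, 2.5, 1) uV² for delta–gamma. These defaults put the artifact-free
post-filter signal at a standard deviation near 4 uV, i.e. a typical
amplitude envelope within ±20 uV and a ≥95% pass rate under the amplitude
criterion — the regime the device's quality thresholds assume. The stress
protocol runs three 120 s blocks per subject in fixed order: meditation
(alpha ×1.5, theta ×1.15, gamma ×0.8; latent stress index 0.05), eyes-open
rest (reference; 0.45), and cold pressor (alpha ×0.7, beta ×1.3, gamma ×1.8
with a slow EMG-like amplitude modulation of the gamma component; 0.9). The
gamma burst component reflects the muscle-activity confound that accompanies
cold-induced tension in ear-level recordings. The workload protocol runs
4 tasks × 3 difficulty levels × 5 sessions × 10 trials of 2.5 s; alpha
decreases and beta increases with difficulty strongly for arithmetic,
moderately for finger tapping, weakly for lexical decision, and not at all
for mental rotation, emulating the observed stability of oscillatory power
in that task. The condition effect sizes are free parameters of the
generator, not estimates from any real dataset; `effect_scale = 0` switches
the band effects off for null-calibration studies.

**Ratings.** Each stress block yields one integer rating
`clip(round(1 + 8·stress_index + rating_bias + N(0, 0.8)), 1, 9)`. The
subject bias is N(0, 0.7); the noise standard deviation 0.8 makes
neighbouring conditions overlap at the single-subject level while keeping
the population ordering meditation < eyes-open < cold pressor.

**Artifacts.** Poisson-arriving events: motion (half-sine transients, 60 uV,
0.5 s), muscle (Hann-windowed high-frequency bursts, 30 uV, 0.3 s),
flatline, saturation rails, and continuous 50 Hz line noise. Default rates
(0.3/min motion and muscle for the stress study) contaminate a few percent
of segments so the QC stage has real work to do.

**Determinism.** All randomness derives from one integer seed through a
multiplicative derived-stream scheme; identical arguments reproduce
recordings bit for bit.

What the generator does *not* emulate: non-Gaussian waveform morphology,
non-stationary drifts, eye blinks, electrode impedance changes, circadian
effects, or any physiologically calibrated effect size. Tests passing on
this generator therefore demonstrate the correctness and sensitivity of the
pipeline, not field performance on real recordings.

## Preprocessing and quality control

The filter chain is a 1 Hz high-pass, 49 Hz low-pass (both 4th-order
Butterworth responses) and a 50 Hz biquad notch with Q = 30. The chain is
applied with zero phase by multiplying the signal's FFT with the chain's
squared magnitude response — exactly the steady-state response that a
forward–backward pass realizes, but free of warm-up transients. We chose
this realization after measuring that padded forward–backward IIR passes
leave notch-bandwidth edge transients around −20 dB RMS on finite
recordings, which would dominate the residual at the notch frequency; the
frequency-domain application leaves the 50 Hz line attenuated by far more
than 40 dB and removes DC to numerical precision.

Stress recordings are cut into non-overlapping 3 s segments (trailing
remainder discarded, no padding); each workload trial is one segment.
Segment QC assigns exactly one status with precedence
saturated > flat > artifact: peak-to-peak range above 80 uV (saturation),
below 1 uV (flat), any sample beyond ±20 uV post-filter (artifact). All
thresholds are strict inequalities, so a sample exactly at a bound is
retained. QC runs on filtered segments by default (the amplitude criterion
is defined post-filter); classes are rebalanced by seeded downsampling to
the minority count before classifier training only — regression targets are
never balanced.

## The 35-feature bank

Per segment: eight statistical/amplitude descriptors (mean, SD, skewness,
excess kurtosis, peak-to-peak, RMS, line length as the sum of absolute first
differences, zero-crossing rate); the three Hjorth parameters — activity
(variance), mobility (`sqrt(var(dx)/var(x))` with the first difference
scaled by the sampling rate, so a pure tone at `f` has mobility `2*pi*f`),
and complexity (mobility of the derivative over mobility of the signal);
absolute power, relative power, and band RMS for the five bands; RMS over
the non-gamma range 0.1–32 Hz; total power; spectral edge frequencies at
50/90/95% of the 0.1–45 Hz power; the power-weighted mean frequency
("weighted average power", interpreted as the spectral centroid since no
standard definition exists); and three band ratios (alpha/beta, theta/alpha,
beta/(alpha+theta)). The roster is a package-level constant
(`feature_roster()`) mapping stable column keys to the display names used in
reports.

Numerical choices: the PSD is a one-sided Welch estimate with 1 s Hann
windows at 50% overlap (five averages per 3 s segment) and per-window mean
removal; band integration uses the half-open convention `[lo, hi)` so the
five bands tile 0.1–45 Hz and relative powers sum to one by construction.
Band RMS uses an ideal frequency-domain band-pass of the segment. Although
the delta band is defined from 0.1 Hz, the 1 Hz high-pass means delta
content below 1 Hz is attenuated before feature extraction; the band-power
fidelity test therefore uses 4 s Welch windows, whose 0.25 Hz resolution
separates the bands cleanly. Kurtosis is reported as excess kurtosis
(Gaussian = 0). Constant segments make Hjorth mobility/complexity undefined;
they are flagged `NaN` with a warning (such segments fail QC as flat in any
case), and features are only computed for QC-passed segments.

## Models and cross-validation

The predictor is a fully connected network with a 35-unit input, hidden
layers of 20, 10 and 5 rectifier units, and a task-matched head: sigmoid
(binary, cross-entropy), softmax (three-class, cross-entropy) or linear
(regression, mean squared error), trained with Adam. The implementation is
native R matrix code so that runs are exactly seeded and the checkpoint
(weights, architecture, standardization constants) serializes to portable
JSON. Training hyperparameters are fixed package defaults — 200 epochs,
learning rate 1e-3, batch size 32, no early stopping — chosen once as
ordinary values for a network of this size on a few thousand instances.
Features are z-scored with training-split statistics only; the constants
travel with the model. Logistic regression, an RBF support-vector machine
and a random forest are available as thin baseline adapters around the
standard implementations.

Cross-subject evaluation uses a subject-grouped shuffle split: subjects are
shuffled by seed and partitioned into three disjoint groups, so no subject
contributes segments to both training and validation in any fold.
Within-subject regression uses a three-fold split of the subject's segments.
Class balancing and standardization happen inside each training split. The
leakage canary test formalizes this: a feature equal to the label, injected
only into validation rows, must leave validation accuracy at chance (it
does; the same canary leaked into training rows drives accuracy to 1, which
is the positive control for the test's sensitivity). Alongside fold
mean ± SD, the per-subject *best fold* R² is reported as a separate mode —
this mirrors a common reporting convention but is upward-biased relative to
the mean across folds, and should be read with that caveat.

## Shapley-value attribution

The value function `val(S)` for an instance fixes the features in coalition
`S` at the instance's values and marginalizes the rest over a background
sample (default 100 training rows drawn with a fixed seed): each background
row supplies the out-of-coalition values, and `val(S)` is the mean model
output (the pre-threshold sigmoid probability for classifiers). Exact
attribution enumerates all `2^p` coalitions (refused above 12 features) and
satisfies the efficiency, symmetry and dummy axioms to numerical precision.
For the full 35-feature models a permutation estimator is used: each
sampled permutation inserts features in order and credits each feature with
the value change its insertion causes; this is unbiased, satisfies
efficiency exactly per permutation by telescoping, and reports a per-feature
Monte-Carlo standard error. Feature importance is the mean absolute
attribution over instances, with ties broken by the stable roster order;
"critical features" are those appearing in at least 7 of the per-task,
per-fold top-10 lists. Because band features are strongly correlated
(band RMS and relative power of the same band carry overlapping
information), attribution credit for an injected band-power effect can
concentrate on either representation of that band.

## Protocol statistics

Pairwise condition comparisons of the subjective ratings use the two-sided
Mann–Whitney U test (exact when the combined sample is below 40 and
tie-free, continuity-corrected normal approximation otherwise), tiered at
the Bonferroni-corrected thresholds for family levels 0.05 (`*`) and 0.01
(`**`) — with three comparisons, 0.017 and 0.0033. The rating trend across
all three conditions uses a one-way repeated-measures ANOVA with subject as
the blocking factor; no sphericity correction is applied by default, and a
Greenhouse–Geisser option is available. Intra-subject feature variation
across difficulty levels uses the Wilcoxon signed-rank test on subjects'
mean feature values, with zero differences removed and the all-tied case
degenerating to p = 1. Both rank tests are calibrated: their simulated
type-I rates at the 0.05 level sit within 0.05 ± 0.01 under a shared
Gaussian null.

## Problem sizes and study design of the shipped analyses

The packaged analyses run at desk scale, chosen as the package's standard
demonstration sizes: the acceptance computation simulates 16 stress
subjects (48 two-minute blocks, about 1 900 segments) and 8 workload
subjects (4 800 trials); the recovery study uses 20 subjects with two
120 s blocks each; null calibration uses 12 effect-free subjects and 5 000
simulated rank tests. These are large enough for stable fold metrics and
calibrated error rates while keeping a full run in minutes on one CPU.

## Known limitations

* The generator's condition effects are stylized; accuracies obtained on it
  characterize the pipeline, not the device or any human population.
* Single-channel input rules out spatial artifact correction (no ICA or
  reference regression); QC is threshold-based exclusion only.
* The Welch-based band powers at 1 s windows underestimate delta power on
  3 s segments (resolution and the 1 Hz high-pass); this bias is common to
  every segment and class, so it does not distort classification, but
  absolute delta power values should not be compared across different
  window settings.
* Three-class stress classification is markedly harder than the binary
  problems whenever the two low-stress conditions are spectrally similar;
  the three-class accuracy is reported for completeness.
* Best-fold regression summaries are optimistic by construction; the fold
  table gives the unbiased view.
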