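---
title: "Methods: MET estimation from skeletal velocities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MET estimation from skeletal velocities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kinemet)
```

## The problem and the model

`kinemet` estimates the energy expenditure of treadmill activities —
standing, walking, running — from depth-camera skeleton sequences, in MET
units (1 MET = 1 kcal·kg⁻¹·h⁻¹, the resting metabolic rate). The premise is
kinematic: the velocity of a person's joints carries most of the information
about how hard they are working, so a compact velocity feature vector can be
regressed onto calorimeter-grade MET values.

The pipeline has five stages, each exposed as ordinary functions:

1. **Re-referencing** (`recenter()`): every frame is translated so the
   shoulder-centre joint sits at the origin. This removes the
   camera-relative position of the body — including the fore–aft drift of
   treadmill locomotion — while preserving all inter-joint geometry. The
   translation is per frame, using that frame's own shoulder-centre
   position.
2. **Denoising** (`smooth_sequence()`): a five-point centred moving average
   per joint and axis. Skeletal tracking jitter is approximately white at
   30 Hz, and a 5-point mean cuts its variance five-fold while attenuating
   a 1 Hz gait fundamental by under 5%.
3. **Steady-state trimming** (`trim_steady_state()`): oxygen kinetics take
   minutes to stabilise after a workload change, so the first 3 minutes of
   each 5-minute bout are discarded and the following 2 minutes analysed.
4. **Features** (`select_joints()`, `joint_velocities()`): finite-difference
   velocities of the six left-side joints (shoulder, elbow, wrist, hip,
   knee, ankle — treadmill gait is near left-right symmetric, so one side
   suffices) give 18 features per frame pair. Optionally, PCA
   (`fit_pca()`) retains the leading components covering at least 90% of
   the training variance.
5. **Classification and regression**: one-against-all RBF SVMs label each
   frame pair; MET regressors are trained per activity and dispatched by
   the classifier (`hierarchical_predict()`), or as a single general model.

Errors are reported as MAE, MSE and RMSE under 10-fold cross-validation.

## The synthetic data generator

No public dataset pairs Kinect-class skeleton streams with breath-by-breath
calorimetry, so the package generates its own data with known structure.
The generator is first-class, tested code, not a fixture: every statistical
property the downstream stages rely on is a deliberate, documented choice.

**Cohort** (`sample_cohort()`): anthropometrics are truncated normals with
defaults matching a young-adult treadmill cohort — 21 subjects (10 male,
11 female), weight 60.20 ± 7.60 kg, age 21.90 ± 1.55 y, body fat
20.69 ± 7.37%. Truncation bounds are broad physiological limits (weight
35–150 kg, age 16–90 y, body fat 3–60%); for body fat the lower bound sits
2.4 SD below the mean, so the realised mean is analytically ~0.17 points
above the nominal one — tests compare against the truncated-normal moment.

**Protocol** (`default_protocol()`): six bouts — standing, walking at
4.8/5.6/6.4 km/h, running at 8.0/8.3 km/h — of 5 minutes each, with 5- and
10-minute rests bookkept after moderate and vigorous bouts. Three camera
views: side (yaw 90°), rear-side (45°), rear (0°), each 0.9 m high and 2 m
from the subject. `n_subjects` and `duration` scale the protocol without
changing its structure.

**Kinematics** (`motion_params()`, `generate_sequence()`): a static
20-joint standing pose is animated by sinusoidal limb oscillation at the
stride frequency `f = 0.5 + 0.1·v` Hz (v in km/h; ≈1.0 Hz at 4.8 km/h,
≈1.3 Hz at 8 km/h, in the physiological range). Modelling choices, fixed
once and not revisited:

* contralateral limbs oscillate in counter-phase; arms counter-swing
  against the ipsilateral leg;
* phase lags grow proximal-to-distal along each limb (ankle 0, knee 0.6,
  hip 1.2 rad), so the 18-dimensional velocity vector never collapses to
  zero mid-cycle, as in real gait;
* amplitudes scale with speed (`0.6 + 0.08·v`) and running multiplies them
  by 1.5, reflecting its longer stride and higher limb excursion;
* a whole-body vertical bounce runs at twice the stride frequency (the two
  steps per stride), and a slow sinusoidal fore–aft drift (0.05 m at
  0.05 Hz) emulates imperfect station-keeping on the belt;
* standing is the static pose plus slow postural sway; sensor noise is
  i.i.d. Gaussian per coordinate (default SD 5 mm, typical of skeletal
  tracking jitter).

**Metabolic ground truth** (`met_params()`, `met_ground_truth()`): the
speed-to-MET map uses the standard ambulation oxygen-cost relations with v
in m/min — walking `(0.1·v + 3.5)/3.5` MET, running `(0.2·v + 3.5)/3.5`
MET — and quiet standing at 1.3 MET. These are citable physiological
stand-ins chosen because they are monotone in speed and keep standing <
walking < running for every subject. A per-subject Gaussian offset (SD
0.2 MET) models between-subject metabolic variation; each simulated breath
(every 3 s) adds Gaussian noise (SD 0.1 MET). Those SDs give the
within/between-subject spread the regression stages need without being
claims about any particular cohort.

**Randomness**: one root seed is split hierarchically into streams keyed by
subject, bout and view, so regenerating with an extra bout or view never
perturbs existing sequences, and everything is bit-reproducible.

**What the generator does not emulate** — and hence what passing tests do
and do not show: the gait model is sinusoidal, not biomechanically
validated (no stance/swing asymmetry, no ground-reaction dynamics, no
inter-stride variability); tracking noise is white and Gaussian, whereas
real skeletal trackers produce occasional gross outliers and dropped
frames; MET levels follow a smooth population relation rather than
individual physiology. Results on synthetic data demonstrate that the
pipeline is correct and that its qualitative behaviour (separability of
activities, benefit of activity-specific routing) emerges under realistic
signal-to-noise ratios — they are not error estimates for real recordings.

## Numerical and design choices

* **Smoothing boundaries**: the first and last two frames, whose 5-point
  window is incomplete, are dropped rather than padded — padding would
  invent data, and 4 frames of a 3600-frame window are negligible.
* **Trim window**: frames with `t − t₀ ∈ [discard, discard + keep)` are
  kept; the half-open-from-above convention matches the sampling grid (a
  5-minute bout at 30 Hz yields exactly 3600 retained frames). The span
  precondition allows 1 s of slack so the frames consumed by smoothing do
  not disqualify a nominally sufficient bout.
* **Order of operations**: recenter → smooth → trim. Re-centring and
  smoothing are both per-axis affine maps, so they commute on the common
  frame grid; the order only affects the boundary frames.
* **Velocity denominators** use actual timestamp differences, not an
  assumed 1/30 s, tolerating frame jitter. Duplicate timestamps are an
  error, never a division by zero.
* **Standardisation**: features are z-scored with training statistics
  before PCA, SVM and neural training — RBF kernels and logistic units
  need comparable scales. Within cross-validation, standardisation and PCA
  are fitted on the training folds only.
* **PCA within CV**: fitting per training fold avoids leakage; retained
  counts may therefore vary by a component between folds, which is
  reported, not hidden.
* **SVM hyperparameters**: C = 1 and γ = 1/(n_features · mean feature
  variance) (= 1/18 after standardisation) — the conventional defaults —
  both exposed. Exact decision-value ties are broken by the fixed class
  order standing < walking < running, with a warning.
* **Classification granularity** is the frame pair; `majority_label()`
  aggregates to a bout when wanted.
* **MLP**: three hidden layers, logistic activations, linear output.
  Width defaults to 70 after the node sweep (`sweep_mlp_nodes()` re-derives
  it on any dataset over candidates 10…90; ties go to the smaller width).
  Training is mini-batch Adam (lr 1e-3, batch 64, ≤ 200 epochs) with early
  stopping on a 10% validation split; inputs and targets are standardised
  internally and the fit is bit-reproducible per seed.
* **CNN**: the "length-3 kernels on an 18×1 input" reading is the only one
  consistent with the input shape — convolutions run along the 18-long
  feature axis with same-padding, pooling windows are length 2, filter
  counts default to 16 and 32, and the dense head is two 16-unit layers.
  The CNN requires the full 18-wide input; with-PCA runs must explicitly
  request zero-padding back to 18 (`pad_pca = TRUE`), which the experiment
  harness does for its with-PCA CNN cells.
* **MET targets per frame** use previous-breath step interpolation, since
  calorimetry reports per breath and a breath value holds until the next.
* **Routing defaults** (`default_routing()`): standing → CNN on the rear
  view, walking → CNN on the side view, running → MLP on the rear view;
  the classifier reads the side view (the most accurate one). All
  configurable, as the per-activity optimum is data-dependent.
* **CV unit**: rows (frame pairs), stratified by activity. Frame-level CV
  mixes subjects across folds; subject-wise grouping is the stricter design
  and can be had by filtering `meta$subject_id` before calling
  `kfold_cv()`.
* **Fold-averaged reports** define RMSE as √(mean per-fold MSE), so the
  RMSE = √MSE identity holds exactly for averaged reports and MAE ≤ RMSE
  follows from Jensen's inequality. `validate_report()` asserts both on
  every emitted table. Rendered tables round to 2 decimals; CSV outputs
  keep full precision.

## Problem sizes

The shipped tests and examples run the generator at reduced scale — 3–4
subjects, 30-second steady-state windows, feature sets thinned to 4000–5000
rows, neural nets at ≤ 60 epochs — sizes chosen so the full suite exercises
every stage, including 10-fold SVM cross-validation and the
classify-then-route comparison, in well under a minute of training per
model while leaving the statistical conclusions unchanged. The full
protocol (21 subjects, 5-minute bouts, three views) is the default of
`default_protocol()` and runs unchanged, just longer.

## Known limitations

* The simulator's gait is a harmonic caricature; classifiers trained on it
  will not transfer to real skeletal streams.
* Per-frame-pair classification ignores temporal context; sequence models
  are out of scope.
* Camera-to-camera coordinate transfer (training on one view, predicting
  on another) is not attempted.
* No significance testing between experiment cells is performed; reported
  differences are point estimates under the configured seeds.
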