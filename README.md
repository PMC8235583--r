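# kinemet

Energy-expenditure (EE) estimation from depth-camera skeletal kinematics.

People quantify physical activity in **METs** (metabolic equivalents of
task; 1 MET = 1 kcal·kg⁻¹·h⁻¹), conventionally measured with portable
indirect calorimeters that require a face mask — impractical for everyday
monitoring. `kinemet` implements a contact-free alternative: a depth camera
(Kinect-class, 30 Hz) tracks 20 skeletal joints while a subject stands,
walks or runs on a treadmill, and the package estimates the MET trace from
joint velocities alone.

The pipeline:

1. **Preprocessing** — each frame is re-referenced to the shoulder centre
   (`xᵢ′ = xᵢ − xᵣ`, removing camera-relative body motion), denoised with a
   five-point centred moving average, and trimmed to the steady-state window
   (discard 3 min, keep 2 min).
2. **Features** — per-frame velocities
   `v_k = (p*_k − p*_{k−1}) / (t_k − t_{k−1})` of the six left-side joints
   (shoulder, elbow, wrist, hip, knee, ankle) give an 18-dimensional feature
   vector; optional PCA retains the components covering ≥ 90% of variance.
3. **Classification** — one-against-all RBF-kernel SVMs label every frame
   pair as standing / walking / running.
4. **Estimation** — three regressor families map velocities to METs: linear
   regression, a 3-hidden-layer logistic MLP (70 nodes per layer by
   default, re-derivable with `sweep_mlp_nodes()`), and a 1-D CNN
   (two length-3 convolution + max-pool stages and a 16×2 dense head over
   the 18×1 input). Models are trained either as one *general* model or as
   *activity-specific* models dispatched by the classifier
   (`hierarchical_predict()`), which improves light-to-moderate activity
   estimates.
5. **Harness** — MAE / MSE / RMSE (`MAE = (1/N) Σ|Ŷ_k − Y_k|`, etc.) under
   10-fold cross-validation, over the full camera-view × model-family ×
   PCA experiment grid (`run_experiment()`).

Because depth-camera recordings with paired calorimetry are not readily
available, the package ships a first-class **synthetic data generator**: a
configurable cohort (default 21 subjects, weight 60.20 ± 7.60 kg), a
six-bout treadmill protocol (standing; walking 4.8/5.6/6.4 km/h; running
8.0/8.3 km/h; 5-min bouts), three camera views (side / rear-side / rear,
tripod 0.9 m, ~2 m standoff), sinusoidal gait kinematics with tracking
noise, and breath-by-breath MET ground truth built on the standard
ambulation cost relations (walking `(0.1·v + 3.5)/3.5`, running
`(0.2·v + 3.5)/3.5`, v in m/min).

## Worked example

```r
library(kinemet)

ds <- simulate_dataset(
  default_protocol(n_subjects = 4, duration = 0.5,
                   views = canonical_views()[c("side", "rear")]),
  seed = 9, discard_min = 0, keep_min = 0.5, max_rows = 5000)

cfg <- experiment_config(views = c("side", "rear"), folds = 5, seed = 9,
                         nn_args = list(epochs = 60))
res <- run_experiment(cfg, dataset = ds, stages = "hierarchical")
res$hierarchical
#>   activity rmse_hierarchical rmse_general   n
#> 1 standing         0.1974433    0.2119968 278
#> 2  walking         0.2892035    0.3160162 834
#> 3  running         0.2601378    0.2899307 556
attr(res$hierarchical, "classifier_accuracy")
#> [1] 1
```

Reading: on a held-out split of the simulated protocol, routing each frame
through its activity-specific model (CNN for standing and walking, MLP for
running) lowers the MET RMSE versus a single general MLP for every
activity — most usefully for the light and moderate ones. The classifier
labelled every held-out frame correctly. A 0.55 MET error sustained for one
hour by a 60 kg subject corresponds to `met_to_kcal(0.55, 60, 1)` = 33 kcal.

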