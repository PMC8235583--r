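Package: kinemet
Title: Energy-Expenditure Estimation from Depth-Camera Skeletal Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for estimating the energy expenditure (EE) of
    treadmill activities from depth-camera skeleton sequences, in metabolic
    equivalent of task (MET) units.  Skeleton joint trajectories are
    re-referenced to the shoulder centre, denoised with a centred moving
    average, and trimmed to the steady-state window; per-frame joint
    velocities of six left-side joints form an 18-dimensional feature
    vector, optionally reduced by principal components retaining 90% of the
    variance.  Activities (standing, walking, running) are classified with
    one-against-all radial-basis-function support-vector machines, and MET
    values are regressed with linear, multilayer-perceptron, or
    one-dimensional convolutional models, either as a single general model
    or as activity-specific models dispatched by the classifier.  A
    synthetic skeletal-motion and metabolic data generator reproduces the
    statistical structure of a treadmill protocol (cohort anthropometrics,
    camera viewpoints, gait oscillations, breath-level MET noise) so the
    whole pipeline can be exercised and validated without depth-camera
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
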