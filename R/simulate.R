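#' Activity bouts, camera views and simulation parameters
#'
#' `activity_bout()` describes one treadmill bout; `camera_view()` a depth
#' camera placement; `canonical_views()` returns the three standard
#' placements (side, rear-side and rear view; tripod 0.9 m high, 2 m from the
#' subject).  Yaw is the rotation about the vertical axis between the
#' subject's facing direction and the camera's optical axis: 0 deg for the
#' rear view, 45 deg for the rear-side view and 90 deg for the side view.
#'
#' @param activity One of `"standing"`, `"walking"`, `"running"`.
#' @param speed Treadmill speed, km/h (0 for standing).
#' @param duration Bout duration, minutes.
#' @param rest_after Rest after the bout, minutes (protocol bookkeeping only).
#' @return `activity_bout()`: a list of class `activity_bout`.
#' @export
activity_bout <- function(activity, speed, duration = 5, rest_after = 5) {
  activity <- match.arg(activity, c("standing", "walking", "running"))
  stop_if_not_number(speed, "speed", min = 0)
  stop_if_not_number(duration, "duration", min = 0, strict = TRUE)
  if (activity == "standing" && speed != 0) {
    stop("standing bouts must have speed 0", call. = FALSE)
  }
  if (activity != "standing" && speed <= 0) {
    stop("walking/running bouts need a positive speed", call. = FALSE)
  }
  structure(list(activity = activity, speed = speed, duration = duration,
                 rest_after = rest_after),
            class = "activity_bout")
}

#' @rdname activity_bout
#' @param name View name.
#' @param yaw Rotation about the vertical axis, degrees.
#' @param height Camera height above the floor, m (> 0).
#' @param standoff Camera-to-subject distance, m (> 0).
#' @export
camera_view <- function(name, yaw, height = 0.9, standoff = 2) {
  stop_if_not_number(height, "height", min = 0, strict = TRUE)
  stop_if_not_number(standoff, "standoff", min = 0, strict = TRUE)
  structure(list(name = name, yaw = yaw, height = height, standoff = standoff),
            class = "camera_view")
}

#' @rdname activity_bout
#' @export
canonical_views <- function() {
  list(side = camera_view("side", 90),
       rear_side = camera_view("rear_side", 45),
       rear = camera_view("rear", 0))
}

#' Intensity class of an activity
#'
#' Standing, walking and running are the light, moderate and vigorous
#' activities of the protocol, respectively.
#'
#' @param activity Character vector of activity labels.
#' @return Character vector of `"light"`, `"moderate"`, `"vigorous"`.
#' @export
activity_intensity <- function(activity) {
  unname(c(standing = "light", walking = "moderate",
           running = "vigorous")[as.character(activity)])
}

#' Kinematic simulation parameters
#'
#' Parameters of the gait model used by [generate_sequence()].  Joint motion
#' is sinusoidal limb oscillation at the stride frequency
#' `cadence_base + cadence_speed_gain * speed`, with contralateral limbs in
#' counter-phase, a distal-to-proximal phase lag along each limb, a vertical
#' whole-body bounce at twice the stride frequency, and a slow fore-aft
#' treadmill drift.  Oscillation amplitudes grow with speed
#' (`amplitude_base + amplitude_speed_gain * speed`) and running amplifies
#' them by `run_amplitude_factor`, reflecting the longer stride and higher
#' knee lift of running.  Standing is a static pose with slow postural sway.
#' Additive white Gaussian sensor noise emulates skeletal-tracking jitter.
#'
#' @param cadence_base Stride frequency at zero speed, Hz.
#' @param cadence_speed_gain Stride-frequency gain, Hz per (km/h).
#' @param limb_amplitudes Named fore-aft oscillation amplitudes (m) for the
#'   six left-side limb joints; mirrored to the right side, inherited by
#'   hands/feet.
#' @param amplitude_base,amplitude_speed_gain Dimensionless amplitude scale
#'   and its gain per (km/h).
#' @param run_amplitude_factor Amplitude multiplier applied when running.
#' @param bounce_amplitude Vertical pelvis bounce amplitude, m.
#' @param sway_sd Standing postural sway amplitude, m.
#' @param drift_amplitude Fore-aft body drift amplitude on the treadmill, m.
#' @param drift_freq Drift frequency, Hz.
#' @param sensor_noise_sd Skeletal-tracking noise SD per coordinate, m.
#' @param frame_rate Camera frame rate, Hz (default 30).
#' @return A list of class `motion_params`.
#' @export
motion_params <- function(cadence_base = 0.5, cadence_speed_gain = 0.1,
                          limb_amplitudes = c(shoulder = 0.03, elbow = 0.10,
                                              wrist = 0.18, hip = 0.03,
                                              knee = 0.15, ankle = 0.30),
                          amplitude_base = 0.6, amplitude_speed_gain = 0.08,
                          run_amplitude_factor = 1.5,
                          bounce_amplitude = 0.02,
                          sway_sd = 0.005, drift_amplitude = 0.05,
                          drift_freq = 0.05, sensor_noise_sd = 0.005,
                          frame_rate = 30) {
  for (nm in c("sway_sd", "drift_amplitude", "sensor_noise_sd",
               "bounce_amplitude")) {
    stop_if_not_number(get(nm), nm, min = 0)
  }
  stop_if_not_number(frame_rate, "frame_rate", min = 0, strict = TRUE)
  if (any(limb_amplitudes < 0)) {
    stop("limb amplitudes must be non-negative", call. = FALSE)
  }
  structure(list(cadence_base = cadence_base,
                 cadence_speed_gain = cadence_speed_gain,
                 limb_amplitudes = limb_amplitudes,
                 amplitude_base = amplitude_base,
                 amplitude_speed_gain = amplitude_speed_gain,
                 run_amplitude_factor = run_amplitude_factor,
                 bounce_amplitude = bounce_amplitude,
                 sway_sd = sway_sd, drift_amplitude = drift_amplitude,
                 drift_freq = drift_freq, sensor_noise_sd = sensor_noise_sd,
                 frame_rate = frame_rate),
            class = "motion_params")
}

#' Metabolic ground-truth parameters
#'
#' The speed-to-MET map is the standard ambulation relation with speed `v` in
#' m/min: gross walking cost `0.1 v + 3.5` and running cost `0.2 v + 3.5`
#' ml O2/kg/min, divided by the resting 3.5 ml O2/kg/min to express the
#' result in METs; quiet standing costs `standing_met` (1.3 MET).  A
#' per-subject additive Gaussian effect (SD `subject_sd`) captures
#' between-subject metabolic variation, and each simulated breath adds
#' Gaussian noise (SD `breath_sd`) at intervals of `breath_interval` seconds.
#'
#' @param standing_met Standing baseline, MET.
#' @param walk_slope,run_slope Oxygen-cost slopes per (m/min).
#' @param rest_vo2 Resting oxygen uptake used as intercept and divisor.
#' @param subject_sd Between-subject SD, MET.
#' @param breath_sd Breath-level noise SD, MET.
#' @param breath_interval Breath sampling interval, s.
#' @param floor Lower clamp on generated MET values (must stay positive).
#' @return A list of class `met_params`.
#' @export
met_params <- function(standing_met = 1.3, walk_slope = 0.1, run_slope = 0.2,
                       rest_vo2 = 3.5, subject_sd = 0.2, breath_sd = 0.1,
                       breath_interval = 3, floor = 0.1) {
  stop_if_not_number(subject_sd, "subject_sd", min = 0)
  stop_if_not_number(breath_sd, "breath_sd", min = 0)
  stop_if_not_number(breath_interval, "breath_interval", min = 0,
                     strict = TRUE)
  structure(list(standing_met = standing_met, walk_slope = walk_slope,
                 run_slope = run_slope, rest_vo2 = rest_vo2,
                 subject_sd = subject_sd, breath_sd = breath_sd,
                 breath_interval = breath_interval, floor = floor),
            class = "met_params")
}

#' Ground-truth MET for an activity and speed
#'
#' Deterministic speed-to-MET map plus an optional subject-level offset.
#' At the default parameters the result is strictly increasing from standing
#' through any walking speed to any running speed of the protocol.
#'
#' @param activity `"standing"`, `"walking"` or `"running"`.
#' @param speed Speed in km/h (>= 0).
#' @param params A [met_params()] object.
#' @param subject_effect Additive subject-level offset, MET.
#' @return MET value (scalar).
#' @export
met_ground_truth <- function(activity, speed = 0, params = met_params(),
                             subject_effect = 0) {
  activity <- match.arg(activity, c("standing", "walking", "running"))
  stop_if_not_number(speed, "speed", min = 0)
  v <- speed * 1000 / 60  # m/min
  base <- switch(activity,
    standing = params$standing_met,
    walking = (params$walk_slope * v + params$rest_vo2) / params$rest_vo2,
    running = (params$run_slope * v + params$rest_vo2) / params$rest_vo2)
  max(base + subject_effect, params$floor)
}

# Per-subject metabolic offset, drawn once per subject from its own stream.
subject_met_effect <- function(subject_id, seed, params = met_params()) {
  if (params$subject_sd == 0) return(0)
  with_seed(split_seed(seed, subject_id, "met_subject"),
            stats::rnorm(1, 0, params$subject_sd))
}

# Static reference pose (m): body frame with origin on the floor between the
# feet, y up, z the facing (fore-aft) direction, x lateral.
base_pose <- function() {
  p <- rbind(
    hip_center      = c( 0.00, 1.00, 0.00),
    spine           = c( 0.00, 1.15, 0.00),
    shoulder_center = c( 0.00, 1.45, 0.00),
    head            = c( 0.00, 1.65, 0.00),
    shoulder_left   = c( 0.18, 1.42, 0.00),
    elbow_left      = c( 0.22, 1.15, 0.00),
    wrist_left      = c( 0.24, 0.90, 0.02),
    hand_left       = c( 0.25, 0.82, 0.04),
    shoulder_right  = c(-0.18, 1.42, 0.00),
    elbow_right     = c(-0.22, 1.15, 0.00),
    wrist_right     = c(-0.24, 0.90, 0.02),
    hand_right      = c(-0.25, 0.82, 0.04),
    hip_left        = c( 0.10, 0.95, 0.00),
    knee_left       = c( 0.11, 0.50, 0.00),
    ankle_left      = c( 0.12, 0.08, 0.00),
    foot_left       = c( 0.12, 0.02, 0.12),
    hip_right       = c(-0.10, 0.95, 0.00),
    knee_right      = c(-0.11, 0.50, 0.00),
    ankle_right     = c(-0.12, 0.08, 0.00),
    foot_right      = c(-0.12, 0.02, 0.12))
  colnames(p) <- c("x", "y", "z")
  p[kinect_joints(), , drop = FALSE]
}

# Oscillation plan: amplitude entry, side sign, intra-limb phase lag and
# arm/leg role for each moving joint.  Arms swing in counter-phase with the
# ipsilateral leg; the phase lag grows proximal-to-distal so joint velocities
# are never simultaneously zero, as in real gait.
oscillation_plan <- function() {
  data.frame(
    joint = c("shoulder_left", "elbow_left", "wrist_left", "hand_left",
              "hip_left", "knee_left", "ankle_left", "foot_left",
              "shoulder_right", "elbow_right", "wrist_right", "hand_right",
              "hip_right", "knee_right", "ankle_right", "foot_right"),
    amp = c("shoulder", "elbow", "wrist", "wrist",
            "hip", "knee", "ankle", "ankle",
            "shoulder", "elbow", "wrist", "wrist",
            "hip", "knee", "ankle", "ankle"),
    amp_scale = c(1, 1, 1, 1.05, 1, 1, 1, 1.05,
                  1, 1, 1, 1.05, 1, 1, 1, 1.05),
    side_phase = rep(c(0, pi), each = 8),
    lag = c(1.2, 0.6, 0.0, 0.0, 1.2, 0.6, 0.0, 0.0,
            1.2, 0.6, 0.0, 0.0, 1.2, 0.6, 0.0, 0.0),
    arm = rep(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), 2),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic skeleton sequence with its MET trace
#'
#' Simulates one recording bout: joint trajectories from the kinematic model
#' in [motion_params()], expressed in the given camera view's coordinate
#' frame with additive sensor noise, plus an aligned breath-by-breath MET
#' trace around [met_ground_truth()].  All randomness is drawn from streams
#' derived from `seed` and keyed by subject, bout and view, so results are
#' reproducible and adding bouts or views never perturbs existing ones.
#'
#' @param subject A one-row subject profile (see [sample_cohort()]) or a
#'   subject id string.
#' @param bout An [activity_bout()].
#' @param view A [camera_view()].
#' @param params A [motion_params()] object.
#' @param seed Integer root seed.
#' @param met A [met_params()] object.
#' @return A list with elements `sequence` (a [skeleton_sequence()]) and
#'   `met` (a [met_trace()]).
#' @export
generate_sequence <- function(subject, bout, view, params = motion_params(),
                              seed = 1, met = met_params()) {
  if (is.character(subject)) subject <- data.frame(subject_id = subject)
  if (!inherits(bout, "activity_bout")) {
    stop("`bout` must come from activity_bout()", call. = FALSE)
  }
  if (!inherits(view, "camera_view")) {
    stop("`view` must come from camera_view()", call. = FALSE)
  }
  sid <- subject$subject_id[1]
  fr <- params$frame_rate
  n <- round(bout$duration * 60 * fr)
  t <- (seq_len(n) - 1) / fr

  joints <- kinect_joints()
  pose <- base_pose()
  coords <- array(rep(pose, each = n), c(n, length(joints), 3L),
                  dimnames = list(NULL, joints, c("x", "y", "z")))

  motion_seed <- split_seed(seed, sid, bout$activity, bout$speed, "motion")
  if (bout$activity == "standing") {
    if (params$sway_sd > 0) {
      ph <- with_seed(motion_seed, stats::runif(3, 0, 2 * pi))
      sway_x <- params$sway_sd * sqrt(2) * sin(2 * pi * 0.25 * t + ph[1])
      sway_z <- params$sway_sd * sqrt(2) * sin(2 * pi * 0.20 * t + ph[2])
      coords[, , "x"] <- coords[, , "x"] + sway_x
      coords[, , "z"] <- coords[, , "z"] + sway_z
    }
  } else {
    f <- params$cadence_base + params$cadence_speed_gain * bout$speed
    s_amp <- params$amplitude_base + params$amplitude_speed_gain * bout$speed
    if (bout$activity == "running") s_amp <- s_amp * params$run_amplitude_factor
    ph <- with_seed(motion_seed, stats::runif(2, 0, 2 * pi))
    w <- 2 * pi * f
    plan <- oscillation_plan()
    for (i in seq_len(nrow(plan))) {
      A <- params$limb_amplitudes[[plan$amp[i]]] * plan$amp_scale[i] * s_amp
      phase <- w * t + ph[1] + plan$side_phase[i] + plan$lag[i] +
        if (plan$arm[i]) pi else 0
      vert_frac <- if (plan$arm[i]) 0.15 else 0.5
      j <- plan$joint[i]
      coords[, j, "z"] <- coords[, j, "z"] + A * sin(phase)
      coords[, j, "y"] <- coords[, j, "y"] + vert_frac * A * cos(phase)
      coords[, j, "x"] <- coords[, j, "x"] + 0.1 * A * sin(phase + pi / 4)
    }
    bounce <- params$bounce_amplitude * s_amp * sin(2 * w * t + 2 * ph[1])
    coords[, , "y"] <- coords[, , "y"] + bounce
    drift <- params$drift_amplitude *
      sin(2 * pi * params$drift_freq * t + ph[2])
    coords[, , "z"] <- coords[, , "z"] + drift
  }

  world <- skeleton_sequence(t, coords, frame_rate = fr, view = "world",
                             subject_id = sid, activity = bout$activity,
                             speed = bout$speed)
  cam <- project_to_view(world, view)
  if (params$sensor_noise_sd > 0) {
    noise_seed <- split_seed(seed, sid, bout$activity, bout$speed,
                             view$name, "noise")
    cam$coords <- cam$coords + with_seed(
      noise_seed,
      array(stats::rnorm(length(cam$coords), 0, params$sensor_noise_sd),
            dim(cam$coords)))
  }

  eff <- subject_met_effect(sid, seed, met)
  bt <- seq(0, bout$duration * 60, by = met$breath_interval)
  base <- met_ground_truth(bout$activity, bout$speed, met, eff)
  met_seed <- split_seed(seed, sid, bout$activity, bout$speed, "met")
  vals <- base + if (met$breath_sd > 0) {
    with_seed(met_seed, stats::rnorm(length(bt), 0, met$breath_sd))
  } else 0
  vals <- pmax(vals, met$floor)

  list(sequence = cam, met = met_trace(bt, vals))
}

#' Express a skeleton sequence in a camera view's coordinate frame
#'
#' Applies the rigid motion of the view: rotation about the vertical axis by
#' the view yaw, then translation by the camera placement (the camera sits at
#' `height` above the floor, `standoff` metres from the subject, so the
#' camera-frame origin is the sensor).  Inter-joint distances are preserved.
#' With yaw 0 (rear view) coordinates change only by the translation; with
#' yaw 90 deg the world fore-aft axis maps onto the camera's lateral axis.
#'
#' @param x A [skeleton_sequence()] in world/body coordinates.
#' @param view A [camera_view()].
#' @return A `skeleton_sequence` in camera coordinates.
#' @export
project_to_view <- function(x, view) {
  if (!inherits(view, "camera_view")) {
    stop("`view` must come from camera_view()", call. = FALSE)
  }
  th <- view$yaw * pi / 180
  cx <- x$coords[, , "x"]; cz <- x$coords[, , "z"]
  x$coords[, , "x"] <- cos(th) * cx + sin(th) * cz
  x$coords[, , "z"] <- -sin(th) * cx + cos(th) * cz + view$standoff
  x$coords[, , "y"] <- x$coords[, , "y"] - view$height
  x$view <- view$name
  x
}

#' Default simulation protocol
#'
#' The treadmill protocol emulated by the generator: a 21-subject cohort,
#' three camera views, and six 5-minute bouts (standing; walking at 4.8, 5.6
#' and 6.4 km/h; running at 8.0 and 8.3 km/h) with 5-minute rests after
#' light-to-moderate bouts and 10-minute rests after vigorous ones.
#' `n_subjects` and `duration` scale the protocol down for quick runs without
#' changing its structure.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param duration Bout duration in minutes.
#' @param views List of [camera_view()]s.
#' @param cohort A [cohort_params()] object.
#' @param motion A [motion_params()] object.
#' @param met A [met_params()] object.
#' @return A list of class `sim_protocol`.
#' @export
default_protocol <- function(n_subjects = 21, duration = 5,
                             views = canonical_views(),
                             cohort = cohort_params(),
                             motion = motion_params(),
                             met = met_params()) {
  bouts <- list(
    activity_bout("standing", 0, duration, 0),
    activity_bout("walking", 4.8, duration, 5),
    activity_bout("walking", 5.6, duration, 5),
    activity_bout("walking", 6.4, duration, 5),
    activity_bout("running", 8.0, duration, 10),
    activity_bout("running", 8.3, duration, 10))
  structure(list(n_subjects = n_subjects, bouts = bouts, views = views,
                 cohort = cohort, motion = motion, met = met),
            class = "sim_protocol")
}
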