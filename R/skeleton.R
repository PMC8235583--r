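#' Kinect-v1 joint vocabulary
#'
#' The 20 joints tracked by a first-generation Kinect depth camera, in the
#' fixed order used throughout the package.
#'
#' @return Character vector of 20 joint names.
#' @export
kinect_joints <- function() {
  c("hip_center", "spine", "shoulder_center", "head",
    "shoulder_left", "elbow_left", "wrist_left", "hand_left",
    "shoulder_right", "elbow_right", "wrist_right", "hand_right",
    "hip_left", "knee_left", "ankle_left", "foot_left",
    "hip_right", "knee_right", "ankle_right", "foot_right")
}

#' Construct a skeleton sequence
#'
#' A skeleton sequence holds time-stamped 3-D joint positions for one
#' recording bout as seen from one camera view.  Coordinates are in metres in
#' a right-handed frame with `y` vertical and `z` the camera depth axis.
#'
#' @param timestamps Numeric vector of frame times in seconds, strictly
#'   increasing.
#' @param coords Numeric array `[frame, joint, axis]`; the joint dimension
#'   must carry names and the axis dimension is `c("x", "y", "z")`.
#' @param frame_rate Nominal frame rate in Hz.
#' @param view Camera view name (`"side"`, `"rear_side"`, `"rear"`) or `NA`.
#' @param subject_id Subject identifier or `NA`.
#' @param activity Activity label (`"standing"`, `"walking"`, `"running"`) or
#'   `NA` when unknown.
#' @param speed Treadmill speed in km/h or `NA`.
#' @param stage Character vector of processing stages already applied
#'   (subset of `"raw"`, `"recentered"`, `"smoothed"`, `"trimmed"`).
#'
#' @return An object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(timestamps, coords, frame_rate = 30,
                              view = NA_character_, subject_id = NA_character_,
                              activity = NA_character_, speed = NA_real_,
                              stage = "raw") {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("`coords` must be a [frame, joint, axis] array with 3 axes",
         call. = FALSE)
  }
  if (dim(coords)[1] != length(timestamps)) {
    stop("number of frames in `coords` must match `timestamps`", call. = FALSE)
  }
  if (is.null(dimnames(coords)[[2]])) {
    stop("`coords` must have named joints", call. = FALSE)
  }
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  dimnames(coords)[[3]] <- c("x", "y", "z")
  structure(
    list(timestamps = as.numeric(timestamps), coords = coords,
         frame_rate = frame_rate, view = view, subject_id = subject_id,
         activity = activity, speed = speed, stage = stage),
    class = "skeleton_sequence"
  )
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf(
    "<skeleton_sequence> %d frames x %d joints @ %g Hz\n",
    n_frames(x), length(joint_names(x)), x$frame_rate))
  cat(sprintf("  subject: %s  activity: %s  speed: %s km/h  view: %s\n",
              x$subject_id, x$activity, format(x$speed), x$view))
  cat(sprintf("  stage: %s\n", paste(x$stage, collapse = " > ")))
  invisible(x)
}

#' @rdname skeleton_sequence
#' @param x A `skeleton_sequence`.
#' @export
n_frames <- function(x) length(x$timestamps)

#' @rdname skeleton_sequence
#' @export
joint_names <- function(x) dimnames(x$coords)[[2]]

# Subset frames, preserving metadata.
subset_frames <- function(x, idx) {
  x$timestamps <- x$timestamps[idx]
  x$coords <- x$coords[idx, , , drop = FALSE]
  x
}

#' Read and write skeleton sequences as CSV
#'
#' The on-disk format is plain UTF-8 CSV with a mandatory header: a
#' `timestamp_s` column followed by `<joint>_x`, `<joint>_y`, `<joint>_z`
#' triples for each named joint, one row per frame, `.` as decimal separator.
#'
#' @param x A [skeleton_sequence()].
#' @param path File path.
#' @param ... Metadata passed on to [skeleton_sequence()] when reading
#'   (e.g. `view`, `activity`, `frame_rate`).
#' @return `write_skeleton_csv()` returns `path` invisibly;
#'   `read_skeleton_csv()` returns a `skeleton_sequence`.
#' @export
write_skeleton_csv <- function(x, path) {
  joints <- joint_names(x)
  flat <- matrix(aperm(x$coords, c(1L, 3L, 2L)), nrow = n_frames(x))
  colnames(flat) <- as.vector(t(outer(joints, c("x", "y", "z"), paste,
                                      sep = "_")))
  df <- data.frame(timestamp_s = x$timestamps, flat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_skeleton_csv
#' @export
read_skeleton_csv <- function(path, ...) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (names(df)[1] != "timestamp_s") {
    stop("skeleton CSV must start with a `timestamp_s` column", call. = FALSE)
  }
  cols <- names(df)[-1]
  joints <- unique(sub("_[xyz]$", "", cols))
  expected <- as.vector(t(outer(joints, c("x", "y", "z"), paste, sep = "_")))
  if (!identical(sort(cols), sort(expected))) {
    stop("skeleton CSV columns must be <joint>_x/_y/_z triples", call. = FALSE)
  }
  n <- nrow(df)
  coords <- array(NA_real_, c(n, length(joints), 3L),
                  dimnames = list(NULL, joints, c("x", "y", "z")))
  for (j in joints) {
    for (a in c("x", "y", "z")) {
      coords[, j, a] <- df[[paste(j, a, sep = "_")]]
    }
  }
  skeleton_sequence(df$timestamp_s, coords, ...)
}

#' Metabolic ground-truth traces
#'
#' A MET trace pairs strictly increasing timestamps (seconds) with positive
#' MET values (1 MET = 1 kcal per kg of body mass per hour), mimicking the
#' breath-by-breath output of an indirect calorimeter.
#'
#' @param timestamps Numeric vector, seconds, strictly increasing.
#' @param met_values Numeric vector of positive MET values.
#' @return A data frame of class `met_trace` with columns `timestamp_s`, `met`.
#' @export
met_trace <- function(timestamps, met_values) {
  if (length(timestamps) != length(met_values)) {
    stop("timestamps and MET values must have equal length", call. = FALSE)
  }
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0)) {
    stop("MET trace timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(met_values <= 0)) {
    stop("MET values must be positive", call. = FALSE)
  }
  structure(data.frame(timestamp_s = as.numeric(timestamps),
                       met = as.numeric(met_values)),
            class = c("met_trace", "data.frame"))
}

#' @rdname met_trace
#' @param x A `met_trace`.
#' @param path File path.
#' @export
write_met_trace <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname met_trace
#' @export
read_met_trace <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  met_trace(df$timestamp_s, df$met)
}
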