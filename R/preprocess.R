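#' Re-reference a skeleton sequence to the shoulder centre
#'
#' Translates every frame so the shoulder-centre joint becomes the origin:
#' each joint `i` is replaced by `(xi - xr, yi - yr, zi - zr)` where
#' `(xr, yr, zr)` is that frame's own shoulder-centre position.  This removes
#' the camera-relative body position (fore-aft treadmill drift included)
#' while preserving all inter-joint distances.
#'
#' @param x A [skeleton_sequence()].
#' @param reference_joint Name of the reference joint
#'   (default `"shoulder_center"`).
#' @return The re-referenced `skeleton_sequence`; the reference joint is
#'   exactly `(0, 0, 0)` in every frame.
#' @export
recenter <- function(x, reference_joint = "shoulder_center") {
  if (!inherits(x, "skeleton_sequence")) {
    stop("`x` must be a skeleton_sequence", call. = FALSE)
  }
  if (!reference_joint %in% joint_names(x)) {
    stop(sprintf("reference joint '%s' missing from the sequence",
                 reference_joint), call. = FALSE)
  }
  ref <- x$coords[, reference_joint, , drop = FALSE]  # n x 1 x 3
  bad <- which(!is.finite(ref))
  if (length(bad)) {
    stop(sprintf("non-finite %s position at frame %d", reference_joint,
                 ((bad[1] - 1) %% n_frames(x)) + 1), call. = FALSE)
  }
  x$coords <- x$coords - ref[, rep(1L, length(joint_names(x))), , drop = FALSE]
  x$stage <- union(x$stage, "recentered")
  x
}

#' Smooth a skeleton sequence with a centred moving average
#'
#' Replaces each interior frame `k` by the per-axis, per-joint mean of frames
#' `k-2 ... k+2` (a five-point centred moving average), attenuating
#' skeletal-tracking jitter.  The first and last two frames, for which the
#' window is incomplete, are dropped rather than padded; timestamps of the
#' retained frames are unchanged.
#'
#' @param x A [skeleton_sequence()] with at least 5 frames.
#' @param window Odd window length (default 5).
#' @return The smoothed `skeleton_sequence`, `window - 1` frames shorter.
#' @export
smooth_sequence <- function(x, window = 5) {
  if (!inherits(x, "skeleton_sequence")) {
    stop("`x` must be a skeleton_sequence", call. = FALSE)
  }
  if (window %% 2 != 1 || window < 3) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  n <- n_frames(x)
  if (n < window) {
    stop(sprintf("sequence has %d frames; smoothing needs at least %d",
                 n, window), call. = FALSE)
  }
  half <- (window - 1) / 2
  flat <- matrix(x$coords, nrow = n)
  sm <- stats::filter(flat, rep(1 / window, window), sides = 2)
  keep <- (half + 1):(n - half)
  x$coords <- array(as.numeric(sm[keep, ]),
                    c(length(keep), dim(x$coords)[2:3]),
                    dimnames = c(list(NULL), dimnames(x$coords)[2:3]))
  x$timestamps <- x$timestamps[keep]
  x$stage <- union(x$stage, "smoothed")
  x
}

#' Trim a sequence to its steady-state window
#'
#' Discards the non-steady-state start of a bout and keeps the following
#' steady-state window: frames with time `t` relative to the first frame in
#' `[discard_min, discard_min + keep_min)` minutes are retained.  With the
#' defaults, the first 3 minutes are discarded and the next 2 minutes kept
#' (3600 frames at 30 Hz).
#'
#' @param x A [skeleton_sequence()].
#' @param discard_min Minutes to discard from the start.
#' @param keep_min Minutes to keep after the discarded window.
#' @param tol Seconds of slack allowed in the span precondition, so that the
#'   handful of boundary frames consumed by [smooth_sequence()] does not
#'   disqualify a bout that nominally covers the window.
#' @return The trimmed `skeleton_sequence` (frame order and timestamps
#'   preserved).
#' @export
trim_steady_state <- function(x, discard_min = 3, keep_min = 2, tol = 1) {
  if (!inherits(x, "skeleton_sequence")) {
    stop("`x` must be a skeleton_sequence", call. = FALSE)
  }
  stop_if_not_number(discard_min, "discard_min", min = 0)
  stop_if_not_number(keep_min, "keep_min", min = 0, strict = TRUE)
  t0 <- x$timestamps[1]
  dt <- if (n_frames(x) > 1) stats::median(diff(x$timestamps)) else 0
  span <- (x$timestamps[n_frames(x)] - t0) + dt
  needed <- (discard_min + keep_min) * 60
  if (span < needed - tol) {
    stop(sprintf(
      "sequence covers %.1f s but %.1f s are required (%g min discarded + %g min kept)",
      span, needed, discard_min, keep_min), call. = FALSE)
  }
  rel <- x$timestamps - t0
  keep <- which(rel >= discard_min * 60 - 1e-9 & rel < needed - 1e-9)
  x <- subset_frames(x, keep)
  x$stage <- union(x$stage, "trimmed")
  x
}

#' Full preprocessing chain
#'
#' Convenience wrapper applying, in order, [recenter()], [smooth_sequence()]
#' and [trim_steady_state()].
#'
#' @inheritParams trim_steady_state
#' @param window Smoothing window length.
#' @return The preprocessed `skeleton_sequence`.
#' @export
preprocess_sequence <- function(x, discard_min = 3, keep_min = 2, window = 5) {
  trim_steady_state(smooth_sequence(recenter(x), window = window),
                    discard_min = discard_min, keep_min = keep_min)
}
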