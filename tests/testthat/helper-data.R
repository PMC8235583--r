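# Shared fixtures, built once per test run and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A skeleton sequence with arbitrary coordinates (random walk around a pose),
# for algebraic property tests.
random_sequence <- function(n = 40, seed = 1, joints = kinect_joints(),
                            frame_rate = 30) {
  coords <- array(0, c(n, length(joints), 3L),
                  dimnames = list(NULL, joints, c("x", "y", "z")))
  with_seed <- getFromNamespace("with_seed", "kinemet")
  with_seed(seed, {
    coords[] <- rnorm(length(coords), sd = 0.3)
  })
  skeleton_sequence((seq_len(n) - 1) / frame_rate, coords,
                    frame_rate = frame_rate)
}

# A minimal two-joint sequence whose x-coordinates follow a given function of
# the frame index; other axes and the reference joint stay at zero.
ramp_sequence <- function(xs, frame_rate = 30) {
  n <- length(xs)
  joints <- c("shoulder_center", "ankle_left")
  coords <- array(0, c(n, 2L, 3L), dimnames = list(NULL, joints,
                                                   c("x", "y", "z")))
  coords[, "ankle_left", "x"] <- xs
  skeleton_sequence((seq_len(n) - 1) / frame_rate, coords,
                    frame_rate = frame_rate)
}

# Scaled simulation of the full six-bout protocol: 3 subjects, 3 views,
# 30 s steady-state windows, thinned to 4000 feature rows.
small_dataset <- function() {
  cached("small_ds", simulate_dataset(
    default_protocol(n_subjects = 3, duration = 0.5),
    seed = 11, discard_min = 0, keep_min = 0.5, max_rows = 4000))
}

# Two-view (side + rear) version used by the routing/hierarchical tests.
routing_dataset <- function() {
  cached("route_ds", simulate_dataset(
    default_protocol(n_subjects = 4, duration = 0.5,
                     views = canonical_views()[c("side", "rear")]),
    seed = 9, discard_min = 0, keep_min = 0.5, max_rows = 5000))
}

# Two well-separated Gaussian blobs in 2-D, labelled standing/walking.
blob_data <- function(n_per = 60, seed = 4) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 2, 0, 0.3), ncol = 2),
             matrix(rnorm(n_per * 2, 4, 0.3), ncol = 2))
  list(x = x, labels = rep(c("standing", "walking"), each = n_per))
}

pairwise_distances <- function(seq, frame = 1) {
  as.matrix(dist(seq$coords[frame, , ]))
}
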