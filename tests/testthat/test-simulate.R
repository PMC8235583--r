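test_that("the speed-to-MET map is monotone across the protocol", {
  expect_equal(met_ground_truth("standing", 0), 1.3)
  # walking: (0.1 v + 3.5)/3.5 with v in m/min
  expect_equal(met_ground_truth("walking", 4.8), (0.1 * 80 + 3.5) / 3.5)
  expect_gt(met_ground_truth("walking", 6.4), met_ground_truth("walking", 4.8))
  expect_gt(met_ground_truth("running", 8.3), met_ground_truth("walking", 6.4))
  expect_gt(met_ground_truth("running", 8.0), met_ground_truth("running", 0))
  expect_error(met_ground_truth("walking", -1), "speed")
})

test_that("MET ordering standing < walking < running holds for every subject", {
  met <- met_params()
  for (sid in sprintf("S%03d", 1:8)) {
    eff <- kinemet:::subject_met_effect(sid, seed = 31, met)
    mets <- c(met_ground_truth("standing", 0, met, eff),
              met_ground_truth("walking", 4.8, met, eff),
              met_ground_truth("walking", 6.4, met, eff),
              met_ground_truth("running", 8.0, met, eff),
              met_ground_truth("running", 8.3, met, eff))
    expect_true(all(diff(mets) > 0))
  }
})

test_that("a 5-minute bout at 30 Hz yields 9000 frames with a breath-level trace", {
  g <- generate_sequence("S001", activity_bout("walking", 4.8, duration = 5),
                         canonical_views()$side, motion_params(), seed = 7)
  expect_equal(n_frames(g$sequence), 5 * 60 * 30)
  expect_s3_class(g$met, "met_trace")
  expect_true(all(diff(g$met$timestamp_s) > 0))
  expect_true(all(g$met$met > 0))
  # breath interval default 3 s over 300 s
  expect_equal(nrow(g$met), 101)
})

test_that("noiseless standing is a static pose with zero downstream velocities", {
  p0 <- motion_params(sway_sd = 0, sensor_noise_sd = 0)
  g <- generate_sequence("S001", activity_bout("standing", 0, duration = 0.1),
                         canonical_views()$rear, p0, seed = 3)
  rng <- apply(g$sequence$coords, 2:3, function(z) diff(range(z)))
  expect_equal(max(rng), 0)
  v <- joint_velocities(select_joints(recenter(g$sequence)))
  expect_equal(max(abs(v)), 0)
})

test_that("generated cadence is recoverable as the ankle's dominant vertical frequency", {
  p0 <- motion_params(sensor_noise_sd = 0)
  for (speed in c(4.8, 6.4)) {
    g <- generate_sequence("S001", activity_bout("walking", speed, duration = 2),
                           canonical_views()$side, p0, seed = 13)
    y <- g$sequence$coords[, "ankle_left", "y"]
    n <- length(y)
    spec <- Mod(stats::fft(y - mean(y)))[2:(n %/% 2)]
    freq <- (1:(n %/% 2 - 1)) * 30 / n
    expect_lt(abs(freq[which.max(spec)] - (0.5 + 0.1 * speed)), 30 / n)
  }
})

test_that("sequences and traces are bit-identical under a fixed seed", {
  b <- activity_bout("running", 8.0, duration = 0.1)
  v <- canonical_views()$rear_side
  g1 <- generate_sequence("S002", b, v, motion_params(), seed = 21)
  g2 <- generate_sequence("S002", b, v, motion_params(), seed = 21)
  expect_identical(g1$sequence$coords, g2$sequence$coords)
  expect_identical(g1$met, g2$met)
  g3 <- generate_sequence("S002", b, v, motion_params(), seed = 22)
  expect_false(identical(g1$sequence$coords, g3$sequence$coords))
})

test_that("view projection is a rigid motion with the stated yaw convention", {
  seq <- random_sequence(10, seed = 8)
  # yaw 0 (rear view): translation only
  rear <- project_to_view(seq, camera_view("rear", 0))
  expect_equal(rear$coords[, , "x"], seq$coords[, , "x"])
  expect_equal(rear$coords[, , "y"], seq$coords[, , "y"] - 0.9)
  expect_equal(rear$coords[, , "z"], seq$coords[, , "z"] + 2)
  # yaw 90: the world fore-aft axis becomes the camera's lateral axis
  side <- project_to_view(seq, camera_view("side", 90))
  expect_equal(side$coords[, , "x"], seq$coords[, , "z"], tolerance = 1e-12)
  # arbitrary yaw preserves all inter-joint distances
  skew <- project_to_view(seq, camera_view("skew", 37.3))
  for (f in c(1, 5, 10)) {
    expect_equal(pairwise_distances(skew, f), pairwise_distances(seq, f),
                 tolerance = 1e-12)
  }
})

test_that("bout invariants are enforced", {
  expect_error(activity_bout("standing", 2), "speed 0")
  expect_error(activity_bout("walking", 0), "positive speed")
  expect_error(activity_bout("walking", 4.8, duration = 0), "duration")
  expect_error(camera_view("x", 0, height = 0), "height")
})
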