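test_that("re-centring subtracts the shoulder centre exactly", {
  joints <- c("shoulder_center", "ankle_left")
  coords <- array(0, c(1, 2, 3), dimnames = list(NULL, joints,
                                                 c("x", "y", "z")))
  coords[1, "shoulder_center", ] <- c(0.1, 1.4, 2.0)
  coords[1, "ankle_left", ] <- c(0.1, 0.3, 2.1)
  seq <- skeleton_sequence(0, coords)
  rc <- recenter(seq)
  expect_equal(rc$coords[1, "ankle_left", ], c(x = 0.0, y = -1.1, z = 0.1))
  expect_equal(rc$coords[1, "shoulder_center", ], c(x = 0, y = 0, z = 0))
})

test_that("re-centring places the shoulder centre at the origin and preserves distances", {
  seq <- random_sequence(20, seed = 2)
  rc <- recenter(seq)
  expect_equal(max(abs(rc$coords[, "shoulder_center", ])), 0)
  for (f in c(1, 10, 20)) {
    expect_equal(pairwise_distances(rc, f), pairwise_distances(seq, f),
                 tolerance = 1e-12)
  }
  # idempotent: once the reference joint is at the origin, nothing moves
  expect_equal(recenter(rc)$coords, rc$coords)
})

test_that("re-centring requires the reference joint", {
  seq <- random_sequence(5, seed = 3, joints = c("head", "spine"))
  expect_error(recenter(seq), "shoulder_center")
})

test_that("the moving average leaves constant sequences unchanged and averages ramps", {
  const <- ramp_sequence(rep(1.5, 9))
  sm <- smooth_sequence(const)
  expect_equal(n_frames(sm), 5)
  expect_equal(unname(sm$coords[, "ankle_left", "x"]), rep(1.5, 5))
  # hand evaluation on [0, 1, 2, 3, 4]: middle frame -> mean = 2
  ramp <- ramp_sequence(0:4)
  expect_equal(unname(smooth_sequence(ramp)$coords[1, "ankle_left", "x"]), 2.0)
  # timestamps of surviving frames unchanged
  expect_equal(sm$timestamps, const$timestamps[3:7])
})

test_that("smoothing cuts i.i.d. noise variance about five-fold", {
  set.seed(17)
  n <- 4000
  noisy <- ramp_sequence(rnorm(n, sd = 0.02))
  sm <- smooth_sequence(noisy)
  ratio <- var(sm$coords[, "ankle_left", "x"]) /
    var(noisy$coords[, "ankle_left", "x"])
  expect_lt(abs(ratio - 1 / 5), 0.03)
})

test_that("smoothing is linear and commutes with re-centring", {
  s1 <- random_sequence(30, seed = 4)
  s2 <- random_sequence(30, seed = 5)
  lin <- s1
  lin$coords <- 2 * s1$coords + 3 * s2$coords
  expect_equal(smooth_sequence(lin)$coords,
               2 * smooth_sequence(s1)$coords + 3 * smooth_sequence(s2)$coords,
               tolerance = 1e-12)
  expect_equal(smooth_sequence(recenter(s1))$coords,
               recenter(smooth_sequence(s1))$coords, tolerance = 1e-12)
})

test_that("too-short sequences cannot be smoothed", {
  expect_error(smooth_sequence(ramp_sequence(1:4)), "at least 5")
})

test_that("steady-state trimming keeps exactly the configured window", {
  g <- generate_sequence("S001", activity_bout("walking", 4.8, duration = 5),
                         canonical_views()$side,
                         motion_params(sensor_noise_sd = 0), seed = 7)
  tr <- trim_steady_state(g$sequence, discard_min = 3, keep_min = 2)
  expect_equal(n_frames(tr), 2 * 60 * 30)
  expect_true(all(diff(tr$timestamps) > 0))
  expect_gte(min(tr$timestamps), 180)
  expect_lt(max(tr$timestamps), 300)
  # no-op configuration
  short <- ramp_sequence(1:30)
  expect_equal(trim_steady_state(short, 0, 1 / 60, tol = 0)$timestamps,
               short$timestamps)
  # a 4-minute bout cannot supply 3 + 2 minutes
  g4 <- generate_sequence("S001", activity_bout("walking", 4.8, duration = 4),
                          canonical_views()$side, motion_params(), seed = 7)
  expect_error(trim_steady_state(g4$sequence), "covers")
})
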