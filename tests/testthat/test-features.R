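test_that("joint selection keeps the six left-side joints in fixed order", {
  seq <- random_sequence(10, seed = 6)
  sel <- select_joints(seq)
  expect_equal(joint_names(sel),
               c("shoulder_left", "elbow_left", "wrist_left",
                 "hip_left", "knee_left", "ankle_left"))
  expect_equal(select_joints(sel)$coords, sel$coords)  # idempotent
  no_ankle <- random_sequence(10, seed = 6,
                              joints = setdiff(kinect_joints(), "ankle_left"))
  expect_error(select_joints(no_ankle), "ankle_left")
})

test_that("velocities are finite differences over actual timestamp gaps", {
  seq <- ramp_sequence(c(0.0, 0.1))
  v <- joint_velocities(seq)
  expect_equal(nrow(v), 1)
  expect_equal(unname(v[1, "ankle_left_vx"]), 3.0)
  # six joints x three axes = 18 columns
  big <- select_joints(random_sequence(12, seed = 9))
  expect_equal(ncol(joint_velocities(big)), 18)
  expect_equal(nrow(joint_velocities(big)), 11)
})

test_that("a uniformly translating pose has constant velocity equal to the rate", {
  n <- 20
  seq <- ramp_sequence(0.25 * (0:(n - 1)) / 30)  # 0.25 m/s along x
  v <- joint_velocities(seq)
  expect_equal(unname(v[, "ankle_left_vx"]), rep(0.25, n - 1))
  expect_equal(max(abs(v[, "ankle_left_vy"])), 0)
})

test_that("duplicate timestamps are rejected rather than divided by", {
  joints <- c("shoulder_center", "ankle_left")
  coords <- array(0, c(3, 2, 3), dimnames = list(NULL, joints,
                                                 c("x", "y", "z")))
  expect_error(skeleton_sequence(c(0, 0, 1), coords), "increasing")
  seq <- skeleton_sequence(c(0, 1, 2), coords)
  seq$timestamps <- c(0, 1, 1)  # corrupt after construction
  expect_error(joint_velocities(seq), "zero time step")
})

test_that("rear and side views differ only by the view rotation of velocities", {
  p0 <- motion_params(sensor_noise_sd = 0)
  b <- activity_bout("walking", 5.6, duration = 0.2)
  gr <- generate_sequence("S001", b, canonical_views()$rear, p0, seed = 5)
  gs <- generate_sequence("S001", b, canonical_views()$side, p0, seed = 5)
  vr <- joint_velocities(select_joints(recenter(gr$sequence)))
  vs <- joint_velocities(select_joints(recenter(gs$sequence)))
  for (j in left_joints()) {
    expect_equal(unname(vs[, paste0(j, "_vx")]), unname(vr[, paste0(j, "_vz")]),
                 tolerance = 1e-10)
    expect_equal(unname(vs[, paste0(j, "_vz")]), -unname(vr[, paste0(j, "_vx")]),
                 tolerance = 1e-10)
    expect_equal(unname(vs[, paste0(j, "_vy")]), unname(vr[, paste0(j, "_vy")]),
                 tolerance = 1e-10)
  }
})

test_that("PCA retention follows the 90% cumulative-variance rule", {
  expect_equal(pca_retained_count(c(0.50, 0.30, 0.15, 0.05)), 3)
  expect_equal(pca_retained_count(c(1)), 1)
  # rank-1 data -> a single component
  set.seed(10)
  dir <- rnorm(18)
  x1 <- outer(rnorm(50), dir)
  expect_equal(fit_pca(x1)$retained, 1)
  # isotropic 18-d data: 16 equal shares ~ 88.9% < 90%, 17 ~ 94.4%
  xi <- matrix(rnorm(20000 * 18), ncol = 18)
  pi18 <- fit_pca(xi)
  expect_equal(pi18$retained, 17)
  expect_equal(sum(pi18$explained), 1)
  # retained loadings are orthonormal
  g <- crossprod(pi18$rotation)
  expect_equal(g, diag(ncol(pi18$rotation)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(fit_pca(matrix(1, 10, 3)), "zero-variance")
})

test_that("PCA projection is lossless on rank-1 and full-retention data", {
  set.seed(11)
  dir <- rnorm(18)
  x1 <- outer(rnorm(60), dir)
  p1 <- fit_pca(x1)
  rec <- apply_pca(p1, x1) %*% t(p1$rotation)
  rec <- sweep(rec, 2, p1$center, "+")
  expect_equal(rec, x1, tolerance = 1e-8, ignore_attr = TRUE)
  xf <- matrix(rnorm(200 * 6), ncol = 6)
  pf <- fit_pca(xf, variance_threshold = 1.0)
  expect_equal(pf$retained, 6)
  recf <- sweep(apply_pca(pf, xf) %*% t(pf$rotation), 2, pf$center, "+")
  expect_equal(recf, xf, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(apply_pca(pf, xf[, 1:5]), "does not match")
})

test_that("a train-fitted transform generalises to held-out rows of the same distribution", {
  set.seed(12)
  L <- matrix(rnorm(18 * 3), 18, 3)
  make <- function(n) matrix(rnorm(n * 3), ncol = 3) %*% t(L) +
    matrix(rnorm(n * 18, sd = 0.1), ncol = 18)
  tr <- make(3000); te <- make(3000)
  p <- fit_pca(tr)
  vtr <- sum(apply(apply_pca(p, tr), 2, var))
  vte <- sum(apply(apply_pca(p, te), 2, var))
  expect_lt(abs(vte / vtr - 1), 0.1)
})

test_that("MET targets use previous-breath step interpolation", {
  trace <- met_trace(c(0, 3, 6), c(1.0, 2.0, 3.0))
  expect_equal(met_targets_for(c(0, 1, 2.9, 3, 4, 6, 10), trace),
               c(1, 1, 1, 2, 2, 3, 3))
})
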