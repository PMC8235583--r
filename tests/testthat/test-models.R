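test_that("OLS recovers exact linear structure and matches the normal-equation oracle", {
  set.seed(30)
  x <- matrix(rnorm(200 * 4), ncol = 4)
  beta <- c(1.5, -2, 0.5, 3)
  y <- drop(x %*% beta) + 0.7
  m <- train_lr(x, y)
  expect_equal(unname(m$coef), c(0.7, beta), tolerance = 1e-10)
  expect_equal(predict_met(m, x), y, tolerance = 1e-10)
  # constant target: intercept only
  mc <- train_lr(x, rep(2.2, nrow(x)))
  expect_equal(unname(mc$coef), c(2.2, 0, 0, 0, 0), tolerance = 1e-10)
  # noisy case against the closed-form normal equations
  x1 <- matrix(rnorm(1000), ncol = 1)
  y1 <- 2 * x1[, 1] + 1 + rnorm(1000, sd = 0.1)
  m1 <- train_lr(x1, y1)
  X <- cbind(1, x1)
  oracle <- solve(t(X) %*% X, t(X) %*% y1)
  expect_equal(unname(m1$coef), drop(oracle), tolerance = 1e-8)
  expect_lt(abs(m1$coef[2] - 2), 0.05)
})

test_that("degenerate OLS designs are rejected", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(train_lr(cbind(x, x[, 1]), rnorm(10)), "rank-deficient")
  expect_error(train_lr(matrix(rnorm(4), 2, 2), rnorm(2)), "p \\+ 1")
})

test_that("the MLP fits constants, beats the mean predictor, and is seed-stable", {
  set.seed(31)
  x <- matrix(rnorm(300 * 3), ncol = 3)
  mc <- train_mlp(x, rep(1.7, 300), n_nodes = 10, seed = 1, epochs = 60)
  expect_lt(max(abs(predict_met(mc, x) - 1.7)), 0.05)
  # smooth monotone target
  x1 <- matrix(runif(2000, -2, 2), ncol = 1)
  y1 <- tanh(x1[, 1]) + rnorm(2000, sd = 0.05)
  tr <- 1:1600; te <- 1601:2000
  m <- train_mlp(x1[tr, , drop = FALSE], y1[tr], n_nodes = 20, seed = 2,
                 epochs = 120)
  expect_lt(mse(predict_met(m, x1[te, , drop = FALSE]), y1[te]), var(y1[te]))
  m2 <- train_mlp(x1[tr, , drop = FALSE], y1[tr], n_nodes = 20, seed = 2,
                  epochs = 120)
  expect_identical(predict_met(m, x1[te, , drop = FALSE]),
                   predict_met(m2, x1[te, , drop = FALSE]))
  expect_error(train_mlp(x, c(NA, rnorm(299))), "finite")
  expect_error(train_mlp(x, rnorm(300), n_nodes = 0), "n_nodes")
})

test_that("the node sweep returns one row per candidate and a well-defined argmin", {
  set.seed(32)
  x <- matrix(runif(300, -2, 2), ncol = 1)
  y <- sin(x[, 1]) + rnorm(300, sd = 0.05)
  sw <- sweep_mlp_nodes(x, y, seed = 3, epochs = 15)
  expect_equal(nrow(sw$table), 9)
  expect_equal(sw$table$n_nodes, seq(10, 90, by = 10))
  expect_true(sw$best_n %in% sw$table$n_nodes)
  expect_equal(sw$table$mse[sw$table$n_nodes == sw$best_n], min(sw$table$mse))
  one <- sweep_mlp_nodes(x, y, candidates = 25, seed = 3, epochs = 10)
  expect_equal(one$best_n, 25)
  expect_error(sweep_mlp_nodes(x, y, candidates = numeric(0)), "empty")
})

test_that("the CNN requires 18 inputs, fits constants, and learns a conv-expressible statistic", {
  set.seed(33)
  x <- matrix(rnorm(200 * 18), ncol = 18)
  expect_error(train_cnn(x[, 1:17], rnorm(200)), "18-wide")
  mc <- train_cnn(x, rep(2.5, 200), seed = 4, epochs = 50)
  expect_lt(max(abs(predict_met(mc, x) - 2.5)), 0.1)
  # mean absolute velocity target, a statistic the conv/pool stack expresses
  xb <- matrix(rnorm(1500 * 18), ncol = 18)
  yb <- rowMeans(abs(xb))
  tr <- 1:1200; te <- 1201:1500
  m <- train_cnn(xb[tr, ], yb[tr], seed = 5, epochs = 40)
  base <- mse(rep(mean(yb[tr]), length(te)), yb[te])
  expect_lt(mse(predict_met(m, xb[te, ]), yb[te]), 0.5 * base)
  m2 <- train_cnn(xb[tr, ], yb[tr], seed = 5, epochs = 40)
  expect_identical(predict_met(m, xb[te, ]), predict_met(m2, xb[te, ]))
})

test_that("prediction validates dimensions", {
  set.seed(34)
  m <- train_lr(matrix(rnorm(60), ncol = 2), rnorm(30))
  expect_error(predict_met(m, matrix(rnorm(30), ncol = 3)), "does not match")
})

test_that("MET-to-kcal conversion follows the unit definition and is bilinear", {
  expect_equal(met_to_kcal(0.55, 60, 1), 33)
  expect_equal(met_to_kcal(0, 60, 1), 0)
  expect_equal(met_to_kcal(1, 70, 2), 140)
  expect_equal(met_to_kcal(1.2, 2 * 60, 1), 2 * met_to_kcal(1.2, 60, 1))
  expect_equal(met_to_kcal(1.2, 60, 3 * 1), 3 * met_to_kcal(1.2, 60, 1))
  expect_error(met_to_kcal(-1, 60, 1), "non-negative")
})
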