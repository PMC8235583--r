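test_that("separable blobs are memorised and the model holds one machine per class", {
  d <- blob_data()
  m <- train_activity_classifier(d$x, d$labels, seed = 1)
  expect_equal(length(m$machines), 2)
  expect_equal(classification_accuracy(classify_activity(m, d$x), d$labels), 1.0)
  # three classes -> exactly three binary machines
  d3x <- rbind(d$x, matrix(rnorm(60 * 2, -4, 0.3), ncol = 2))
  d3y <- c(d$labels, rep("running", 60))
  m3 <- train_activity_classifier(d3x, d3y, seed = 1)
  expect_equal(length(m3$machines), 3)
  expect_setequal(names(m3$machines), activity_levels())
  expect_equal(classification_accuracy(classify_activity(m3, d3x), d3y), 1.0)
})

test_that("training twice with the same seed gives identical predictions", {
  d <- blob_data(seed = 7)
  probe <- matrix(rnorm(40, 2, 2), ncol = 2)
  m1 <- train_activity_classifier(d$x, d$labels, seed = 3)
  m2 <- train_activity_classifier(d$x, d$labels, seed = 3)
  expect_identical(classify_activity(m1, probe), classify_activity(m2, probe))
})

test_that("zero-velocity standing frames separate from oscillatory walking frames", {
  ds <- small_dataset()
  sel <- ds$meta$activity %in% c("standing", "walking")
  x <- ds$features$side[sel, ]
  y <- as.character(ds$meta$activity[sel])
  idx <- seq_along(y) %% 5 == 0
  m <- train_activity_classifier(x[!idx, ], y[!idx], seed = 2)
  pred <- classify_activity(m, x[idx, ])
  stand <- y[idx] == "standing"
  expect_gte(classification_accuracy(pred[stand], y[idx][stand]), 0.99)
})

test_that("degenerate classifier inputs are rejected", {
  d <- blob_data()
  expect_error(train_activity_classifier(d$x, rep("standing", nrow(d$x))),
               "2 classes")
  bad <- d$x; bad[1, 1] <- NaN
  expect_error(train_activity_classifier(bad, d$labels), "finite")
  m <- train_activity_classifier(d$x, d$labels)
  expect_error(classify_activity(m, d$x[, 1, drop = FALSE]), "does not match")
})

test_that("accuracy counts matches and behaves at chance under permutation", {
  expect_equal(classification_accuracy(c("a", "b"), c("a", "b")), 1.0)
  pred <- rep("standing", 100); truth <- pred; truth[1:3] <- "walking"
  expect_equal(classification_accuracy(pred, truth), 0.97)
  expect_error(classification_accuracy(c("a"), c("a", "b")), "equal length")
  set.seed(20)
  labels <- rep(activity_levels(), 400)
  perm <- sample(labels)
  expect_lt(abs(classification_accuracy(perm, labels) - 1 / 3), 0.05)
})

test_that("one-vs-all accuracy agrees with an independent multiclass SVM", {
  ds <- small_dataset()
  x <- ds$features$rear
  y <- as.character(ds$meta$activity)
  idx <- seq_along(y) %% 4 == 0
  ours <- train_activity_classifier(x[!idx, ], y[!idx], seed = 5)
  acc_ours <- classification_accuracy(classify_activity(ours, x[idx, ]),
                                      y[idx])
  ref <- kernlab::ksvm(x[!idx, ], factor(y[!idx]), kernel = "rbfdot",
                       C = 1, scaled = TRUE)
  acc_ref <- mean(as.character(kernlab::predict(ref, x[idx, ])) == y[idx])
  expect_gte(acc_ours, acc_ref - 0.02)
  expect_gte(acc_ours, 0.98)
})

test_that("majority vote yields a bout-level label", {
  expect_equal(majority_label(c("walking", "walking", "running")), "walking")
  expect_equal(majority_label(c("standing")), "standing")
})
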