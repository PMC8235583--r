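#' Train a linear MET regression model
#'
#' Ordinary least squares with intercept, fitted by QR decomposition.  Serves
#' as the statistical baseline among the three regressor families.
#'
#' @param x Feature matrix (rows = frame pairs).
#' @param y MET targets, one per row.
#' @return An `ee_model` with family `"lr"`.
#' @export
train_lr <- function(x, y) {
  x <- unclass(as.matrix(x))
  if (nrow(x) != length(y)) stop("rows and targets misaligned", call. = FALSE)
  if (nrow(x) < ncol(x) + 1L) {
    stop("OLS needs at least p + 1 rows", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("features and targets must be finite", call. = FALSE)
  }
  X <- cbind(`(intercept)` = 1, x)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    stop("rank-deficient design: remove collinear features", call. = FALSE)
  }
  structure(list(family = "lr", coef = fit$coefficients,
                 input_dim = ncol(x)),
            class = "ee_model")
}

#' Train a multilayer-perceptron MET regressor
#'
#' A feed-forward network with three hidden layers of `n_nodes` units each,
#' logistic hidden activations and a linear scalar MET output, trained with
#' mini-batch Adam on standardised inputs and targets, with early stopping on
#' a validation split carved from the training rows.  Deterministic for a
#' fixed seed.
#'
#' @param x Feature matrix.
#' @param y MET targets.
#' @param n_nodes Hidden-layer width (default 70, the node-sweep optimum).
#' @param seed Integer seed for initialisation and batching.
#' @param epochs Maximum training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param val_fraction Fraction of rows held out for early stopping.
#' @param patience Epochs without validation improvement before stopping.
#' @return An `ee_model` with family `"mlp"`.
#' @export
train_mlp <- function(x, y, n_nodes = 70, seed = 1, epochs = 200,
                      learning_rate = 1e-3, batch_size = 64,
                      val_fraction = 0.1, patience = 20) {
  stop_if_not_number(n_nodes, "n_nodes", min = 1)
  x <- unclass(as.matrix(x))
  check_net_inputs(x, y)
  xs <- fit_scaler(x); ys <- list(center = mean(y), scale = max(stats::sd(y),
                                                                1e-8))
  X <- apply_scaler(xs, x)
  yn <- (y - ys$center) / ys$scale
  params <- with_seed(split_seed(seed, "mlp_init"),
                      mlp_init(ncol(x), as.integer(n_nodes)))
  res <- train_net(X, yn, params, mlp_forward, mlp_backward, epochs,
                   learning_rate, batch_size, val_fraction, patience,
                   seed = split_seed(seed, "mlp_train"))
  structure(list(family = "mlp", params = res$params, x_scaler = xs,
                 y_scaler = ys, n_nodes = n_nodes, input_dim = ncol(x),
                 seed = seed, epochs_run = res$epochs_run),
            class = "ee_model")
}

#' Sweep the MLP hidden-layer width
#'
#' Trains one MLP per candidate width on a fixed training split and scores
#' each on the same validation split; the best width is the argmin of
#' validation MSE (ties broken towards the smaller width).
#'
#' @inheritParams train_mlp
#' @param candidates Candidate widths (default 10, 20, ..., 90).
#' @param ... Passed to [train_mlp()].
#' @return A list with `best_n` and `table` (data frame of `n_nodes`, `mse`).
#' @export
sweep_mlp_nodes <- function(x, y, candidates = seq(10, 90, by = 10),
                            seed = 1, ...) {
  if (!length(candidates)) stop("empty candidate list", call. = FALSE)
  x <- unclass(as.matrix(x))
  n <- nrow(x)
  idx <- with_seed(split_seed(seed, "sweep_split"), sample.int(n))
  n_val <- max(1L, round(0.2 * n))
  val <- idx[seq_len(n_val)]; tr <- idx[-seq_len(n_val)]
  mses <- vapply(candidates, function(h) {
    fit <- train_mlp(x[tr, , drop = FALSE], y[tr], n_nodes = h,
                     seed = split_seed(seed, "sweep", h), ...)
    mse(predict_met(fit, x[val, , drop = FALSE]), y[val])
  }, numeric(1))
  list(best_n = candidates[which.min(mses)],
       table = data.frame(n_nodes = candidates, mse = mses))
}

#' Train a one-dimensional convolutional MET regressor
#'
#' The 18 velocity features enter as an 18 x 1 signal; two convolutional
#' layers (length-3 kernels, same-padding, rectified-linear activations)
#' each followed by a length-2 max-pooling layer feed a dense head of two
#' 16-unit layers and a scalar MET output.  Trained like [train_mlp()].
#' The input must be the full 18-wide velocity vector; PCA-reduced inputs
#' are rejected.
#'
#' @inheritParams train_mlp
#' @param filters Filter counts of the two convolutional layers.
#' @param dense_units Units per dense hidden layer.
#' @return An `ee_model` with family `"cnn"`.
#' @export
train_cnn <- function(x, y, seed = 1, epochs = 200, learning_rate = 1e-3,
                      batch_size = 64, val_fraction = 0.1, patience = 20,
                      filters = c(16, 32), dense_units = 16) {
  x <- unclass(as.matrix(x))
  if (ncol(x) != 18L) {
    stop(sprintf(
      "the CNN takes the full 18-wide velocity vector, got %d columns",
      ncol(x)), call. = FALSE)
  }
  check_net_inputs(x, y)
  xs <- fit_scaler(x); ys <- list(center = mean(y), scale = max(stats::sd(y),
                                                                1e-8))
  X <- apply_scaler(xs, x)
  yn <- (y - ys$center) / ys$scale
  params <- with_seed(split_seed(seed, "cnn_init"),
                      cnn_init(filters, dense_units, width = ncol(x)))
  res <- train_net(X, yn, params, cnn_forward, cnn_backward, epochs,
                   learning_rate, batch_size, val_fraction, patience,
                   seed = split_seed(seed, "cnn_train"))
  structure(list(family = "cnn", params = res$params, x_scaler = xs,
                 y_scaler = ys, filters = filters, dense_units = dense_units,
                 input_dim = ncol(x), seed = seed,
                 epochs_run = res$epochs_run),
            class = "ee_model")
}

check_net_inputs <- function(x, y) {
  if (nrow(x) != length(y)) stop("rows and targets misaligned", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("features and targets must be finite", call. = FALSE)
  }
  invisible(NULL)
}

#' Predict METs with a trained regressor
#'
#' @param model An `ee_model` from [train_lr()], [train_mlp()] or
#'   [train_cnn()].
#' @param x Feature matrix with the training dimensionality.
#' @return Numeric vector of MET predictions, one per row.
#' @export
predict_met <- function(model, x) {
  if (!inherits(model, "ee_model")) {
    stop("`model` must be an ee_model", call. = FALSE)
  }
  x <- unclass(as.matrix(x))
  if (ncol(x) != model$input_dim) {
    stop(sprintf("feature count %d does not match training (%d)",
                 ncol(x), model$input_dim), call. = FALSE)
  }
  if (model$family == "lr") {
    return(as.numeric(cbind(1, x) %*% model$coef))
  }
  X <- apply_scaler(model$x_scaler, x)
  fwd <- switch(model$family,
                mlp = mlp_forward(model$params, X),
                cnn = cnn_forward(model$params, X),
                stop("unknown model family", call. = FALSE))
  as.numeric(fwd$yhat) * model$y_scaler$scale + model$y_scaler$center
}

#' @export
print.ee_model <- function(x, ...) {
  desc <- switch(x$family,
    lr = sprintf("OLS, %d features + intercept", x$input_dim),
    mlp = sprintf("MLP %d-[%dx3 logistic]-1", x$input_dim, x$n_nodes),
    cnn = sprintf("CNN 18x1, conv(3)x%d -> pool2 -> conv(3)x%d -> pool2 -> dense %dx2 -> 1",
                  x$filters[1], x$filters[2], x$dense_units))
  cat(sprintf("<ee_model:%s> %s\n", x$family, desc))
  invisible(x)
}

#' Convert a MET quantity to kilocalories
#'
#' By definition 1 MET = 1 kcal per kg of body mass per hour, so a MET value
#' (or MET error) converts to kilocalories as `met * weight * duration`.
#' Bilinear in weight and duration.
#'
#' @param met_value MET value (>= 0).
#' @param weight Body mass, kg (>= 0).
#' @param duration Duration, hours (>= 0).
#' @return Energy in kcal.
#' @export
met_to_kcal <- function(met_value, weight, duration) {
  if (any(met_value < 0) || any(weight < 0) || any(duration < 0)) {
    stop("all arguments must be non-negative", call. = FALSE)
  }
  met_value * weight * duration
}
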