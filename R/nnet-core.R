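# Internal neural-network machinery: Glorot initialisation, Adam updates,
# and forward/backward passes for the MLP and the 1-D CNN.  Everything is
# plain matrix arithmetic so training is bit-reproducible for a fixed seed.

sigmoid <- function(z) 1 / (1 + exp(-z))
relu <- function(z) pmax(z, 0)

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

# ---- MLP: p -> h -> h -> h -> 1, logistic hidden activations, linear output

mlp_init <- function(p, h) {
  list(W1 = glorot(p, h), b1 = rep(0, h),
       W2 = glorot(h, h), b2 = rep(0, h),
       W3 = glorot(h, h), b3 = rep(0, h),
       W4 = glorot(h, 1), b4 = 0)
}

mlp_forward <- function(params, X, cache = FALSE) {
  A1 <- sigmoid(sweep(X %*% params$W1, 2, params$b1, "+"))
  A2 <- sigmoid(sweep(A1 %*% params$W2, 2, params$b2, "+"))
  A3 <- sigmoid(sweep(A2 %*% params$W3, 2, params$b3, "+"))
  yhat <- A3 %*% params$W4 + params$b4
  list(A1 = A1, A2 = A2, A3 = A3, yhat = yhat)
}

mlp_backward <- function(params, X, y, fwd) {
  n <- nrow(X)
  dy <- 2 * (fwd$yhat - y) / n
  dW4 <- crossprod(fwd$A3, dy); db4 <- sum(dy)
  dA3 <- dy %*% t(params$W4)
  dZ3 <- dA3 * fwd$A3 * (1 - fwd$A3)
  dW3 <- crossprod(fwd$A2, dZ3); db3 <- colSums(dZ3)
  dA2 <- dZ3 %*% t(params$W3)
  dZ2 <- dA2 * fwd$A2 * (1 - fwd$A2)
  dW2 <- crossprod(fwd$A1, dZ2); db2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(params$W2)
  dZ1 <- dA1 * fwd$A1 * (1 - fwd$A1)
  dW1 <- crossprod(X, dZ1); db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
}

# ---- CNN on an 18 x 1 input: conv(3, F1) -> maxpool(2) -> conv(3, F2)
# ---- -> maxpool(2) -> dense 16 -> dense 16 -> 1.  Convolutions use
# ---- same-padding along the 18-long feature axis (length-3 kernels).

cnn_init <- function(filters = c(16, 32), dense_units = 16, width = 18) {
  F1 <- filters[1]; F2 <- filters[2]
  flat <- (width %/% 2 %/% 2) * F2
  list(W1 = glorot(3, F1), b1 = rep(0, F1),
       W2 = glorot(3 * F1, F2, c(3 * F1, F2)), b2 = rep(0, F2),
       Wd1 = glorot(flat, dense_units), bd1 = rep(0, dense_units),
       Wd2 = glorot(dense_units, dense_units), bd2 = rep(0, dense_units),
       Wo = glorot(dense_units, 1), bo = 0)
}

cnn_forward <- function(params, X, cache = FALSE) {
  B <- nrow(X); W <- ncol(X)
  F1 <- length(params$b1); F2 <- length(params$b2)
  P <- W %/% 2          # pooled length after pool 1
  Q <- P %/% 2          # pooled length after pool 2
  Xp <- cbind(0, X, 0)
  P1 <- matrix(Xp[, c(outer(seq_len(W), 0:2, "+"))], B * W, 3)
  Z1 <- sweep(P1 %*% params$W1, 2, params$b1, "+")
  A1 <- array(relu(Z1), c(B, W, F1))
  odd1 <- seq(1, 2 * P - 1, 2)
  mask1 <- (A1[, odd1, , drop = FALSE] >= A1[, odd1 + 1, , drop = FALSE]) * 1
  o1 <- pmax(A1[, odd1, , drop = FALSE], A1[, odd1 + 1, , drop = FALSE])
  Ap <- array(0, c(B, P + 2, F1))
  Ap[, 2:(P + 1), ] <- o1
  a2 <- array(Ap[, c(outer(seq_len(P), 0:2, "+")), , drop = FALSE],
              c(B, P, 3, F1))
  P2 <- array(a2, c(B * P, 3 * F1))
  Z2 <- sweep(P2 %*% params$W2, 2, params$b2, "+")
  A2 <- array(relu(Z2), c(B, P, F2))
  odd2 <- seq(1, 2 * Q - 1, 2)
  mask2 <- (A2[, odd2, , drop = FALSE] >= A2[, odd2 + 1, , drop = FALSE]) * 1
  o2 <- pmax(A2[, odd2, , drop = FALSE], A2[, odd2 + 1, , drop = FALSE])
  Fl <- array(o2, c(B, Q * F2))
  H1 <- relu(sweep(Fl %*% params$Wd1, 2, params$bd1, "+"))
  H2 <- relu(sweep(H1 %*% params$Wd2, 2, params$bd2, "+"))
  yhat <- H2 %*% params$Wo + params$bo
  if (!cache) return(list(yhat = yhat))
  list(yhat = yhat, P1 = P1, Z1 = Z1, mask1 = mask1, P2 = P2, Z2 = Z2,
       mask2 = mask2, Fl = Fl, H1 = H1, H2 = H2,
       dims = list(B = B, W = W, P = P, Q = Q, F1 = F1, F2 = F2))
}

cnn_backward <- function(params, X, y, fwd) {
  d <- fwd$dims
  B <- d$B; W <- d$W; P <- d$P; Q <- d$Q; F1 <- d$F1; F2 <- d$F2
  dy <- 2 * (fwd$yhat - y) / B
  dWo <- crossprod(fwd$H2, dy); dbo <- sum(dy)
  dH2 <- (dy %*% t(params$Wo)) * (fwd$H2 > 0)
  dWd2 <- crossprod(fwd$H1, dH2); dbd2 <- colSums(dH2)
  dH1 <- (dH2 %*% t(params$Wd2)) * (fwd$H1 > 0)
  dWd1 <- crossprod(fwd$Fl, dH1); dbd1 <- colSums(dH1)
  dFl <- dH1 %*% t(params$Wd1)
  dO2 <- array(dFl, c(B, Q, F2))
  dA2 <- array(0, c(B, P, F2))
  odd2 <- seq(1, 2 * Q - 1, 2)
  dA2[, odd2, ] <- dO2 * fwd$mask2
  dA2[, odd2 + 1, ] <- dO2 * (1 - fwd$mask2)
  dZ2 <- array(dA2, c(B * P, F2)) * (fwd$Z2 > 0)
  dW2 <- crossprod(fwd$P2, dZ2); db2 <- colSums(dZ2)
  dP2 <- array(dZ2 %*% t(params$W2), c(B, P, 3, F1))
  dAp <- array(0, c(B, P + 2, F1))
  for (tp in 1:3) {
    dAp[, tp:(tp + P - 1), ] <- dAp[, tp:(tp + P - 1), ] +
      array(dP2[, , tp, , drop = FALSE], c(B, P, F1))
  }
  dO1 <- dAp[, 2:(P + 1), , drop = FALSE]
  dA1 <- array(0, c(B, W, F1))
  odd1 <- seq(1, 2 * P - 1, 2)
  dA1[, odd1, ] <- dO1 * fwd$mask1
  dA1[, odd1 + 1, ] <- dO1 * (1 - fwd$mask1)
  dZ1 <- array(dA1, c(B * W, F1)) * (fwd$Z1 > 0)
  dW1 <- crossprod(fwd$P1, dZ1); db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       Wd1 = dWd1, bd1 = dbd1, Wd2 = dWd2, bd2 = dbd2,
       Wo = dWo, bo = dbo)
}

# Shared mini-batch Adam training loop with early stopping on a validation
# split carved from the training rows.
train_net <- function(X, y, params, forward, backward, epochs, lr,
                      batch_size, val_fraction, patience, seed) {
  n <- nrow(X)
  set.seed(seed)
  n_val <- if (val_fraction > 0 && n >= 20) max(1L, round(n * val_fraction))
           else 0L
  idx <- sample.int(n)
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- if (n_val) idx[-seq_len(n_val)] else idx
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]
  state <- adam_init(params)
  best <- params; best_loss <- Inf; wait <- 0
  ntr <- nrow(Xtr)
  bs <- min(batch_size, ntr)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(ntr)
    for (start in seq(1, ntr, by = bs)) {
      b <- ord[start:min(start + bs - 1, ntr)]
      fwd <- forward(params, Xtr[b, , drop = FALSE], cache = TRUE)
      grads <- backward(params, Xtr[b, , drop = FALSE], ytr[b], fwd)
      upd <- adam_step(state, params, grads, lr)
      state <- upd$state; params <- upd$params
    }
    mon_X <- if (n_val) Xval else Xtr
    mon_y <- if (n_val) yval else ytr
    loss <- mean((forward(params, mon_X)$yhat - mon_y)^2)
    if (loss < best_loss - 1e-9) {
      best_loss <- loss; best <- params; wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  list(params = best, val_loss = best_loss, epochs_run = ep)
}
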