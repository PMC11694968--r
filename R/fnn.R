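# Single-hidden-layer feedforward network for binary classification,
# trained with Adam on a class-weighted loss. Written in plain matrix R:
# one hidden tanh layer, inverted dropout between hidden and output, a
# sigmoid output unit, and a squared-L2 penalty on the weights. Weight
# initialization is uniform fan-in; all randomness (init, batch shuffling,
# dropout masks) flows from one seed, so a fit is exactly reproducible.

sigmoid <- function(z) 1 / (1 + exp(-z))

fnn_fit <- function(X, y, class_weights,
                    hidden_units = 10L, dropout = 0.6, epochs = 20L,
                    learning_rate = 0.001, batch_size = 32L, l2 = 1e-4,
                    loss = c("bce", "squared"), seed = 1L) {
  loss <- match.arg(loss)
  set.seed(seed)
  n <- nrow(X)
  d <- ncol(X)
  H <- hidden_units
  keep <- 1 - dropout

  lim1 <- 1 / sqrt(d)
  W1 <- matrix(stats::runif(d * H, -lim1, lim1), d, H)
  b1 <- numeric(H)
  lim2 <- 1 / sqrt(H)
  W2 <- matrix(stats::runif(H, -lim2, lim2), H, 1)
  b2 <- 0

  sw <- unname(class_weights[as.character(y)])
  # Adam state per parameter
  m <- list(W1 = W1 * 0, b1 = b1 * 0, W2 = W2 * 0, b2 = 0)
  v <- m
  beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-8
  t <- 0

  full_loss <- function() {
    p <- fnn_forward(X, W1, b1, W2, b2)
    eps <- 1e-12
    base <- if (loss == "bce") {
      -sum(sw * (y * log(p + eps) + (1 - y) * log(1 - p + eps))) / sum(sw)
    } else {
      sum(sw * (p - y)^2) / sum(sw)
    }
    base + l2 * (sum(W1^2) + sum(W2^2))
  }

  loss_history <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      bi <- idx[s:min(s + batch_size - 1L, n)]
      Xb <- X[bi, , drop = FALSE]
      yb <- y[bi]
      swb <- sw[bi]

      Z1 <- sweep(Xb %*% W1, 2, b1, `+`)
      A1 <- tanh(Z1)
      mask <- matrix(stats::runif(length(A1)) < keep, nrow(A1), ncol(A1)) / keep
      A1d <- A1 * mask
      p <- drop(sigmoid(A1d %*% W2 + b2))

      wsum <- sum(swb)
      g2 <- if (loss == "bce") {
        swb * (p - yb) / wsum
      } else {
        swb * 2 * (p - yb) * p * (1 - p) / wsum
      }
      gW2 <- crossprod(A1d, g2) + 2 * l2 * W2
      gb2 <- sum(g2)
      g1 <- (g2 %*% t(W2)) * mask * (1 - A1^2)
      gW1 <- crossprod(Xb, g1) + 2 * l2 * W1
      gb1 <- colSums(g1)

      t <- t + 1
      upd <- function(mm, vv, g) {
        mm <- beta1 * mm + (1 - beta1) * g
        vv <- beta2 * vv + (1 - beta2) * g^2
        mhat <- mm / (1 - beta1^t)
        vhat <- vv / (1 - beta2^t)
        list(m = mm, v = vv, step = learning_rate * mhat / (sqrt(vhat) + aeps))
      }
      u <- upd(m$W1, v$W1, gW1); m$W1 <- u$m; v$W1 <- u$v; W1 <- W1 - u$step
      u <- upd(m$b1, v$b1, gb1); m$b1 <- u$m; v$b1 <- u$v; b1 <- b1 - u$step
      u <- upd(m$W2, v$W2, gW2); m$W2 <- u$m; v$W2 <- u$v; W2 <- W2 - u$step
      u <- upd(m$b2, v$b2, gb2); m$b2 <- u$m; v$b2 <- u$v; b2 <- b2 - u$step
    }
    loss_history[epoch] <- full_loss()
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, loss_history = loss_history,
       loss = loss)
}

fnn_forward <- function(X, W1, b1, W2, b2) {
  A1 <- tanh(sweep(X %*% W1, 2, b1, `+`))
  drop(sigmoid(A1 %*% W2 + b2))
}

# Deterministic inference: dropout is inverted at train time, so prediction
# uses the weights as-is.
fnn_predict <- function(fit, X) {
  fnn_forward(X, fit$W1, fit$b1, fit$W2, fit$b2)
}
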