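# Minimal recurrent networks for the wrist -> reference correction stage.
# Plain-R matrix implementations (BPTT + Adam) sized for short univariate
# heart-rate windows; inputs and targets are min-max normalized to [0, 1]
# and both nets end in a sigmoid head.

sigmoid <- function(z) 1 / (1 + exp(-z))

adam_state <- function(shapes) {
  lapply(shapes, function(s) list(m = array(0, dim = s), v = array(0, dim = s)))
}

adam_update <- function(param, grad, state, lr, beta1, beta2, eps = 1e-8, t) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

glorot <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
}

net_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

#' @noRd
rnn_fit <- function(X, y, hidden = 8L, epochs = 15L, batch_size = 64L,
                    lr = 0.1, beta1 = 0.5, beta2 = 0.999, seed = 1L) {
  withr::with_seed(seed, {
    H <- hidden
    Tlen <- ncol(X)
    W <- list(Wxh = glorot(1, H), Whh = glorot(H, H), bh = matrix(0, 1, H),
              Why = glorot(H, 1), by = matrix(0, 1, 1))
    st <- adam_state(lapply(W, dim))
    step <- 0L
    epoch_loss <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      losses <- c()
      for (b in net_batches(nrow(X), batch_size)) {
        xb <- X[b, , drop = FALSE]
        yb <- y[b]
        B <- length(b)
        hs <- vector("list", Tlen + 1L)
        hs[[1]] <- matrix(0, B, H)
        for (t in seq_len(Tlen)) {
          hs[[t + 1L]] <- tanh(xb[, t, drop = FALSE] %*% W$Wxh +
                               hs[[t]] %*% W$Whh +
                               matrix(W$bh, B, H, byrow = TRUE))
        }
        yhat <- sigmoid(hs[[Tlen + 1L]] %*% W$Why + W$by[1, 1])
        losses <- c(losses, mean((yhat - yb)^2))
        dz <- (2 * (yhat - yb) / B) * yhat * (1 - yhat)
        g <- list(Wxh = 0 * W$Wxh, Whh = 0 * W$Whh, bh = 0 * W$bh,
                  Why = crossprod(hs[[Tlen + 1L]], dz), by = matrix(sum(dz), 1, 1))
        dh <- dz %*% t(W$Why)
        for (t in rev(seq_len(Tlen))) {
          dpre <- dh * (1 - hs[[t + 1L]]^2)
          g$Wxh <- g$Wxh + crossprod(xb[, t, drop = FALSE], dpre)
          g$Whh <- g$Whh + crossprod(hs[[t]], dpre)
          g$bh <- g$bh + matrix(colSums(dpre), 1, H)
          dh <- dpre %*% t(W$Whh)
        }
        step <- step + 1L
        for (nm in names(W)) {
          upd <- adam_update(W[[nm]], g[[nm]], st[[nm]], lr, beta1, beta2, t = step)
          W[[nm]] <- upd$param
          st[[nm]] <- upd$state
        }
      }
      epoch_loss[ep] <- mean(losses)
    }
    structure(list(weights = W, hidden = H, window = Tlen,
                   epoch_loss = epoch_loss), class = "wristhrv_rnn")
  })
}

#' @noRd
rnn_predict <- function(model, X) {
  W <- model$weights
  B <- nrow(X)
  h <- matrix(0, B, model$hidden)
  for (t in seq_len(ncol(X))) {
    h <- tanh(X[, t, drop = FALSE] %*% W$Wxh + h %*% W$Whh +
              matrix(W$bh, B, model$hidden, byrow = TRUE))
  }
  as.numeric(sigmoid(h %*% W$Why + W$by[1, 1]))
}

#' @noRd
lstm_fit <- function(X, y, hidden = 8L, dense_units = 8L, dropout = 0.2,
                     epochs = 15L, batch_size = 64L,
                     lr = 0.1, beta1 = 0.5, beta2 = 0.999, seed = 1L) {
  withr::with_seed(seed, {
    H <- hidden
    D <- dense_units
    Tlen <- ncol(X)
    W <- list(Wx = glorot(1, 4 * H), Wh = glorot(H, 4 * H), b = matrix(0, 1, 4 * H),
              W1 = glorot(H, D), b1 = matrix(0, 1, D),
              W2 = glorot(D, 1), b2 = matrix(0, 1, 1))
    # forget-gate bias starts at 1 (standard LSTM initialization)
    W$b[1, (H + 1):(2 * H)] <- 1
    st <- adam_state(lapply(W, dim))
    step <- 0L
    epoch_loss <- numeric(epochs)
    gi <- 1:H; gf <- (H + 1):(2 * H); go <- (2 * H + 1):(3 * H); gg <- (3 * H + 1):(4 * H)
    for (ep in seq_len(epochs)) {
      losses <- c()
      for (b in net_batches(nrow(X), batch_size)) {
        xb <- X[b, , drop = FALSE]
        yb <- y[b]
        B <- length(b)
        hs <- cs <- is <- fs <- os <- gs <- vector("list", Tlen + 1L)
        hs[[1]] <- cs[[1]] <- matrix(0, B, H)
        for (t in seq_len(Tlen)) {
          z <- xb[, t, drop = FALSE] %*% W$Wx + hs[[t]] %*% W$Wh +
            matrix(W$b, B, 4 * H, byrow = TRUE)
          is[[t + 1L]] <- sigmoid(z[, gi, drop = FALSE])
          fs[[t + 1L]] <- sigmoid(z[, gf, drop = FALSE])
          os[[t + 1L]] <- sigmoid(z[, go, drop = FALSE])
          gs[[t + 1L]] <- tanh(z[, gg, drop = FALSE])
          cs[[t + 1L]] <- fs[[t + 1L]] * cs[[t]] + is[[t + 1L]] * gs[[t + 1L]]
          hs[[t + 1L]] <- os[[t + 1L]] * tanh(cs[[t + 1L]])
        }
        # inverted dropout on the recurrent output and the first dense layer
        m1 <- matrix(stats::rbinom(B * H, 1, 1 - dropout) / (1 - dropout), B, H)
        m2 <- matrix(stats::rbinom(B * D, 1, 1 - dropout) / (1 - dropout), B, D)
        u <- hs[[Tlen + 1L]] * m1
        a1 <- sigmoid(u %*% W$W1 + matrix(W$b1, B, D, byrow = TRUE))
        a1d <- a1 * m2
        yhat <- sigmoid(a1d %*% W$W2 + W$b2[1, 1])
        losses <- c(losses, mean((yhat - yb)^2))

        dz2 <- (2 * (yhat - yb) / B) * yhat * (1 - yhat)
        g <- list(Wx = 0 * W$Wx, Wh = 0 * W$Wh, b = 0 * W$b,
                  W1 = NULL, b1 = NULL,
                  W2 = crossprod(a1d, dz2), b2 = matrix(sum(dz2), 1, 1))
        da1 <- (dz2 %*% t(W$W2)) * m2 * a1 * (1 - a1)
        g$W1 <- crossprod(u, da1)
        g$b1 <- matrix(colSums(da1), 1, D)
        dh <- (da1 %*% t(W$W1)) * m1
        dc <- matrix(0, B, H)
        for (t in rev(seq_len(Tlen))) {
          tc <- tanh(cs[[t + 1L]])
          i <- is[[t + 1L]]; f <- fs[[t + 1L]]; o <- os[[t + 1L]]; gg_ <- gs[[t + 1L]]
          do_ <- dh * tc
          dc <- dc + dh * o * (1 - tc^2)
          dzi <- (dc * gg_) * i * (1 - i)
          dzf <- (dc * cs[[t]]) * f * (1 - f)
          dzo <- do_ * o * (1 - o)
          dzg <- (dc * i) * (1 - gg_^2)
          dz <- cbind(dzi, dzf, dzo, dzg)
          g$Wx <- g$Wx + crossprod(xb[, t, drop = FALSE], dz)
          g$Wh <- g$Wh + crossprod(hs[[t]], dz)
          g$b <- g$b + matrix(colSums(dz), 1, 4 * H)
          dh <- dz %*% t(W$Wh)
          dc <- dc * f
        }
        step <- step + 1L
        for (nm in names(W)) {
          upd <- adam_update(W[[nm]], g[[nm]], st[[nm]], lr, beta1, beta2, t = step)
          W[[nm]] <- upd$param
          st[[nm]] <- upd$state
        }
      }
      epoch_loss[ep] <- mean(losses)
    }
    structure(list(weights = W, hidden = H, dense_units = D, window = Tlen,
                   epoch_loss = epoch_loss), class = "wristhrv_lstm")
  })
}

#' @noRd
lstm_predict <- function(model, X) {
  W <- model$weights
  H <- model$hidden
  B <- nrow(X)
  gi <- 1:H; gf <- (H + 1):(2 * H); go <- (2 * H + 1):(3 * H); gg <- (3 * H + 1):(4 * H)
  h <- cmat <- matrix(0, B, H)
  for (t in seq_len(ncol(X))) {
    z <- X[, t, drop = FALSE] %*% W$Wx + h %*% W$Wh + matrix(W$b, B, 4 * H, byrow = TRUE)
    i <- sigmoid(z[, gi, drop = FALSE]); f <- sigmoid(z[, gf, drop = FALSE])
    o <- sigmoid(z[, go, drop = FALSE]); g <- tanh(z[, gg, drop = FALSE])
    cmat <- f * cmat + i * g
    h <- o * tanh(cmat)
  }
  a1 <- sigmoid(h %*% W$W1 + matrix(W$b1, B, model$dense_units, byrow = TRUE))
  as.numeric(sigmoid(a1 %*% W$W2 + W$b2[1, 1]))
}

# Sliding windows of the wrist series per subject (stride 1), target = the
# aligned reference value at the window end; the first window-1 positions are
# left-padded with each subject's first value so every row gets a window.
build_windows <- function(wrist, subject_ids, window = 10L) {
  out <- matrix(0, length(wrist), window)
  for (s in unique(subject_ids)) {
    rows <- which(subject_ids == s)
    x <- wrist[rows]
    padded <- c(rep(x[1], window - 1L), x)
    for (j in seq_along(rows)) {
      out[rows[j], ] <- padded[j:(j + window - 1L)]
    }
  }
  out
}
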