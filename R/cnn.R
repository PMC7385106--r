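# Compact convolutional regressor: conv(1->16, 5x5, stride 1, pad 2) +
# ReLU + 2x2 max-pool, conv(16->32, 5x5, stride 1, pad 2) + ReLU + 2x2
# max-pool, fully connected 32*(D/4)^2 -> 1, squared-error loss.
#
# Convolutions are evaluated as im2col matrix products. Activation matrices
# between stages have rows indexed (sample b, spatial position p) with b
# fastest: row = b + (p - 1) * B. All geometry (patch-gather indices, pool
# windows, the col2im scatter matrix) is precomputed per D at build time.

#' Build the MLI convolutional regressor (untrained)
#'
#' Constructs the network mapping a `D x D` neighborhood feature matrix to a
#' scalar influence score: two 5x5 convolution blocks (1->16 and 16->32
#' channels, stride 1, padding 2, ReLU, 2x2 max-pooling each) followed by a
#' fully connected layer of input size `32 * (D/4)^2`. Weights use seeded
#' He-normal initialization; biases start at zero.
#'
#' @param D side length of the input feature matrix; must be divisible by 4
#'   (two 2x2 poolings).
#' @param seed integer seed for weight initialization.
#' @return An object of class `mli_regressor`: weights `W1, b1, W2, b2, W3,
#'   b3`, the architecture record `spec`, and precomputed layer geometry.
#' @export
#' @examples
#' reg <- build_regressor(8, seed = 1)
#' reg$spec$fc_in  # 128
build_regressor <- function(D, seed = 1L) {
  D <- as.integer(D)
  if (is.na(D) || D < 4L || D %% 4L != 0L)
    stop("`D` must be a positive multiple of 4 (two 2x2 poolings)")
  geom <- cnn_geometry(D)
  fc_in <- 32L * (D %/% 4L)^2
  weights <- withr::with_seed(seed, list(
    W1 = matrix(stats::rnorm(25L * 16L, sd = sqrt(2 / 25)), 25L, 16L),
    b1 = numeric(16L),
    W2 = matrix(stats::rnorm(400L * 32L, sd = sqrt(2 / 400)), 400L, 32L),
    b2 = numeric(32L),
    W3 = matrix(stats::rnorm(fc_in, sd = sqrt(2 / fc_in)), fc_in, 1L),
    b3 = 0))
  structure(
    c(weights,
      list(spec = list(D = D, kernel = 5L, channels = c(16L, 32L),
                       pool = 2L, fc_in = fc_in),
           geom = geom)),
    class = "mli_regressor")
}

#' @export
print.mli_regressor <- function(x, ...) {
  cat(sprintf(paste0("mli_regressor: D=%d, conv 1->16 and 16->32 (5x5, pad 2),",
                     " 2x2 max-pools, FC %d -> 1\n"),
              x$spec$D, x$spec$fc_in))
  invisible(x)
}

# ---- geometry ------------------------------------------------------------

cnn_geometry <- function(D) {
  S1 <- D
  S2 <- D %/% 2L   # side after pool1 == conv2 input/output side
  Q2 <- D %/% 4L   # side after pool2
  g1 <- conv_patch_idx(S1)                       # single input channel
  g2 <- conv_patch_idx(S2)
  pad2_area <- (S2 + 4L)^2
  # conv2 gathers 5x5 patches from all 16 channels of the padded input:
  # column (k, c) -> padded index I2[p, k] + (c - 1) * pad2_area
  idxcols2 <- matrix(0L, S2^2, 25L * 16L)
  for (cc in seq_len(16L))
    idxcols2[, (cc - 1L) * 25L + seq_len(25L)] <-
      g2$patch + (cc - 1L) * pad2_area
  int2full <- as.integer(outer(g2$interior, (seq_len(16L) - 1L) * pad2_area,
                               "+"))
  scatter2 <- Matrix::sparseMatrix(
    i = seq_len(length(idxcols2)), j = as.vector(idxcols2), x = 1,
    dims = c(length(idxcols2), pad2_area * 16L))
  list(S1 = S1, S2 = S2, Q1 = S2, Q2 = Q2,
       patch1 = g1$patch, int1 = g1$interior,
       idxcols2 = idxcols2, int2full = int2full, scatter2 = scatter2,
       pool1 = pool_window_idx(S1), pool2 = pool_window_idx(S2))
}

# 5x5 patch-gather indices for a side-S image with padding 2: entry [p, k]
# is the column-major index into the padded (S+4)^2 image feeding output
# position p through kernel element k.
conv_patch_idx <- function(S) {
  P <- S + 4L
  patch <- matrix(0L, S * S, 25L)
  interior <- integer(S * S)
  for (j in seq_len(S)) {
    for (i in seq_len(S)) {
      p <- i + (j - 1L) * S
      interior[p] <- (i + 2L) + (j + 1L) * P
      for (b in 0:4)
        for (a in 0:4)
          patch[p, (a + 1L) + b * 5L] <- (i + a) + (j + b - 1L) * P
    }
  }
  list(patch = patch, interior = interior)
}

# 2x2 pooling windows on a side-S image: entry [w, q] is the input position
# feeding window slot w of pooled position q.
pool_window_idx <- function(S) {
  Q <- S %/% 2L
  pos <- matrix(0L, 4L, Q * Q)
  for (qj in seq_len(Q)) {
    for (qi in seq_len(Q)) {
      q <- qi + (qj - 1L) * Q
      rr <- c(2L * qi - 1L, 2L * qi, 2L * qi - 1L, 2L * qi)
      cc <- c(2L * qj - 1L, 2L * qj - 1L, 2L * qj, 2L * qj)
      pos[, q] <- rr + (cc - 1L) * S
    }
  }
  pos
}

# (b, p)-row gather indices for one pooling layer at batch size B
pool_row_idx <- function(pos, B) {
  lapply(seq_len(4L), function(w)
    as.vector(outer(seq_len(B), (pos[w, ] - 1L) * B, "+")))
}

# ---- forward / backward --------------------------------------------------

# X: B x D^2 matrix of flattened feature matrices (column-major pixels)
cnn_forward <- function(model, X, keep = FALSE) {
  g <- model$geom
  B <- nrow(X)
  pad1 <- matrix(0, B, (g$S1 + 4L)^2)
  pad1[, g$int1] <- X
  M1 <- matrix(array(pad1[, as.vector(g$patch1)], c(B, g$S1^2, 25L)),
               B * g$S1^2, 25L)
  C1 <- M1 %*% model$W1 + rep(model$b1, each = B * g$S1^2)
  R1 <- C1 * (C1 > 0)
  ridx1 <- pool_row_idx(g$pool1, B)
  p1 <- max_pool_forward(R1, ridx1)
  # conv2 over the padded 16-channel pooled map
  a2flat <- matrix(array(p1$pooled, c(B, g$Q1^2, 16L)), B, g$Q1^2 * 16L)
  pad2 <- matrix(0, B, (g$S2 + 4L)^2 * 16L)
  pad2[, g$int2full] <- a2flat
  M2 <- matrix(array(pad2[, as.vector(g$idxcols2)], c(B, g$S2^2, 400L)),
               B * g$S2^2, 400L)
  C2 <- M2 %*% model$W2 + rep(model$b2, each = B * g$S2^2)
  R2 <- C2 * (C2 > 0)
  ridx2 <- pool_row_idx(g$pool2, B)
  p2 <- max_pool_forward(R2, ridx2)
  fc_in <- matrix(array(p2$pooled, c(B, g$Q2^2, 32L)), B, g$Q2^2 * 32L)
  out <- as.numeric(fc_in %*% model$W3 + model$b3)
  if (!keep) return(list(out = out))
  list(out = out,
       cache = list(B = B, M1 = M1, C1 = C1, ridx1 = ridx1, am1 = p1$argmax,
                    M2 = M2, C2 = C2, ridx2 = ridx2, am2 = p2$argmax,
                    fc_in = fc_in))
}

max_pool_forward <- function(act, ridx) {
  cur <- act[ridx[[1L]], , drop = FALSE]
  am <- matrix(1L, nrow(cur), ncol(cur))
  for (w in 2:4) {
    cand <- act[ridx[[w]], , drop = FALSE]
    upd <- cand > cur
    cur[upd] <- cand[upd]
    am[upd] <- w
  }
  list(pooled = cur, argmax = am)
}

max_pool_backward <- function(dpooled, am, ridx, n_rows) {
  dact <- matrix(0, n_rows, ncol(dpooled))
  for (w in 1:4)  # window slots partition the input positions: no collisions
    dact[ridx[[w]], ] <- dpooled * (am == w)
  dact
}

# dout: gradient of the loss w.r.t. the B network outputs
cnn_backward <- function(model, cache, dout) {
  g <- model$geom
  B <- cache$B
  dout <- matrix(dout, ncol = 1L)
  dW3 <- crossprod(cache$fc_in, dout)
  db3 <- sum(dout)
  dfc <- dout %*% t(model$W3)
  dp2 <- matrix(array(dfc, c(B, g$Q2^2, 32L)), B * g$Q2^2, 32L)
  dR2 <- max_pool_backward(dp2, cache$am2, cache$ridx2, B * g$S2^2)
  dC2 <- dR2 * (cache$C2 > 0)
  dW2 <- crossprod(cache$M2, dC2)
  db2 <- colSums(dC2)
  dM2 <- dC2 %*% t(model$W2)
  dpad2 <- as.matrix(matrix(array(dM2, c(B, g$S2^2, 400L)),
                            B, g$S2^2 * 400L) %*% g$scatter2)
  dp1 <- matrix(array(dpad2[, g$int2full], c(B, g$Q1^2, 16L)),
                B * g$Q1^2, 16L)
  dR1 <- max_pool_backward(dp1, cache$am1, cache$ridx1, B * g$S1^2)
  dC1 <- dR1 * (cache$C1 > 0)
  list(W1 = crossprod(cache$M1, dC1), b1 = colSums(dC1),
       W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

# ---- training ------------------------------------------------------------

#' Train the convolutional regressor on feature matrices and labels
#'
#' Minimizes the mean squared error between network outputs and labels with
#' Adam (learning rate `lr`, default 1e-3), shuffled mini-batches and a
#' seeded random stream, recording the mean training loss per epoch.
#'
#' @param model an untrained (or previously trained) [build_regressor()]
#'   object.
#' @param features numeric array `n x D x D` (or `n x D^2` matrix) of
#'   per-node feature matrices, already on a common scale.
#' @param labels numeric vector of length `n` of regression targets.
#' @param epochs number of passes over the data.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param seed integer seed controlling shuffling (initialization was seeded
#'   at build time).
#' @return List with `model` (trained `mli_regressor`) and `history`
#'   (per-epoch mean squared error).
#' @export
train_regressor <- function(model, features, labels, epochs = 200L,
                            batch_size = 32L, lr = 1e-3, seed = 1L) {
  stopifnot(inherits(model, "mli_regressor"))
  D <- model$spec$D
  X <- flatten_features(features, D)
  n <- nrow(X)
  if (length(labels) != n)
    stop("need exactly one label per feature matrix")
  history <- numeric(epochs)
  adam <- adam_init(model)
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      ep_loss <- 0
      for (s0 in starts) {
        idx <- perm[s0:min(s0 + batch_size - 1L, n)]
        fw <- cnn_forward(model, X[idx, , drop = FALSE], keep = TRUE)
        resid <- fw$out - labels[idx]
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop(sprintf(
            "training diverged: non-finite loss at epoch %d; lower `lr`", ep))
        ep_loss <- ep_loss + loss * length(idx)
        grads <- cnn_backward(model, fw$cache, 2 * resid / length(idx))
        st <- adam_step(model, grads, adam, lr)
        model <- st$model
        adam <- st$state
      }
      history[ep] <- ep_loss / n
    }
  })
  list(model = model, history = history)
}

#' Score feature matrices with a trained regressor
#'
#' One forward pass per feature matrix; deterministic given the weights.
#'
#' @inheritParams train_regressor
#' @return Numeric vector of predicted scores.
#' @export
predict_regressor <- function(model, features) {
  stopifnot(inherits(model, "mli_regressor"))
  X <- flatten_features(features, model$spec$D)
  cnn_forward(model, X)$out
}

flatten_features <- function(features, D) {
  if (is.matrix(features) && ncol(features) == D^2)
    return(features)
  dm <- dim(features)
  if (length(dm) == 3L && dm[2L] == D && dm[3L] == D)
    return(matrix(features, dm[1L], D^2))
  if (length(dm) == 2L && all(dm == D))  # a single feature matrix
    return(matrix(as.numeric(features), 1L, D^2))
  stop(sprintf("features do not match the model's D = %d", D))
}

adam_init <- function(model) {
  zero <- lapply(model[c("W1", "b1", "W2", "b2", "W3", "b3")],
                 function(p) p * 0)
  list(m = zero, v = zero, t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(model, grads, state, lr) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g^2
    model[[nm]] <- model[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + state$eps)
  }
  list(model = model, state = state)
}
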