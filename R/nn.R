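# Pure-R reference implementation of the network forward/backward pass and
# Adam, kept independent of the compiled engine (src/engine.cpp) so the two
# can be cross-checked in the test suite: 1-D convolution via im2col + BLAS
# matrix products, max-pooling, dense layers, inverted dropout, softmax
# cross-entropy.  Activations for a batch are stored "stacked":
# a (batch * length) x channels matrix whose row (b - 1) * L + l is sample
# b at position l, so convolution and pooling reduce to row indexing plus
# one matrix product per layer.

# --- layout helpers ---------------------------------------------------------

# Row indices of positions k..k+L-1 of every sample in a (B * Lp)-row stack.
stack_rows <- function(first, len, block, B) {
  as.vector(outer(first:(first + len - 1L), (0:(B - 1L)) * block, "+"))
}

# B x D matrix (one row per sample) from a stacked (B * L) x C matrix.
stack_to_flat <- function(X, L, B, C) {
  t(matrix(aperm(array(X, c(L, B, C)), c(1, 3, 2)), nrow = L * C, ncol = B))
}

flat_to_stack <- function(F_, L, B, C) {
  matrix(aperm(array(t(F_), c(L, C, B)), c(1, 3, 2)), nrow = L * B, ncol = C)
}

# --- layers -----------------------------------------------------------------

# Same-padding 1-D convolution. X: (B*L) x C_in stacked; W: (KS*C_in) x KC.
conv1d_forward <- function(X, W, b, B, L, KS) {
  C <- ncol(X)
  pad <- (KS - 1L) %/% 2L
  Lp <- L + 2L * pad
  Xp <- matrix(0, nrow = B * Lp, ncol = C)
  rows_x <- stack_rows(pad + 1L, L, Lp, B)
  Xp[rows_x, ] <- X
  Xcol <- matrix(0, nrow = B * L, ncol = KS * C)
  for (k in seq_len(KS)) {
    Xcol[, ((k - 1L) * C + 1L):(k * C)] <- Xp[stack_rows(k, L, Lp, B), ]
  }
  Y <- Xcol %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, Xcol = Xcol, B = B, L = L, KS = KS, C = C, pad = pad, Lp = Lp,
       rows_x = rows_x)
}

conv1d_backward <- function(dY, W, cache) {
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- tcrossprod(dY, W)
  dXp <- matrix(0, nrow = cache$B * cache$Lp, ncol = cache$C)
  for (k in seq_len(cache$KS)) {
    idx <- stack_rows(k, cache$L, cache$Lp, cache$B)
    dXp[idx, ] <- dXp[idx, ] +
      dXcol[, ((k - 1L) * cache$C + 1L):(k * cache$C)]
  }
  list(dX = dXp[cache$rows_x, , drop = FALSE], dW = dW, db = db)
}

# Max-pool, size 2 / stride 2, trailing odd sample dropped; ties keep the
# earlier position (deterministic backward routing).
pool2_forward <- function(X, B, L) {
  Lo <- L %/% 2L
  a_idx <- stack_rows(1L, 2L * Lo, L, B)
  a_idx <- a_idx[seq(1L, length(a_idx), by = 2L)]
  b_idx <- a_idx + 1L
  Xa <- X[a_idx, , drop = FALSE]
  Xb <- X[b_idx, , drop = FALSE]
  take_a <- Xa >= Xb
  Y <- Xa
  Y[!take_a] <- Xb[!take_a]
  list(Y = Y, take_a = take_a, a_idx = a_idx, b_idx = b_idx, B = B, L = L,
       Lo = Lo, C = ncol(X))
}

pool2_backward <- function(dY, cache) {
  dX <- matrix(0, nrow = cache$B * cache$L, ncol = cache$C)
  dX[cache$a_idx, ] <- dY * cache$take_a
  dX[cache$b_idx, ] <- dX[cache$b_idx, ] + dY * (!cache$take_a)
  dX
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# --- parameter initialization ----------------------------------------------

# He-normal initialization, drawn inside the caller's seeded context.
init_network_params <- function(arch) {
  lapply(arch, function(ly) {
    fan_in <- ly$in_dim
    W <- matrix(rnorm(ly$in_dim * ly$out_dim, 0, sqrt(2 / fan_in)),
                nrow = ly$in_dim, ncol = ly$out_dim)
    list(type = ly$type, W = W, b = numeric(ly$out_dim), KS = ly$KS,
         act = ly$act, flatten = isTRUE(ly$flatten))
  })
}

# --- full network forward / backward ---------------------------------------

# net: list(arch, conv_layers, input_len, n_classes, dropout_keep).
# X: B x input_len matrix (already standardized).  Returns probabilities
# and, when train = TRUE, the caches needed for the backward pass.
network_forward <- function(params, net, X, train = FALSE) {
  B <- nrow(X)
  caches <- vector("list", length(params))
  L <- net$input_len
  A <- matrix(as.vector(t(X)), ncol = 1L)  # stacked (B*L) x 1
  i <- 1L
  for (ly in params) {
    if (ly$type == "conv") {
      cv <- conv1d_forward(A, ly$W, ly$b, B, L, ly$KS)
      Z <- cv$Y
      A <- Z * (Z > 0)
      pl <- pool2_forward(A, B, L)
      caches[[i]] <- list(conv = cv, Z = Z, pool = pl)
      A <- pl$Y
      L <- pl$Lo
    } else {
      if (ly$flatten) {
        C <- ncol(A)
        A <- stack_to_flat(A, L, B, C)
        flat_dims <- c(L, B, C)
        if (train && net$dropout_keep < 1) {
          mask <- matrix((runif(length(A)) < net$dropout_keep) /
                           net$dropout_keep,
                         nrow = nrow(A), ncol = ncol(A))
          A <- A * mask
        } else {
          mask <- NULL
        }
      } else {
        flat_dims <- NULL
        mask <- NULL
      }
      Ain <- A
      Z <- A %*% ly$W
      Z <- Z + rep(ly$b, each = B)
      A <- if (identical(ly$act, "relu")) Z * (Z > 0) else Z
      caches[[i]] <- list(Ain = Ain, Z = Z, mask = mask,
                          flat_dims = flat_dims)
    }
    i <- i + 1L
  }
  P <- softmax_rows(A)
  list(probs = P, caches = if (train) caches else NULL)
}

# y: integer class indices 1..n_classes.  Returns gradients in the same
# structure as `params`, plus the batch loss.
network_backward <- function(params, net, fwd, y) {
  P <- fwd$probs
  B <- nrow(P)
  loss <- -mean(log(pmax(P[cbind(seq_len(B), y)], 1e-12)))
  dZ <- P
  dZ[cbind(seq_len(B), y)] <- dZ[cbind(seq_len(B), y)] - 1
  dZ <- dZ / B
  grads <- vector("list", length(params))
  dA <- dZ
  for (i in rev(seq_along(params))) {
    ly <- params[[i]]
    ch <- fwd$caches[[i]]
    if (ly$type == "dense") {
      # dA is the gradient at this layer's activation output
      dZl <- if (identical(ly$act, "relu")) dA * (ch$Z > 0) else dA
      grads[[i]] <- list(dW = crossprod(ch$Ain, dZl), db = colSums(dZl))
      dA <- tcrossprod(dZl, ly$W)
      if (!is.null(ch$mask)) dA <- dA * ch$mask
      if (!is.null(ch$flat_dims)) {
        d <- ch$flat_dims
        dA <- flat_to_stack(dA, d[1], d[2], d[3])
      }
    } else {
      dP <- pool2_backward(dA, ch$pool)
      dRelu <- dP * (ch$Z > 0)
      bk <- conv1d_backward(dRelu, ly$W, ch$conv)
      grads[[i]] <- list(dW = bk$dW, db = bk$db)
      dA <- bk$dX
    }
  }
  list(grads = grads, loss = loss)
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)),
       v = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)))
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    for (nm in c("W", "b")) {
      g <- grads[[i]][[paste0("d", nm)]]
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g^2
      params[[i]][[nm]] <- params[[i]][[nm]] -
        lr * (state$m[[i]][[nm]] / c1) /
          (sqrt(state$v[[i]][[nm]] / c2) + eps)
    }
  }
  list(params = params, state = state)
}

# Forward in chunks (inference); returns the B x n_classes probability
# matrix.  Chunking bounds the im2col working set.
network_predict_probs <- function(params, net, X, batch_size = 100L) {
  n <- nrow(X)
  out <- matrix(0, nrow = n, ncol = net$n_classes)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    out[idx, ] <- network_forward(params, net,
                                  X[idx, , drop = FALSE])$probs
  }
  out
}
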