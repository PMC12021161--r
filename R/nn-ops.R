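# Minimal neural-network primitives: valid convolution via im2col gather,
# ReLU, global average pooling, dense layers, and Adam. Implemented with
# base matrix algebra plus one sparse scatter matrix per convolution layer
# (for the col2im gradient), which keeps a desk-scale CNN trainable on one
# CPU with fully reproducible arithmetic.
#
# Tensor layout: an image batch is a matrix (C*H*W) x B; the per-image
# flattening order is channel-fastest, then row, then column, i.e. flat
# index fi(c, r, cc) = c + C*((r-1) + H*(cc-1)).

# Geometry + gather/scatter tables for one conv layer on a fixed input size.
conv_cache <- function(in_h, in_w, c_in, c_out, k, stride) {
  out_h <- (in_h - k) %/% stride + 1L
  out_w <- (in_w - k) %/% stride + 1L
  if (out_h < 1L || out_w < 1L)
    stopf("conv layer input %dx%d too small for kernel %d", in_h, in_w, k)
  P <- out_h * out_w
  k2c <- k * k * c_in
  idx <- matrix(0L, k2c, P)
  fi <- function(c, r, cc) c + c_in * ((r - 1L) + in_h * (cc - 1L))
  patch <- integer(k2c)
  p <- 0L
  for (oc in seq_len(out_w)) {
    c0 <- (oc - 1L) * stride
    for (orow in seq_len(out_h)) {
      r0 <- (orow - 1L) * stride
      p <- p + 1L
      j <- 0L
      for (cc in seq_len(k)) for (r in seq_len(k)) for (ch in seq_len(c_in)) {
        j <- j + 1L
        patch[j] <- fi(ch, r0 + r, c0 + cc)
      }
      idx[, p] <- patch
    }
  }
  n_in <- c_in * in_h * in_w
  L <- length(idx)
  S <- Matrix::sparseMatrix(i = as.vector(idx), j = seq_len(L), x = 1,
                            dims = c(n_in, L))
  list(in_h = in_h, in_w = in_w, out_h = out_h, out_w = out_w,
       c_in = c_in, c_out = c_out, k = k, stride = stride,
       P = P, k2c = k2c, n_in = n_in, idx = as.vector(idx), S = S)
}

# Gather im2col columns for a whole batch: returns (k2c) x (P*B).
im2col_batch <- function(X, cache) {
  B <- ncol(X)
  gidx <- outer(cache$idx, (seq_len(B) - 1L) * cache$n_in, "+")
  matrix(X[gidx], nrow = cache$k2c)
}

relu <- function(x) x * (x > 0)

# Forward pass through the conv stack; returns embedding and (optionally)
# the caches needed for backprop.
encoder_forward <- function(params, caches, X, keep = FALSE) {
  B <- ncol(X)
  acts <- if (keep) vector("list", length(caches)) else NULL
  A <- X
  for (l in seq_along(caches)) {
    ch <- caches[[l]]
    Xc <- im2col_batch(A, ch)
    Ypre <- params[[paste0("conv", l, "_W")]] %*% Xc +
      params[[paste0("conv", l, "_b")]][, rep.int(1L, ncol(Xc)), drop = FALSE]
    Y <- relu(Ypre)
    if (keep) acts[[l]] <- list(Xc = Xc, Ypre = Ypre)
    A <- matrix(Y, ch$c_out * ch$P, B)  # reflatten for the next layer
  }
  last <- caches[[length(caches)]]
  A3 <- array(A, c(last$c_out, last$P, B))
  Z <- apply(A3, 3L, function(m) rowMeans(matrix(m, last$c_out, last$P)))
  Z <- matrix(Z, last$c_out, B)
  list(Z = Z, acts = acts)
}

# Backprop through the conv stack given dZ (embed_dim x B).
encoder_backward <- function(params, caches, dZ, acts, B) {
  grads <- list()
  last <- caches[[length(caches)]]
  dA <- dZ[, rep(seq_len(B), each = last$P), drop = FALSE] / last$P
  for (l in rev(seq_along(caches))) {
    ch <- caches[[l]]
    a <- acts[[l]]
    dY <- dA * (a$Ypre > 0)
    grads[[paste0("conv", l, "_W")]] <- dY %*% t(a$Xc)
    grads[[paste0("conv", l, "_b")]] <- matrix(rowSums(dY), ncol = 1)
    if (l > 1L) {
      dXc <- t(params[[paste0("conv", l, "_W")]]) %*% dY
      dX <- as.matrix(ch$S %*% matrix(dXc, ch$k2c * ch$P, B))
      prev <- caches[[l - 1L]]
      dA <- matrix(dX, prev$c_out, prev$P * B)
    }
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
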