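# Minimal convolutional network engine: im2col convolution, ReLU,
# squeeze-and-excitation recalibration, and exact manual backpropagation.
# Everything operates on single images as (channels, height, width) arrays;
# batching is a loop with gradient averaging (problem sizes here are tiny).

he_uniform <- function(nrow, ncol, fan_in = ncol) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# Precomputed gather-indices turning convolution into one matrix product.
# idx[r, l] is the linear index into the zero-padded input of the r-th
# element (channel fastest, then kernel row, then kernel col) of the patch
# that produces output location l (output locations in column-major order).
conv_plan <- function(in_channels, H, W, k = 3L, stride = 2L, pad = 1L) {
  C <- in_channels
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  H_out <- (Hp - k) %/% stride + 1L
  W_out <- (Wp - k) %/% stride + 1L
  if (H_out < 1L || W_out < 1L)
    stop_dim("input ", H, "x", W, " too small for kernel ", k)
  patch_off <- as.vector(outer(outer(seq_len(C), (0:(k - 1L)) * C, `+`),
                               (0:(k - 1L)) * C * Hp, `+`))
  bases <- as.vector(outer(C * stride * (0:(H_out - 1L)),
                           C * Hp * stride * (0:(W_out - 1L)), `+`))
  list(idx = outer(patch_off, bases, `+`),
       C = C, H = H, W = W, Hp = Hp, Wp = Wp, pad = pad,
       H_out = H_out, W_out = W_out, k = k, stride = stride)
}

pad_input <- function(x, plan) {
  xp <- array(0, c(plan$C, plan$Hp, plan$Wp))
  xp[, plan$pad + seq_len(plan$H), plan$pad + seq_len(plan$W)] <- x
  xp
}

conv_forward <- function(x, W, b, plan) {
  xp <- pad_input(x, plan)
  cols <- matrix(xp[as.vector(plan$idx)], nrow = nrow(plan$idx))
  z <- W %*% cols + b
  list(z = z, cols = cols)           # z: C_out x L
}

conv_backward <- function(dz, cols, W, plan) {
  dW <- dz %*% t(cols)
  db <- rowSums(dz)
  dcols <- crossprod(W, dz)
  acc <- rowsum(as.vector(dcols), group = as.vector(plan$idx))
  dxp <- numeric(plan$C * plan$Hp * plan$Wp)
  dxp[as.integer(rownames(acc))] <- acc
  dxp <- array(dxp, c(plan$C, plan$Hp, plan$Wp))
  dx <- dxp[, plan$pad + seq_len(plan$H), plan$pad + seq_len(plan$W), drop = FALSE]
  list(dW = dW, db = db, dx = array(dx, c(plan$C, plan$H, plan$W)))
}

# --- squeeze-and-excitation forward/backward over the C x L matrix view ---

se_forward <- function(u_mat, se) {
  s <- rowMeans(u_mat)
  z1 <- as.vector(se$W1 %*% s)
  h <- pmax(z1, 0)
  z2 <- as.vector(se$W2 %*% h)
  e <- 1 / (1 + exp(-z2))
  list(out = u_mat * e, s = s, z1 = z1, h = h, e = e)
}

se_backward <- function(dout, u_mat, cache, se) {
  L <- ncol(u_mat)
  de <- rowSums(dout * u_mat)
  dz2 <- de * cache$e * (1 - cache$e)
  dW2 <- outer(dz2, cache$h)
  dh <- as.vector(crossprod(se$W2, dz2))
  dz1 <- dh * (cache$z1 > 0)
  dW1 <- outer(dz1, cache$s)
  ds <- as.vector(crossprod(se$W1, dz1))
  du <- dout * cache$e + matrix(ds / L, nrow(u_mat), L)
  list(dW1 = dW1, dW2 = dW2, dx = du)
}

# --- backbone: a stack of conv(3x3, stride 2, pad 1) + ReLU (+ SE) stages ---

backbone_forward <- function(bk, x) {
  if (!identical(dim(x)[1], bk$in_channels) ||
      dim(x)[2] != bk$input_size || dim(x)[3] != bk$input_size)
    stop_dim("input shape ", paste(dim(x), collapse = "x"),
             " does not match backbone contract ",
             bk$in_channels, "x", bk$input_size, "x", bk$input_size)
  caches <- vector("list", length(bk$stages))
  for (i in seq_along(bk$stages)) {
    st <- bk$stages[[i]]
    plan <- bk$plans[[i]]
    cf <- conv_forward(x, st$W, st$b, plan)
    act <- pmax(cf$z, 0)                      # C_out x L
    se_cache <- NULL
    out_mat <- act
    if (!is.null(st$se)) {
      sf <- se_forward(act, st$se)
      se_cache <- sf
      out_mat <- sf$out
    }
    caches[[i]] <- list(cols = cf$cols, z = cf$z, act = act, se = se_cache,
                        out = out_mat)
    x <- array(out_mat, c(nrow(out_mat), plan$H_out, plan$W_out))
  }
  list(fmap = x, caches = caches)
}

# dfmap: gradient wrt the final feature map (C x H' x W' array).
# Returns per-stage weight gradients and, for interpretability, the gradient
# at each stage's output.
backbone_backward <- function(bk, fw, dfmap) {
  n <- length(bk$stages)
  grads <- vector("list", n)
  d_stage_out <- vector("list", n)
  dmat <- matrix(dfmap, nrow = dim(dfmap)[1])
  for (i in rev(seq_len(n))) {
    st <- bk$stages[[i]]
    plan <- bk$plans[[i]]
    cache <- caches_i <- fw$caches[[i]]
    d_stage_out[[i]] <- array(dmat, c(nrow(dmat), plan$H_out, plan$W_out))
    g <- list()
    if (!is.null(st$se)) {
      sb <- se_backward(dmat, cache$act, cache$se, st$se)
      g$se.W1 <- sb$dW1; g$se.W2 <- sb$dW2
      dmat <- sb$dx
    }
    dz <- dmat * (cache$z > 0)
    cb <- conv_backward(dz, cache$cols, st$W, plan)
    g$W <- cb$dW; g$b <- cb$db
    grads[[i]] <- g
    dmat <- matrix(cb$dx, nrow = plan$C)
  }
  list(stage_grads = grads, d_stage_out = d_stage_out,
       dx = array(dmat, c(bk$in_channels, bk$input_size, bk$input_size)))
}

# --- classification heads -------------------------------------------------

softmax <- function(logits) {
  z <- logits - max(logits)
  ez <- exp(z)
  ez / sum(ez)
}

# Bilinear head: pool -> signed sqrt -> L2 normalize -> affine -> softmax.
# `X_a`, `X_b` are C x L matrix views of the stream feature maps (identical
# object for the fast single-stream variant).
bilinear_head_forward <- function(X_a, X_b, Wc, bc, pooling = "sum") {
  phi <- X_a %*% t(X_b)
  if (pooling == "mean") phi <- phi / ncol(X_a)
  v <- as.vector(t(phi))
  vs <- sign(v) * sqrt(abs(v))
  nrm <- sqrt(sum(vs * vs))
  z <- vs / max(nrm, 1e-12)
  logits <- as.vector(Wc %*% z + bc)
  list(logits = logits, p = softmax(logits), z = z, vs = vs, v = v,
       nrm = nrm, phi_dim = dim(phi), pooling = pooling)
}

# Derivative of sign(v)*sqrt(|v|) is 1/(2*sqrt(|v|)); the denominator is
# floored so gradients stay bounded near v = 0 (forward pass stays exact).
SQRT_GRAD_FLOOR <- 1e-4

bilinear_head_backward <- function(dlogits, hf, X_a, X_b, Wc) {
  dWc <- outer(dlogits, hf$z)
  dbc <- dlogits
  dz <- as.vector(crossprod(Wc, dlogits))
  n <- max(hf$nrm, 1e-12)
  if (hf$nrm >= 1e-12) {
    dvs <- (dz - hf$z * sum(hf$z * dz)) / n
  } else {
    dvs <- dz / n
  }
  dv <- dvs * 0.5 / sqrt(pmax(abs(hf$v), SQRT_GRAD_FLOOR))
  dphi <- t(matrix(dv, hf$phi_dim[2], hf$phi_dim[1]))
  if (hf$pooling == "mean") dphi <- dphi / ncol(X_a)
  same <- identical(X_a, X_b)
  if (same) {
    dX <- (dphi + t(dphi)) %*% X_a
    list(dWc = dWc, dbc = dbc, dX_a = dX, dX_b = NULL)
  } else {
    list(dWc = dWc, dbc = dbc, dX_a = dphi %*% X_b, dX_b = t(dphi) %*% X_a)
  }
}

# Global-average-pooling head (first-order baseline).
gap_head_forward <- function(X, Wc, bc) {
  z <- rowMeans(X)
  logits <- as.vector(Wc %*% z + bc)
  list(logits = logits, p = softmax(logits), z = z)
}

gap_head_backward <- function(dlogits, hf, X, Wc) {
  dWc <- outer(dlogits, hf$z)
  dz <- as.vector(crossprod(Wc, dlogits))
  list(dWc = dWc, dbc = dlogits, dX = matrix(dz / ncol(X), nrow(X), ncol(X)))
}
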