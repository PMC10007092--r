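# Independent brute-force oracles: explicit loops, written without reference
# to the package internals, used to pin down the vectorized implementations.

# Same-padded (zero) 2D convolution by direct sliding-window loops.
# x: (h, w, cin) array; W: (k, k, cin, cout); b: length cout.
conv2d_oracle <- function(x, W, b) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; Cin <- dim(x)[3]
  k <- dim(W)[1]; Cout <- dim(W)[4]
  p <- (k - 1) %/% 2
  out <- array(0, c(H, Wd, Cout))
  for (co in seq_len(Cout)) for (i in seq_len(H)) for (j in seq_len(Wd)) {
    acc <- b[co]
    for (ci in seq_len(Cin)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
      ii <- i + ki - 1 - p
      jj <- j + kj - 1 - p
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= Wd) {
        acc <- acc + x[ii, jj, ci] * W[ki, kj, ci, co]
      }
    }
    out[i, j, co] <- acc
  }
  out
}

# Channel-attention descriptor by explicit loops: global max/avg pooling,
# shared two-layer MLP with leaky hidden units, sum, sigmoid.
channel_descriptor_oracle <- function(feat, params, alpha) {
  C <- dim(feat)[3]
  pmax_v <- numeric(C)
  pavg_v <- numeric(C)
  for (c in seq_len(C)) {
    pmax_v[c] <- max(feat[, , c])
    pavg_v[c] <- mean(feat[, , c])
  }
  leaky <- function(z) ifelse(z > 0, z, alpha * z)
  mlp <- function(p) {
    hidden <- leaky(as.vector(t(params$W1) %*% p) + params$b1)
    as.vector(t(params$W2) %*% hidden) + params$b2
  }
  1 / (1 + exp(-(mlp(pmax_v) + mlp(pavg_v))))
}

# Spatial-attention descriptor: channel-pooled max/avg maps, 7x7
# same-padded convolution, sigmoid — all by loops.
spatial_descriptor_oracle <- function(feat, params) {
  H <- dim(feat)[1]; Wd <- dim(feat)[2]
  mx <- apply(feat, c(1, 2), max)
  av <- apply(feat, c(1, 2), mean)
  stacked <- array(0, c(H, Wd, 2))
  stacked[, , 1] <- mx
  stacked[, , 2] <- av
  logit <- conv2d_oracle(stacked, params$W, params$b)
  1 / (1 + exp(-logit[, , 1]))
}

# Dice loss by explicit per-class sums (squared-sum denominator, smoothed
# numerator and denominator).
dice_loss_oracle <- function(probs, onehot, weights, eps = 1e-6) {
  L <- dim(probs)[3]
  total <- 0
  for (l in seq_len(L)) {
    num <- 0; dp <- 0; dt <- 0
    for (i in seq_len(dim(probs)[1])) for (j in seq_len(dim(probs)[2])) {
      num <- num + probs[i, j, l] * onehot[i, j, l]
      dp <- dp + probs[i, j, l]^2
      dt <- dt + onehot[i, j, l]^2
    }
    total <- total + weights[l] * (2 * num + eps) / (dp + dt + eps)
  }
  1 - total
}

# Per-pixel confusion counting loop.
confusion_oracle <- function(pred, truth, positive) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(pred)) {
    p <- pred[i] == positive
    t <- truth[i] == positive
    if (p && t) tp <- tp + 1
    else if (p && !t) fp <- fp + 1
    else if (!p && !t) tn <- tn + 1
    else fn <- fn + 1
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Haar single-level 2D DWT by direct 2x2 block filter arithmetic
# (orthonormal normalization), independent of the transform matrices.
haar_dwt_oracle <- function(x) {
  r2 <- nrow(x) %/% 2
  c2 <- ncol(x) %/% 2
  ll <- lh <- hl <- hh <- matrix(0, r2, c2)
  for (i in seq_len(r2)) for (j in seq_len(c2)) {
    a <- x[2 * i - 1, 2 * j - 1]; b <- x[2 * i - 1, 2 * j]
    c <- x[2 * i, 2 * j - 1]; d <- x[2 * i, 2 * j]
    ll[i, j] <- (a + b + c + d) / 2
    lh[i, j] <- (a - b + c - d) / 2   # row-low, column-high
    hl[i, j] <- (a + b - c - d) / 2   # row-high, column-low
    hh[i, j] <- (a - b - c + d) / 2
  }
  list(ll = ll, lh = lh, hl = hl, hh = hh)
}

# Zeroed copies of attention/block parameter sets.
zero_ch_params <- function(p) {
  p$W1[] <- 0; p$b1[] <- 0; p$W2[] <- 0; p$b2[] <- 0
  p
}
zero_sp_params <- function(p) {
  p$W[] <- 0; p$b <- 0
  p
}
zero_ssab_params <- function(p) {
  p$conv$W[] <- 0; p$conv$b[] <- 0
  p$ch <- zero_ch_params(p$ch)
  p$sp <- zero_sp_params(p$sp)
  p
}
identity_conv <- function(p) {
  p$conv$W[] <- 0
  w <- dim(p$conv$W)[3]
  for (c in seq_len(w)) p$conv$W[2, 2, c, c] <- 1
  p$conv$b[] <- 0
  p
}

random_feat <- function(h, w, c, seed) {
  set.seed(seed)
  array(rnorm(h * w * c), c(h, w, c))
}
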