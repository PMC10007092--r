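# Batched same-padded 2D convolution via im2col + BLAS matmul, with the
# exact adjoint (backward) pass.  Arrays are (height, width, channels,
# batch); kernels are (k, k, in_channels, out_channels) with odd k.

.conv_fwd <- function(x, W, b, keep = TRUE) {
  d <- dim(x)
  H <- d[1]; Wd <- d[2]; Cin <- d[3]; N <- d[4]
  k <- dim(W)[1]
  if (dim(W)[2] != k) stop("convolution kernels must be square", call. = FALSE)
  if (dim(W)[3] != Cin) {
    stop("kernel expects ", dim(W)[3], " input channels, got ", Cin, call. = FALSE)
  }
  Cout <- dim(W)[4]
  p <- (k - 1L) %/% 2L
  if (p > 0L) {
    xp <- array(0, c(H + 2L * p, Wd + 2L * p, Cin, N))
    xp[p + seq_len(H), p + seq_len(Wd), , ] <- x
  } else {
    xp <- x
  }
  P <- matrix(0, H * Wd * N, k * k * Cin)
  col <- 0L
  for (ci in seq_len(Cin)) for (kj in seq_len(k)) for (ki in seq_len(k)) {
    col <- col + 1L
    P[, col] <- xp[ki:(ki + H - 1L), kj:(kj + Wd - 1L), ci, ]
  }
  out_mat <- P %*% matrix(W, k * k * Cin, Cout)
  out_mat <- out_mat + rep(b, each = nrow(out_mat))
  out <- aperm(array(out_mat, c(H, Wd, N, Cout)), c(1L, 2L, 4L, 3L))
  list(out = out,
       cache = if (keep) list(P = P, dimx = d, k = k, W = W) else NULL)
}

.conv_bwd <- function(cache, dout) {
  d <- cache$dimx
  H <- d[1]; Wd <- d[2]; Cin <- d[3]; N <- d[4]
  k <- cache$k
  W <- cache$W
  Cout <- dim(W)[4]
  p <- (k - 1L) %/% 2L
  dmat <- matrix(aperm(dout, c(1L, 2L, 4L, 3L)), H * Wd * N, Cout)
  dW <- array(crossprod(cache$P, dmat), dim(W))
  db <- colSums(dmat)
  dP <- tcrossprod(dmat, matrix(W, k * k * Cin, Cout))
  dxp <- array(0, c(H + 2L * p, Wd + 2L * p, Cin, N))
  col <- 0L
  for (ci in seq_len(Cin)) for (kj in seq_len(k)) for (ki in seq_len(k)) {
    col <- col + 1L
    dxp[ki:(ki + H - 1L), kj:(kj + Wd - 1L), ci, ] <-
      dxp[ki:(ki + H - 1L), kj:(kj + Wd - 1L), ci, ] + dP[, col]
  }
  dx <- if (p > 0L) {
    dxp[p + seq_len(H), p + seq_len(Wd), , , drop = FALSE]
  } else {
    dxp
  }
  list(dx = dx, dW = dW, db = db)
}

# Single-image (h, w, c) convenience wrapper.
.conv2d <- function(x3, W, b) {
  x4 <- array(x3, c(dim(x3), 1L))
  out <- .conv_fwd(x4, W, b, keep = FALSE)$out
  array(out, dim(out)[1:3])
}

# 1D bilinear upsampling operator (n_out x n_in), half-pixel centers.
# Its transpose is the exact gradient of the upsampling map.
.bilinear_up_matrix <- function(n_out, n_in) {
  U <- matrix(0, n_out, n_in)
  s <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * s - 0.5
    i0 <- floor(src)
    f <- src - i0
    j0 <- min(max(i0 + 1L, 1L), n_in)
    j1 <- min(max(i0 + 2L, 1L), n_in)
    U[i, j0] <- U[i, j0] + (1 - f)
    U[i, j1] <- U[i, j1] + f
  }
  U
}
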