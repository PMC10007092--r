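# The self-supervised attention block (SSAB): channel attention gates each
# feature channel by a sigmoid descriptor computed from globally pooled
# (max and average) spatial statistics through a shared two-layer MLP;
# spatial attention gates each position by a sigmoid descriptor computed
# from channel-pooled (max and average) maps through a 7x7 convolution.
# A block is conv -> channel attention -> spatial attention -> local skip.
#
# Internals operate on batched (h, w, c, n) arrays with cached forward
# state so the training engine can run the exact backward pass; exported
# functions are single-image (h, w, c) wrappers.

.chatt_fwd <- function(x, W1, b1, W2, b2, alpha) {
  d <- dim(x)
  H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  m2 <- matrix(x, H * Wd, C * N)
  idx <- max.col(t(m2), ties.method = "first")
  Pmax <- matrix(m2[cbind(idx, seq_len(C * N))], C, N)
  Pavg <- matrix(colMeans(m2), C, N)
  mlp <- function(P) {
    Z1 <- crossprod(W1, P) + b1
    A1 <- .lrelu(Z1, alpha)
    Z2 <- crossprod(W2, A1) + b2
    list(Z1 = Z1, A1 = A1, Z2 = Z2)
  }
  mm <- mlp(Pmax)
  ma <- mlp(Pavg)
  M <- .sigmoid(mm$Z2 + ma$Z2)
  Mfull <- array(rep(as.vector(M), each = H * Wd), d)
  list(out = x * Mfull, M = M,
       cache = list(x = x, idx = idx, Pmax = Pmax, Pavg = Pavg,
                    mm = mm, ma = ma, M = M, Mfull = Mfull,
                    W1 = W1, W2 = W2, alpha = alpha, d = d))
}

.chatt_bwd <- function(cache, dout) {
  d <- cache$d
  H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  dM <- matrix(colSums(matrix(dout * cache$x, H * Wd, C * N)), C, N)
  dx_gate <- dout * cache$Mfull
  M <- cache$M
  dZ <- dM * M * (1 - M)                       # shared by both pooled paths
  bwd_mlp <- function(ml, P) {
    dA1 <- cache$W2 %*% dZ
    dW2 <- tcrossprod(ml$A1, dZ)
    db2 <- rowSums(dZ)
    dZ1 <- dA1 * .lrelu_grad(ml$Z1, cache$alpha)
    list(dP = cache$W1 %*% dZ1,
         dW1 = tcrossprod(P, dZ1), db1 = rowSums(dZ1),
         dW2 = dW2, db2 = db2)
  }
  gm <- bwd_mlp(cache$mm, cache$Pmax)
  ga <- bwd_mlp(cache$ma, cache$Pavg)
  dm2 <- matrix(0, H * Wd, C * N)
  dm2[cbind(cache$idx, seq_len(C * N))] <- as.vector(gm$dP)
  dm2 <- dm2 + rep(as.vector(ga$dP) / (H * Wd), each = H * Wd)
  list(dx = dx_gate + array(dm2, d),
       dW1 = gm$dW1 + ga$dW1, db1 = gm$db1 + ga$db1,
       dW2 = gm$dW2 + ga$dW2, db2 = gm$db2 + ga$db2)
}

.spatt_fwd <- function(x, Ws, bs, keep = TRUE) {
  d <- dim(x)
  H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  xm <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), H * Wd * N, C)
  idx <- max.col(xm, ties.method = "first")
  mx <- xm[cbind(seq_len(H * Wd * N), idx)]
  av <- rowMeans(xm)
  S <- array(0, c(H, Wd, 2L, N))
  S[, , 1L, ] <- array(mx, c(H, Wd, N))
  S[, , 2L, ] <- array(av, c(H, Wd, N))
  cf <- .conv_fwd(S, Ws, bs, keep = keep)
  D <- .sigmoid(cf$out)                         # (H, Wd, 1, N)
  Dv <- array(D, c(H, Wd, N))
  Dfull <- aperm(array(Dv, c(H, Wd, N, C)), c(1L, 2L, 4L, 3L))
  list(out = x * Dfull, D = Dv,
       cache = list(x = x, idx = idx, conv = cf$cache, D = D,
                    Dfull = Dfull, d = d))
}

.spatt_bwd <- function(cache, dout) {
  d <- cache$d
  H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  dDv <- rowSums(matrix(aperm(dout * cache$x, c(1L, 2L, 4L, 3L)), H * Wd * N, C))
  dx_gate <- dout * cache$Dfull
  D <- cache$D
  dDlog <- array(dDv, c(H, Wd, 1L, N)) * D * (1 - D)
  cb <- .conv_bwd(cache$conv, dDlog)
  dmx <- as.vector(array(cb$dx[, , 1L, ], c(H, Wd, N)))
  dav <- as.vector(array(cb$dx[, , 2L, ], c(H, Wd, N)))
  dxm <- matrix(0, H * Wd * N, C)
  dxm[cbind(seq_len(H * Wd * N), cache$idx)] <- dmx
  dxm <- dxm + dav / C
  list(dx = dx_gate + aperm(array(dxm, c(H, Wd, N, C)), c(1L, 2L, 4L, 3L)),
       dW = cb$dW, db = cb$db)
}

.check_feat <- function(feat) {
  if (!is.array(feat) || length(dim(feat)) != 3L) {
    stop("feature map must be a 3D (height, width, channels) array", call. = FALSE)
  }
  if (!all(is.finite(feat))) stop("feature map contains non-finite values", call. = FALSE)
  invisible(feat)
}

#' Initialize channel-attention parameters
#'
#' A shared two-layer MLP with a bottleneck of `width / reduction` hidden
#' units; the same weights serve both the max-pooled and average-pooled
#' descriptor paths.  Weights use seeded Kaiming-uniform initialization,
#' biases start at zero.
#'
#' @param width Channel count `w` of the feature maps to gate.
#' @param reduction Reduction ratio `h`; `width` must be divisible by it.
#' @param seed Optional integer seed for reproducible initialization.
#' @return List with `W1` (`w x w/h`), `b1`, `W2` (`w/h x w`), `b2`,
#'   `reduction`.
#' @export
channel_attention_params <- function(width, reduction = 4, seed = NULL) {
  if (width %% reduction != 0) {
    stop("width must be divisible by the reduction ratio", call. = FALSE)
  }
  hdim <- width %/% reduction
  make <- function() {
    list(W1 = .kaiming(c(width, hdim), width), b1 = numeric(hdim),
         W2 = .kaiming(c(hdim, width), hdim), b2 = numeric(width),
         reduction = reduction)
  }
  if (is.null(seed)) make() else .with_seed(seed, make())
}

#' Initialize spatial-attention parameters
#'
#' One 7x7 convolution mapping the two stacked channel-pooled maps (max,
#' average) to a single logit map.
#'
#' @inheritParams channel_attention_params
#' @return List with `W` (`7 x 7 x 2 x 1`) and `b` (scalar).
#' @export
spatial_attention_params <- function(seed = NULL) {
  make <- function() list(W = .kaiming(c(7L, 7L, 2L, 1L), 7 * 7 * 2), b = 0)
  if (is.null(seed)) make() else .with_seed(seed, make())
}

.check_ch_params <- function(feat, params) {
  C <- dim(feat)[3]
  if (nrow(params$W1) != C) {
    stop("channel-attention parameters expect width ", nrow(params$W1),
         ", feature map has ", C, " channels", call. = FALSE)
  }
}

#' Channel-attention descriptor
#'
#' Global max- and average-pooling over all spatial positions give two
#' per-channel vectors; each passes through the shared bottleneck MLP
#' (leaky-ReLU hidden layer), the results are summed and squashed by a
#' sigmoid.  Every entry lies strictly in (0, 1); with all-zero weights
#' the descriptor is exactly 0.5 for every channel.
#'
#' @param feat Numeric `(height, width, channels)` array.
#' @param params See [channel_attention_params()].
#' @param alpha Leaky-ReLU negative slope (default 0.2).
#' @return Numeric vector of length `channels` in (0, 1).
#' @export
channel_descriptor <- function(feat, params, alpha = 0.2) {
  .check_feat(feat)
  .check_ch_params(feat, params)
  x4 <- array(feat, c(dim(feat), 1L))
  as.vector(.chatt_fwd(x4, params$W1, params$b1, params$W2, params$b2, alpha)$M)
}

#' Apply channel attention
#'
#' Multiplies each channel of the feature map by its [channel_descriptor()]
#' entry; input and output shapes are identical.
#'
#' @inheritParams channel_descriptor
#' @return Gated feature map, same shape as `feat`.
#' @export
channel_attention <- function(feat, params, alpha = 0.2) {
  .check_feat(feat)
  .check_ch_params(feat, params)
  x4 <- array(feat, c(dim(feat), 1L))
  out <- .chatt_fwd(x4, params$W1, params$b1, params$W2, params$b2, alpha)$out
  array(out, dim(feat))
}

#' Spatial-attention descriptor
#'
#' Max- and average-pooling along the channel axis give two 2D maps;
#' stacked, convolved with a same-padded 7x7 kernel and squashed by a
#' sigmoid they give one gating value per spatial position, strictly in
#' (0, 1).
#'
#' @param feat Numeric `(height, width, channels)` array.
#' @param params See [spatial_attention_params()].
#' @return Numeric `(height, width)` matrix in (0, 1).
#' @export
spatial_descriptor <- function(feat, params) {
  .check_feat(feat)
  x4 <- array(feat, c(dim(feat), 1L))
  matrix(.spatt_fwd(x4, params$W, params$b, keep = FALSE)$D,
         dim(feat)[1], dim(feat)[2])
}

#' Apply spatial attention
#'
#' Multiplies every channel elementwise by the shared 2D
#' [spatial_descriptor()]; input and output shapes are identical.
#'
#' @inheritParams spatial_descriptor
#' @return Gated feature map, same shape as `feat`.
#' @export
spatial_attention <- function(feat, params) {
  .check_feat(feat)
  x4 <- array(feat, c(dim(feat), 1L))
  out <- .spatt_fwd(x4, params$W, params$b, keep = FALSE)$out
  array(out, dim(feat))
}

#' One self-supervised attention block
#'
#' `block_conv` (3x3, width-preserving, no activation) followed by channel
#' attention, spatial attention, and a local skip connection:
#' `out = spatial(channel(conv(feat))) + feat`.  With all learnable
#' weights zero the block is exactly the identity; with an identity
#' convolution and zero attention weights it returns `1.25 * feat`
#' (two 0.5 sigmoid gates plus the skip).
#'
#' @param feat Numeric `(height, width, channels)` array.
#' @param conv_params List with `W` (`3 x 3 x w x w`) and `b` (length `w`).
#' @param ch_params See [channel_attention_params()].
#' @param sp_params See [spatial_attention_params()].
#' @param alpha Leaky-ReLU negative slope used inside the channel MLP.
#' @return Feature map with the same shape as `feat`.
#' @export
ssab_block <- function(feat, conv_params, ch_params, sp_params, alpha = 0.2) {
  .check_feat(feat)
  w <- dim(feat)[3]
  if (dim(conv_params$W)[3] != w || dim(conv_params$W)[4] != w) {
    stop("block convolution must preserve the feature width ", w, call. = FALSE)
  }
  .check_ch_params(feat, ch_params)
  z <- .conv2d(feat, conv_params$W, conv_params$b)
  z <- channel_attention(z, ch_params, alpha)
  z <- spatial_attention(z, sp_params)
  z + feat
}

#' Initialize the parameters of one SSAB
#'
#' Bundles a width-preserving 3x3 block convolution with channel- and
#' spatial-attention parameters, for use with [ssab_block()].
#'
#' @inheritParams channel_attention_params
#' @return List with elements `conv`, `ch`, `sp`.
#' @export
ssab_params <- function(width, reduction = 4, seed = NULL) {
  make <- function() {
    list(conv = list(W = .kaiming(c(3L, 3L, width, width), 9 * width),
                     b = numeric(width)),
         ch = channel_attention_params(width, reduction),
         sp = spatial_attention_params())
  }
  if (is.null(seed)) make() else .with_seed(seed, make())
}
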