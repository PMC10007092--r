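# Batched forward and backward passes of the full network, the joint
# training loss (per-sample soft Dice + reconstruction MSE + L2), and its
# hand-derived gradients.  All arrays are (h, w, channels, batch).

# Trunk: T SSABs -> channel concatenation -> 3x3 fusion conv -> leaky ->
# {3x3 conv to 4 coefficient channels; 1x1 segmentation head}.
.trunk_fwd <- function(i0, params, config, keep = TRUE) {
  alpha <- config$leaky_slope
  T <- config$num_blocks
  w <- config$width
  d <- dim(i0)
  H <- d[1]; Wd <- d[2]; N <- d[4]
  Is <- vector("list", T + 1L)
  Is[[1L]] <- i0
  bl <- vector("list", T)
  for (t in seq_len(T)) {
    bp <- .block_params(params, t)
    cc <- .conv_fwd(Is[[t]], bp$conv$W, bp$conv$b, keep)
    ca <- .chatt_fwd(cc$out, bp$ch$W1, bp$ch$b1, bp$ch$W2, bp$ch$b2, alpha)
    sa <- .spatt_fwd(ca$out, bp$sp$W, bp$sp$b, keep)
    Is[[t + 1L]] <- sa$out + Is[[t]]
    bl[[t]] <- if (keep) list(conv = cc$cache, ch = ca$cache, sp = sa$cache)
  }
  Icat <- array(0, c(H, Wd, w * T, N))
  for (t in seq_len(T)) Icat[, , (t - 1L) * w + seq_len(w), ] <- Is[[t + 1L]]
  f1 <- .conv_fwd(Icat, params[["fuse1.W"]], params[["fuse1.b"]], keep)
  F1 <- .lrelu(f1$out, alpha)
  f2 <- .conv_fwd(F1, params[["fuse2.W"]], params[["fuse2.b"]], keep)
  hd <- .conv_fwd(F1, params[["head.W"]], params[["head.b"]], keep)
  list(ic = f2$out, logits_lr = hd$out,
       cache = if (keep) list(blocks = bl, f1pre = f1$out, f1 = f1$cache,
                              f2 = f2$cache, hd = hd$cache, F1 = F1))
}

.net_fwd <- function(params, X0, config, keep = TRUE) {
  c0 <- .conv_fwd(X0, params[["shallow.W"]], params[["shallow.b"]], keep)
  I0 <- .lrelu(c0$out, config$leaky_slope)
  tr <- .trunk_fwd(I0, params, config, keep)
  list(ic = tr$ic, logits_lr = tr$logits_lr,
       cache = if (keep) list(c0pre = c0$out, c0 = c0$cache,
                              trunk = tr$cache))
}

# Backward pass; dic and dlogits_lr are the upstream gradients on the
# predicted coefficient stack and the low-resolution class logits.
.net_bwd <- function(fw, params, config, dic, dlogits_lr) {
  alpha <- config$leaky_slope
  T <- config$num_blocks
  w <- config$width
  tc <- fw$cache$trunk
  g <- list()
  cb2 <- .conv_bwd(tc$f2, dic)
  g[["fuse2.W"]] <- cb2$dW; g[["fuse2.b"]] <- cb2$db
  cbh <- .conv_bwd(tc$hd, dlogits_lr)
  g[["head.W"]] <- cbh$dW; g[["head.b"]] <- cbh$db
  dF1 <- cb2$dx + cbh$dx
  dZf1 <- dF1 * .lrelu_grad(tc$f1pre, alpha)
  cb1 <- .conv_bwd(tc$f1, dZf1)
  g[["fuse1.W"]] <- cb1$dW; g[["fuse1.b"]] <- cb1$db
  dIcat <- cb1$dx
  gI <- dIcat[, , (T - 1L) * w + seq_len(w), , drop = FALSE]
  for (t in rev(seq_len(T))) {
    pre <- paste0("block", t, ".")
    sb <- .spatt_bwd(tc$blocks[[t]]$sp, gI)
    g[[paste0(pre, "sp.W")]] <- sb$dW
    g[[paste0(pre, "sp.b")]] <- sb$db
    cb <- .chatt_bwd(tc$blocks[[t]]$ch, sb$dx)
    g[[paste0(pre, "ch.W1")]] <- cb$dW1
    g[[paste0(pre, "ch.b1")]] <- cb$db1
    g[[paste0(pre, "ch.W2")]] <- cb$dW2
    g[[paste0(pre, "ch.b2")]] <- cb$db2
    cvb <- .conv_bwd(tc$blocks[[t]]$conv, cb$dx)
    g[[paste0(pre, "conv.W")]] <- cvb$dW
    g[[paste0(pre, "conv.b")]] <- cvb$db
    gI <- cvb$dx + gI                      # local skip connection
    if (t > 1L) gI <- gI + dIcat[, , (t - 2L) * w + seq_len(w), , drop = FALSE]
  }
  dZ0 <- gI * .lrelu_grad(fw$cache$c0pre, alpha)
  cb0 <- .conv_bwd(fw$cache$c0, dZ0)
  g[["shallow.W"]] <- cb0$dW
  g[["shallow.b"]] <- cb0$db
  g
}

# Assemble the fixed training tensors from a list of phantom samples (or
# any list with $image and $labels): coefficient inputs, bicubic
# baselines, z-scored targets, one-hot labels, upsampling operators.
.sswan_batch <- function(samples, config) {
  N <- length(samples)
  d <- dim(samples[[1]]$image)
  if (any(d %% 2L != 0L)) stop("training images must be even-sized", call. = FALSE)
  H2 <- d[1] %/% 2L
  W2 <- d[2] %/% 2L
  L <- config$num_classes
  X0 <- array(0, c(H2, W2, 4L, N))
  BIC <- array(0, c(d[1], d[2], N))
  TARGET <- array(0, c(d[1], d[2], N))
  ONEHOT <- array(0, c(d[1], d[2], L, N))
  LAB <- array(0L, c(d[1], d[2], N))
  for (n in seq_len(N)) {
    s <- samples[[n]]
    if (!identical(dim(s$image), d)) {
      stop("all samples must share one image size", call. = FALSE)
    }
    prep <- .prep_sample(s$image, config)
    X0[, , , n] <- prep$X0
    BIC[, , n] <- prep$bic
    TARGET[, , n] <- prep$xz
    LAB[, , n] <- s$labels
    for (l in seq_len(L)) ONEHOT[, , l, n] <- (s$labels == l - 1L)
  }
  list(X0 = X0, BIC = BIC, TARGET = TARGET, ONEHOT = ONEHOT, LAB = LAB,
       Ur = .bilinear_up_matrix(d[1], H2), Uc = .bilinear_up_matrix(d[2], W2),
       Wr = .wavelet_matrix(d[1], config$wavelet),
       Wc = .wavelet_matrix(d[2], config$wavelet),
       dim = d, N = N, L = L)
}

# Assemble an (r, c) coefficient-quadrant matrix from 4 channels of ic.
.quadrants_from_channels <- function(ch) {
  rbind(cbind(ch[, , 1], ch[, , 2]), cbind(ch[, , 3], ch[, , 4]))
}

.channels_from_quadrants <- function(C) {
  r2 <- nrow(C) %/% 2L
  c2 <- ncol(C) %/% 2L
  arr <- array(0, c(r2, c2, 4L))
  arr[, , 1] <- C[seq_len(r2), seq_len(c2)]
  arr[, , 2] <- C[seq_len(r2), c2 + seq_len(c2)]
  arr[, , 3] <- C[r2 + seq_len(r2), seq_len(c2)]
  arr[, , 4] <- C[r2 + seq_len(r2), c2 + seq_len(c2)]
  arr
}

# Joint loss and (optionally) gradients for one full batch.
# loss = dice_weight * mean_n dice_n + recon_weight * mean MSE + lambda*||W||^2
.sswan_loss_and_grads <- function(params, batch, config,
                                  dice_weight = 1, recon_weight = 1,
                                  lambda = 1e-4, eps = 1e-6,
                                  want_grads = TRUE) {
  d <- batch$dim
  N <- batch$N
  L <- batch$L
  rc <- d[1] * d[2]
  fw <- .net_fwd(params, batch$X0, config, keep = want_grads)

  # Reconstruction branch: idwt2 of predicted coefficients + baseline.
  recon <- array(0, c(d[1], d[2], N))
  for (n in seq_len(N)) {
    C <- .quadrants_from_channels(fw$ic[, , , n])
    recon[, , n] <- t(batch$Wr) %*% C %*% batch$Wc + batch$BIC[, , n]
  }
  diffR <- recon - batch$TARGET
  loss_rec <- sum(diffR^2) / (rc * N)

  # Segmentation branch: upsampled logits -> softmax -> per-sample Dice.
  logits <- array(0, c(d[1], d[2], L, N))
  for (n in seq_len(N)) for (l in seq_len(L)) {
    logits[, , l, n] <- batch$Ur %*% fw$logits_lr[, , l, n] %*% t(batch$Uc)
  }
  P <- .softmax4(logits)
  wl <- rep(1 / L, L)
  num <- matrix(colSums(matrix(P * batch$ONEHOT, rc, L * N)), L, N)
  pp <- matrix(colSums(matrix(P * P, rc, L * N)), L, N)
  ii <- matrix(colSums(matrix(batch$ONEHOT, rc, L * N)), L, N)  # t^2 = t
  den <- pp + ii + eps
  num2 <- 2 * num + eps
  dice_n <- 1 - colSums(wl * (num2 / den))
  loss_dice <- mean(dice_n)

  loss <- dice_weight * loss_dice + recon_weight * loss_rec +
    lambda * .weight_sq_sum(params)

  out <- list(loss = loss, loss_dice = loss_dice, loss_rec = loss_rec,
              probs = P, recon = recon)
  if (!want_grads) return(out)

  # d(dice)/dP, then softmax backward, then downsample by the transposed
  # bilinear operators.
  c1 <- num2 / den^2                      # (L, N) per-class constants
  c2 <- 1 / den
  c1f <- aperm(array(rep(as.vector(t(c1)), each = rc), c(d[1], d[2], N, L)),
               c(1L, 2L, 4L, 3L))
  c2f <- aperm(array(rep(as.vector(t(c2)), each = rc), c(d[1], d[2], N, L)),
               c(1L, 2L, 4L, 3L))
  wlf <- array(rep(wl, each = rc), c(d[1], d[2], L, N))
  dP <- (dice_weight / N) * 2 * wlf * (P * c1f - batch$ONEHOT * c2f)
  sumd <- (dP * P)[, , 1, , drop = FALSE] * 0
  for (l in seq_len(L)) sumd <- sumd + (dP * P)[, , l, , drop = FALSE]
  dlogits <- P * (dP - .bcast3(sumd, L))
  dlogits_lr <- array(0, dim(fw$logits_lr))
  for (n in seq_len(N)) for (l in seq_len(L)) {
    dlogits_lr[, , l, n] <- t(batch$Ur) %*% dlogits[, , l, n] %*% batch$Uc
  }

  # d(recon MSE)/d(ic) via the adjoint of the orthonormal synthesis.
  dRecon <- (recon_weight * 2 / (rc * N)) * diffR
  dic <- array(0, dim(fw$ic))
  for (n in seq_len(N)) {
    C <- batch$Wr %*% dRecon[, , n] %*% t(batch$Wc)
    dic[, , , n] <- .channels_from_quadrants(C)
  }

  g <- .net_bwd(fw, params, config, dic, dlogits_lr)
  if (lambda > 0) {
    for (nm in names(g)) {
      if (.is_weight_name(nm)) g[[nm]] <- g[[nm]] + 2 * lambda * params[[nm]]
    }
  }
  out$grads <- g
  out
}

# Mean hard foreground Dice across a batch (classes 1..L-1, averaged over
# classes present in the truth, then over samples).
.batch_hard_dice <- function(P, LAB, L) {
  d <- dim(P)
  N <- d[4]
  rcn <- d[1] * d[2]
  out <- numeric(N)
  for (n in seq_len(N)) {
    pred <- .argmax3(array(P[, , , n], d[1:3]))
    truth <- LAB[, , n]
    ds <- vapply(seq_len(L - 1L), function(l) {
      dice_coefficient(pred == l, truth == l)
    }, numeric(1))
    out[n] <- mean(ds, na.rm = TRUE)
  }
  mean(out)
}
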