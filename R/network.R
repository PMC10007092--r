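# The assembled SSW-AN: shallow extraction, T stacked SSABs,
# channel-dimension concatenation, fusion to the four predicted residual
# coefficients, global residual reconstruction, and a softmax
# segmentation head.

#' SSW-AN network configuration
#'
#' @param num_blocks Number `T` of stacked attention blocks (default 8).
#' @param width Feature channel count `w` (default 64; tests and the
#'   desk-scale protocols use 8-16).
#' @param reduction Channel-attention reduction ratio `h`; `width` must be
#'   divisible by it (default 4).
#' @param leaky_slope Negative slope of every leaky-ReLU (default 0.2;
#'   wavelet coefficients are signed, so a leaky activation is required).
#' @param num_classes Number of segmentation classes `L` >= 2.
#' @param wavelet Analysis filter name (default `"haar"`).
#' @param downsample_factor Factor between the full-resolution image and
#'   the low-resolution source of the bicubic baseline (default 2).
#' @param seed Integer seed controlling parameter initialization.
#' @return Object of class `sswan_config`.
#' @export
sswan_config <- function(num_blocks = 8L, width = 64L, reduction = 4L,
                         leaky_slope = 0.2, num_classes = 2L,
                         wavelet = "haar", downsample_factor = 2,
                         seed = 0L) {
  num_blocks <- as.integer(num_blocks)
  width <- as.integer(width)
  reduction <- as.integer(reduction)
  num_classes <- as.integer(num_classes)
  if (num_blocks < 1L) stop("num_blocks must be >= 1", call. = FALSE)
  if (num_classes < 2L) stop("num_classes must be >= 2", call. = FALSE)
  if (width < 1L || width %% reduction != 0L) {
    stop("width must be a positive multiple of the reduction ratio",
         call. = FALSE)
  }
  if (downsample_factor <= 1) {
    stop("downsample_factor must exceed 1", call. = FALSE)
  }
  structure(list(num_blocks = num_blocks, width = width,
                 reduction = reduction, leaky_slope = leaky_slope,
                 num_classes = num_classes, wavelet = wavelet,
                 downsample_factor = downsample_factor,
                 seed = as.integer(seed)),
            class = "sswan_config")
}

#' @export
print.sswan_config <- function(x, ...) {
  cat("<sswan_config> T =", x$num_blocks, " w =", x$width,
      " h =", x$reduction, " L =", x$num_classes,
      " wavelet =", x$wavelet, " seed =", x$seed, "\n")
  invisible(x)
}

#' Initialize all learnable SSW-AN parameters
#'
#' Returns a flat named list of arrays — groups `shallow`, `block1..T`
#' (each with `conv`, `ch`, `sp` sub-groups), `fuse1`, `fuse2`, `head` —
#' with seeded Kaiming-uniform weights and zero biases.  Two calls with
#' the same config are bitwise identical.
#'
#' @param config A [sswan_config()].
#' @return Object of class `sswan_params` (named list of numeric arrays).
#' @export
sswan_init <- function(config) {
  stopifnot(inherits(config, "sswan_config"))
  w <- config$width
  h <- config$reduction
  L <- config$num_classes
  .with_seed(config$seed, {
    p <- list()
    p[["shallow.W"]] <- .kaiming(c(5L, 5L, 4L, w), 5 * 5 * 4)
    p[["shallow.b"]] <- numeric(w)
    for (t in seq_len(config$num_blocks)) {
      pre <- paste0("block", t, ".")
      p[[paste0(pre, "conv.W")]] <- .kaiming(c(3L, 3L, w, w), 9 * w)
      p[[paste0(pre, "conv.b")]] <- numeric(w)
      p[[paste0(pre, "ch.W1")]] <- .kaiming(c(w, w %/% h), w)
      p[[paste0(pre, "ch.b1")]] <- numeric(w %/% h)
      p[[paste0(pre, "ch.W2")]] <- .kaiming(c(w %/% h, w), w %/% h)
      p[[paste0(pre, "ch.b2")]] <- numeric(w)
      p[[paste0(pre, "sp.W")]] <- .kaiming(c(7L, 7L, 2L, 1L), 7 * 7 * 2)
      p[[paste0(pre, "sp.b")]] <- 0
    }
    p[["fuse1.W"]] <- .kaiming(c(3L, 3L, w * config$num_blocks, w),
                               9 * w * config$num_blocks)
    p[["fuse1.b"]] <- numeric(w)
    p[["fuse2.W"]] <- .kaiming(c(3L, 3L, w, 4L), 9 * w)
    p[["fuse2.b"]] <- numeric(4L)
    p[["head.W"]] <- .kaiming(c(1L, 1L, w, L), w)
    p[["head.b"]] <- numeric(L)
    class(p) <- "sswan_params"
    p
  })
}

#' Count learnable parameters of a configuration
#'
#' Exact count of learnable scalars (weights and biases); strictly
#' increasing in both `num_blocks` and `width`.
#'
#' @param config A [sswan_config()].
#' @return Integer count.
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "sswan_config"))
  w <- config$width
  h <- config$reduction
  T <- config$num_blocks
  L <- config$num_classes
  shallow <- 5 * 5 * 4 * w + w
  block <- (9 * w * w + w) +                       # 3x3 conv
    (w * (w / h) + w / h + (w / h) * w + w) +      # shared MLP
    (7 * 7 * 2 + 1)                                # 7x7 spatial conv
  fuse <- (9 * w * T * w + w) + (9 * w * 4 + 4)
  head <- w * L + L
  as.integer(shallow + T * block + fuse + head)
}

#' Shallow feature extraction from a coefficient stack
#'
#' `I0 = leakyReLU(conv5x5(stack4(coeffs)))`: the four wavelet channels
#' are stacked and mapped to `width` feature channels by a same-padded
#' 5x5 convolution with leaky-ReLU activation.
#'
#' @param coeffs A [coeff_stack()].
#' @param params List with `W` (`5 x 5 x 4 x w`) and `b` (length `w`), as
#'   in the `shallow` group of [sswan_init()].
#' @param alpha Leaky-ReLU negative slope.
#' @return `(rows/2, cols/2, w)` feature array.
#' @export
shallow_extract <- function(coeffs, params, alpha = 0.2) {
  if (!inherits(coeffs, "coeff_stack")) {
    stop("coeffs must be a coeff_stack", call. = FALSE)
  }
  if (!identical(dim(params$W)[1:3], c(5L, 5L, 4L))) {
    stop("shallow parameters must be a 5x5x4xw kernel", call. = FALSE)
  }
  .lrelu(.conv2d(.stack_coeffs(coeffs), params$W, params$b), alpha)
}

# Extract the parameter sub-list of block t from flat sswan_params.
.block_params <- function(params, t) {
  pre <- paste0("block", t, ".")
  list(conv = list(W = params[[paste0(pre, "conv.W")]],
                   b = params[[paste0(pre, "conv.b")]]),
       ch = list(W1 = params[[paste0(pre, "ch.W1")]],
                 b1 = params[[paste0(pre, "ch.b1")]],
                 W2 = params[[paste0(pre, "ch.W2")]],
                 b2 = params[[paste0(pre, "ch.b2")]]),
       sp = list(W = params[[paste0(pre, "sp.W")]],
                 b = params[[paste0(pre, "sp.b")]]))
}

#' Run the SSW-AN trunk: blocks, concatenation, fusion
#'
#' Applies the `T` attention blocks sequentially, concatenates their
#' outputs along the channel axis to width `w * T`, and fuses with a
#' 3x3 convolution to width `w`, a leaky-ReLU, and a final 3x3
#' convolution down to the four predicted residual wavelet coefficients.
#'
#' @param i0 `(h, w, width)` feature array from [shallow_extract()].
#' @param params A full [sswan_init()] parameter set.
#' @param config The matching [sswan_config()].
#' @return Predicted residual [coeff_stack()].
#' @export
forward_trunk <- function(i0, params, config) {
  .check_feat(i0)
  if (dim(i0)[3] != config$width) {
    stop("i0 width ", dim(i0)[3], " does not match config width ",
         config$width, call. = FALSE)
  }
  x4 <- array(i0, c(dim(i0), 1L))
  fw <- .trunk_fwd(x4, params, config, keep = FALSE)
  .unstack_coeffs(array(fw$ic, dim(fw$ic)[1:3]), wavelet = config$wavelet)
}

#' Reconstruct an image from predicted residual coefficients
#'
#' Global residual learning: `idwt2(ic) + baseline`.
#'
#' @param ic Predicted residual [coeff_stack()].
#' @param baseline Bicubic baseline image, same shape as `idwt2(ic)`.
#' @return Reconstructed image matrix.
#' @export
reconstruct <- function(ic, baseline) {
  res <- idwt2(ic)
  if (!identical(dim(res), dim(baseline))) {
    stop("baseline shape ", paste(dim(baseline), collapse = "x"),
         " does not match reconstruction ",
         paste(dim(res), collapse = "x"), call. = FALSE)
  }
  res + baseline
}

# Per-image preprocessing shared by segment() and the trainer: z-score,
# build the bicubic baseline via downsample + upsample, take its DWT.
.prep_sample <- function(image, config) {
  mu <- mean(image)
  sdv <- stats::sd(as.vector(image))
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  xz <- (image - mu) / sdv
  f <- config$downsample_factor
  lr <- bicubic_baseline(xz, 1 / f)
  bic <- .bicubic_to(lr, dim(xz))
  cs <- dwt2(bic, config$wavelet)
  list(xz = xz, bic = bic, X0 = .stack_coeffs(cs), mu = mu, sd = sdv)
}

#' Segment one image with the full SSW-AN pipeline
#'
#' Z-scores the input, builds the bicubic baseline (downsample by the
#' configured factor, bicubic upsample back), takes its single-level DWT,
#' runs shallow extraction, the attention trunk and the fusion layers,
#' reconstructs the image estimate by global residual learning, and maps
#' the fused features through a 1x1 segmentation head (bilinearly
#' upsampled to input resolution, softmax over classes).
#'
#' @param image Numeric matrix with even dimensions.
#' @param params A [sswan_init()] parameter set (or the `params` element
#'   of a [sswan_train()] fit).
#' @param config The matching [sswan_config()].
#' @return Object of class `sswan_segmentation`: list with
#'   `reconstructed` (image estimate in the input's intensity units),
#'   `class_probs` (`(rows, cols, L)`, each pixel a probability simplex)
#'   and `label_map` (integer matrix, values `0..L-1`).
#' @export
segment <- function(image, params, config) {
  .assert_finite_matrix(image)
  stopifnot(inherits(config, "sswan_config"))
  if (dim(params[["shallow.W"]])[4] != config$width) {
    stop("params width does not match config", call. = FALSE)
  }
  prep <- .prep_sample(image, config)
  x0 <- array(prep$X0, c(dim(prep$X0), 1L))
  fw <- .net_fwd(params, x0, config, keep = FALSE)
  ic <- .unstack_coeffs(array(fw$ic, dim(fw$ic)[1:3]), config$wavelet)
  recon_z <- reconstruct(ic, prep$bic)
  recon <- recon_z * prep$sd + prep$mu
  d <- dim(image)
  Ur <- .bilinear_up_matrix(d[1], nrow(prep$X0))
  Uc <- .bilinear_up_matrix(d[2], ncol(prep$X0))
  L <- config$num_classes
  logits <- array(0, c(d[1], d[2], L, 1L))
  for (l in seq_len(L)) {
    logits[, , l, 1] <- Ur %*% fw$logits_lr[, , l, 1] %*% t(Uc)
  }
  probs <- .softmax4(logits)
  lab <- .argmax3(array(probs, c(d[1], d[2], L)))
  structure(list(reconstructed = recon,
                 class_probs = array(probs, c(d[1], d[2], L)),
                 label_map = lab),
            class = "sswan_segmentation")
}

#' @export
print.sswan_segmentation <- function(x, ...) {
  tab <- table(x$label_map)
  cat("<sswan_segmentation> ", nrow(x$label_map), "x", ncol(x$label_map),
      "; class pixel counts: ",
      paste(names(tab), tab, sep = ":", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Display a segmentation result
#'
#' @param x A `sswan_segmentation`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.sswan_segmentation <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(t(x$reconstructed[nrow(x$reconstructed):1, ]),
                  axes = FALSE, col = grDevices::gray.colors(256),
                  main = "reconstruction", ...)
  graphics::image(t(x$label_map[nrow(x$label_map):1, ]), axes = FALSE,
                  main = "labels", ...)
  invisible(x)
}

# Softmax over the class (3rd) axis of an (r, c, L, n) array.
.softmax4 <- function(z) {
  L <- dim(z)[3]
  m <- z[, , 1, , drop = FALSE]
  if (L > 1) for (l in 2:L) m <- pmax(m, z[, , l, , drop = FALSE])
  e <- exp(z - .bcast3(m, L))
  s <- e[, , 1, , drop = FALSE]
  if (L > 1) for (l in 2:L) s <- s + e[, , l, , drop = FALSE]
  e / .bcast3(s, L)
}

# Argmax class labels (0-based) of an (r, c, L) probability array.
.argmax3 <- function(p) {
  d <- dim(p)
  idx <- max.col(matrix(p, d[1] * d[2], d[3]), ties.method = "first")
  matrix(as.integer(idx - 1L), d[1], d[2])
}
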