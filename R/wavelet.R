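# Single-level 2D discrete wavelet analysis/synthesis and the bicubic
# baseline used for global residual learning.
#
# The transform is implemented as multiplication by an orthonormal
# periodized analysis matrix: rows 1..n/2 hold the shifted low-pass filter,
# rows n/2+1..n the shifted high-pass (quadrature-mirror) filter.  Because
# the matrix is orthogonal, synthesis is its transpose, perfect
# reconstruction is exact to floating point, and energy is conserved.

.wavelet_filters <- list(
  # Orthonormal low-pass analysis taps.
  haar = c(1, 1) / sqrt(2),
  db2 = c(0.4829629131445341, 0.8365163037378079,
          0.2241438680420134, -0.1294095225512604)
)

.wt_cache <- new.env(parent = emptyenv())

.wavelet_matrix <- function(n, wavelet = "haar") {
  key <- paste0(wavelet, ":", n)
  hit <- .wt_cache[[key]]
  if (!is.null(hit)) return(hit)
  h <- .wavelet_filters[[wavelet]]
  if (is.null(h)) {
    stop("unknown wavelet '", wavelet, "'; available: ",
         paste(names(.wavelet_filters), collapse = ", "), call. = FALSE)
  }
  M <- length(h)
  if (n %% 2L != 0L) stop("wavelet transform length must be even", call. = FALSE)
  if (n < M) stop("signal length ", n, " shorter than filter (", M, ")", call. = FALSE)
  # Quadrature mirror: g[k] = (-1)^k h[M-1-k] (0-based).
  g <- rev(h) * (-1)^(seq_along(h) - 1L)
  W <- matrix(0, n, n)
  half <- n %/% 2L
  for (k in 0:(half - 1L)) {
    cols <- ((2L * k + 0:(M - 1L)) %% n) + 1L
    for (m in seq_len(M)) {
      W[k + 1L, cols[m]] <- W[k + 1L, cols[m]] + h[m]
      W[half + k + 1L, cols[m]] <- W[half + k + 1L, cols[m]] + g[m]
    }
  }
  .wt_cache[[key]] <- W
  W
}

#' Construct a four-channel wavelet coefficient stack
#'
#' Container for the single-level 2D DWT of one image: the approximation
#' (`ll`), vertical-detail (`lh`), horizontal-detail (`hl`) and
#' diagonal-detail (`hh`) channels, each at half the (padded) source
#' resolution.  The channel order (LL, LH, HL, HH) is the package-wide
#' convention, in memory and on disk.
#'
#' @param ll,lh,hl,hh Numeric matrices of one common shape.
#' @param wavelet Name of the analysis filter pair (`"haar"` or `"db2"`).
#' @param pad Integer vector `c(rows, cols)`: how many replicate rows/cols
#'   were appended to make the source even-sized; [idwt2()] strips them.
#' @return An object of class `coeff_stack`.
#' @export
coeff_stack <- function(ll, lh, hl, hh, wavelet = "haar", pad = c(0L, 0L)) {
  chans <- list(ll = ll, lh = lh, hl = hl, hh = hh)
  for (nm in names(chans)) {
    if (!is.matrix(chans[[nm]]) || !is.numeric(chans[[nm]])) {
      stop("coefficient channel '", nm, "' must be a numeric matrix", call. = FALSE)
    }
  }
  d <- dim(ll)
  same <- vapply(chans, function(ch) identical(dim(ch), d), logical(1))
  if (!all(same)) stop("all four coefficient channels must share one shape", call. = FALSE)
  structure(c(chans, list(wavelet = wavelet, pad = as.integer(pad))),
            class = "coeff_stack")
}

#' @export
print.coeff_stack <- function(x, ...) {
  cat("<coeff_stack> ", nrow(x$ll), "x", ncol(x$ll),
      " per channel (LL, LH, HL, HH), wavelet = ", x$wavelet, "\n", sep = "")
  invisible(x)
}

#' @export
dim.coeff_stack <- function(x) c(dim(x$ll), 4L)

# Replicate-pad a matrix to even dimensions; returns list(x, pad).
.pad_even <- function(x) {
  pr <- nrow(x) %% 2L
  pc <- ncol(x) %% 2L
  if (pr) x <- rbind(x, x[nrow(x), , drop = FALSE])
  if (pc) x <- cbind(x, x[, ncol(x), drop = FALSE])
  list(x = x, pad = c(pr, pc))
}

#' Single-level 2D discrete wavelet transform
#'
#' Applies the separable orthonormal analysis filter bank along rows and
#' columns and splits the result into the four half-resolution channels.
#' Odd-sized inputs are symmetrically padded (edge replication) to even
#' size first; the pad is recorded so [idwt2()] restores the original
#' shape.  With an orthonormal filter the total energy (sum of squares) of
#' the coefficients equals the energy of the (padded) image.
#'
#' @param image Numeric matrix with finite values, at least 2x2.
#' @param wavelet Filter name, see [coeff_stack()].
#' @return A [coeff_stack()].
#' @examples
#' x <- matrix(rnorm(64 * 64), 64)
#' cs <- dwt2(x)
#' max(abs(idwt2(cs) - x))  # perfect reconstruction, ~1e-16
#' @export
dwt2 <- function(image, wavelet = "haar") {
  .assert_finite_matrix(image)
  if (nrow(image) < 2L || ncol(image) < 2L) {
    stop("image must be at least 2x2", call. = FALSE)
  }
  p <- .pad_even(image)
  x <- p$x
  Wr <- .wavelet_matrix(nrow(x), wavelet)
  Wc <- .wavelet_matrix(ncol(x), wavelet)
  C <- Wr %*% x %*% t(Wc)
  r2 <- nrow(x) %/% 2L
  c2 <- ncol(x) %/% 2L
  coeff_stack(ll = C[seq_len(r2), seq_len(c2), drop = FALSE],
              lh = C[seq_len(r2), c2 + seq_len(c2), drop = FALSE],
              hl = C[r2 + seq_len(r2), seq_len(c2), drop = FALSE],
              hh = C[r2 + seq_len(r2), c2 + seq_len(c2), drop = FALSE],
              wavelet = wavelet, pad = p$pad)
}

#' Inverse single-level 2D discrete wavelet transform
#'
#' Exact inverse of [dwt2()] up to floating-point round-off: reassembles
#' the quadrant matrix and applies the transposed (orthonormal) transform,
#' then strips any recorded padding.
#'
#' @param coeffs A [coeff_stack()].
#' @return Numeric matrix of the original (pre-pad) shape.
#' @export
idwt2 <- function(coeffs) {
  if (!inherits(coeffs, "coeff_stack")) {
    coeffs <- do.call(coeff_stack, coeffs)
  }
  r2 <- nrow(coeffs$ll)
  c2 <- ncol(coeffs$ll)
  C <- rbind(cbind(coeffs$ll, coeffs$lh), cbind(coeffs$hl, coeffs$hh))
  Wr <- .wavelet_matrix(2L * r2, coeffs$wavelet)
  Wc <- .wavelet_matrix(2L * c2, coeffs$wavelet)
  x <- t(Wr) %*% C %*% Wc
  pad <- coeffs$pad
  if (length(pad) == 2L && any(pad > 0L)) {
    x <- x[seq_len(nrow(x) - pad[1]), seq_len(ncol(x) - pad[2]), drop = FALSE]
  }
  x
}

# Keys cubic-convolution kernel, a = -0.5 (Catmull-Rom).  Reproduces
# constants and linear ramps exactly away from clamped borders.
.cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  out <- numeric(length(x))
  i1 <- x <= 1
  i2 <- x > 1 & x < 2
  out[i1] <- (a + 2) * x[i1]^3 - (a + 3) * x[i1]^2 + 1
  out[i2] <- a * x[i2]^3 - 5 * a * x[i2]^2 + 8 * a * x[i2] - 4 * a
  out
}

# 1D bicubic resampling operator (n_out x n_in), half-pixel centers,
# borders clamped by index replication.
.resample_matrix <- function(n_out, n_in) {
  B <- matrix(0, n_out, n_in)
  s <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * s - 0.5        # 0-based source coordinate
    base <- floor(src)
    f <- src - base
    taps <- base + (-1):2             # 0-based tap indices
    wts <- .cubic_kernel(f - (-1):2)
    taps <- pmin(pmax(taps, 0), n_in - 1L)
    for (m in 1:4) B[i, taps[m] + 1L] <- B[i, taps[m] + 1L] + wts[m]
  }
  B
}

.bicubic_to <- function(image, out_dim) {
  Br <- .resample_matrix(out_dim[1], nrow(image))
  Bc <- .resample_matrix(out_dim[2], ncol(image))
  Br %*% image %*% t(Bc)
}

#' Bicubic image resampling
#'
#' Separable Keys cubic-convolution resampling (kernel parameter
#' a = -0.5) with half-pixel-aligned centers and clamped borders.  Used to
#' build the bicubic baseline image that the network's global residual
#' learning adds back at output.  `scale = 1` returns the input unchanged.
#'
#' @param image Numeric matrix.
#' @param scale Positive scale factor; output size is `round(dim * scale)`.
#' @return Resampled numeric matrix.
#' @export
bicubic_baseline <- function(image, scale) {
  .assert_finite_matrix(image)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0) {
    stop("scale must be a positive number", call. = FALSE)
  }
  out_dim <- pmax(1L, as.integer(round(dim(image) * scale)))
  if (identical(out_dim, dim(image)) && scale == 1) return(image)
  .bicubic_to(image, out_dim)
}

#' Wavelet-domain residual training target
#'
#' The network is trained to predict the four wavelet coefficients of the
#' residual between the full-quality target image and its bicubic
#' baseline; this computes that target: `dwt2(full - baseline)`.
#'
#' @param full,baseline Numeric matrices of one shape.
#' @param wavelet Filter name.
#' @return A [coeff_stack()]; the zero stack when `full == baseline`.
#' @export
residual_target <- function(full, baseline, wavelet = "haar") {
  .assert_finite_matrix(full, "full")
  .assert_finite_matrix(baseline, "baseline")
  if (!identical(dim(full), dim(baseline))) {
    stop("full and baseline must have identical shapes", call. = FALSE)
  }
  dwt2(full - baseline, wavelet = wavelet)
}

# Stack a coeff_stack into an (r/2, c/2, 4) array in (LL, LH, HL, HH) order.
.stack_coeffs <- function(cs) {
  d <- dim(cs$ll)
  arr <- array(0, c(d, 4L))
  arr[, , 1] <- cs$ll
  arr[, , 2] <- cs$lh
  arr[, , 3] <- cs$hl
  arr[, , 4] <- cs$hh
  arr
}

.unstack_coeffs <- function(arr, wavelet = "haar") {
  coeff_stack(ll = arr[, , 1], lh = arr[, , 2], hl = arr[, , 3], hh = arr[, , 4],
              wavelet = wavelet)
}
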