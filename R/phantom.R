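# Synthetic BraTS-like 2D phantoms: nested tumor sub-regions (whole tumor
# > tumor core > enhancing tumor) drawn as concentric random ellipses on a
# textured background, with additive Gaussian noise.  Everything is
# deterministic given the seed, so the generator doubles as the test and
# training fixture factory.

#' Phantom generation settings
#'
#' @param size Even image dimensions `c(rows, cols)`, each >= 16.
#' @param num_classes Number of label classes `L` in 2..4: background plus
#'   up to three nested tumor sub-regions (emulating the whole-tumor /
#'   tumor-core / enhancing-tumor nesting of annotated brain-tumor MRI).
#' @param means Per-class mean intensities, length `num_classes`; defaults
#'   span 0.2 (background) to 0.9 with the innermost region brightest.
#' @param noise_sigma Standard deviation of i.i.d. additive Gaussian noise.
#' @param texture_scale Amplitude of the smooth background texture (sum of
#'   three low-frequency cosine gratings with seeded random orientation
#'   and phase); 0 gives a flat background.
#' @param seed Integer seed; the sample is a pure function of the config.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(size = c(64L, 64L), num_classes = 2L,
                           means = NULL, noise_sigma = 0.05,
                           texture_scale = 0.1, seed = 0L) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 16L) || any(size %% 2L != 0L)) {
    stop("size must be two even integers >= 16", call. = FALSE)
  }
  num_classes <- as.integer(num_classes)
  if (num_classes < 2L || num_classes > 4L) {
    stop("num_classes must be between 2 (background + whole tumor) and 4",
         call. = FALSE)
  }
  if (is.null(means)) {
    means <- switch(num_classes - 1L,
                    c(0.2, 0.9),
                    c(0.2, 0.6, 0.9),
                    c(0.2, 0.55, 0.75, 0.95))
  }
  if (length(means) != num_classes) {
    stop("means must have one entry per class", call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be non-negative", call. = FALSE)
  structure(list(size = size, num_classes = num_classes, means = means,
                 noise_sigma = noise_sigma, texture_scale = texture_scale,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Elliptical mask on the pixel grid (1-based centers, rotation in radians).
.ellipse_mask <- function(size, cx, cy, a, b, theta) {
  rr <- matrix(seq_len(size[1]), size[1], size[2])
  cc <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  u <- ((rr - cx) * cos(theta) + (cc - cy) * sin(theta)) / a
  v <- (-(rr - cx) * sin(theta) + (cc - cy) * cos(theta)) / b
  u * u + v * v <= 1
}

#' Generate one synthetic tumor phantom
#'
#' Draws a whole-tumor ellipse with random center, axes and rotation, and
#' (for `num_classes > 2`) concentric scaled copies for the tumor-core and
#' enhancing-tumor sub-regions, so the label nesting
#' ET-region within TC-region within WT-region holds by construction.
#' Pixel intensities are the per-class means plus background texture plus
#' Gaussian noise.  Ellipses that would cross the image border are
#' resampled internally, never an error.
#'
#' @param config A [phantom_config()].
#' @return Object of class `phantom_sample`: list with `image` (numeric
#'   matrix), `labels` (integer matrix, values `0..L-1`), and `meta`
#'   (config echo plus the ellipse parameters drawn).
#' @export
generate_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) {
    stop("config must be a phantom_config", call. = FALSE)
  }
  .with_seed(config$seed, {
    size <- config$size
    L <- config$num_classes
    n_min <- min(size)
    repeat {
      cx <- stats::runif(1, 0.35, 0.65) * size[1]
      cy <- stats::runif(1, 0.35, 0.65) * size[2]
      a <- stats::runif(1, 0.18, 0.30) * n_min
      b <- stats::runif(1, 0.18, 0.30) * n_min
      theta <- stats::runif(1, 0, pi)
      r <- max(a, b)
      inside <- cx - r >= 1 && cx + r <= size[1] &&
        cy - r >= 1 && cy + r <= size[2]
      if (inside) break
    }
    # Concentric scaled ellipses guarantee the nesting invariant.
    scales <- c(1, 0.6, 0.35)[seq_len(L - 1L)]
    labels <- matrix(0L, size[1], size[2])
    for (k in seq_len(L - 1L)) {
      m <- .ellipse_mask(size, cx, cy, a * scales[k], b * scales[k], theta)
      labels[m] <- k
    }
    image <- matrix(config$means[labels + 1L], size[1], size[2])
    if (config$texture_scale != 0) {
      rr <- matrix(seq_len(size[1]), size[1], size[2])
      cc <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
      for (j in 1:3) {
        fr <- stats::runif(1, 0.5, 2) / size[1]
        fc <- stats::runif(1, 0.5, 2) / size[2]
        phase <- stats::runif(1, 0, 2 * pi)
        image <- image +
          config$texture_scale * cos(2 * pi * (fr * rr + fc * cc) + phase)
      }
    }
    if (config$noise_sigma > 0) {
      image <- image + matrix(stats::rnorm(prod(size), 0, config$noise_sigma),
                              size[1], size[2])
    }
    structure(list(image = image, labels = labels,
                   meta = c(unclass(config),
                            list(ellipse = list(cx = cx, cy = cy, a = a,
                                                b = b, theta = theta,
                                                scales = scales)))),
              class = "phantom_sample")
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat("<phantom_sample> ", nrow(x$image), "x", ncol(x$image),
      ", classes ", paste(sort(unique(as.vector(x$labels))), collapse = "/"),
      ", seed ", x$meta$seed, "\n", sep = "")
  invisible(x)
}

#' Display a phantom and its label map
#'
#' @param x A `phantom_sample`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.phantom_sample <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(t(x$image[nrow(x$image):1, ]), axes = FALSE,
                  col = grDevices::gray.colors(256), main = "image", ...)
  graphics::image(t(x$labels[nrow(x$labels):1, ]), axes = FALSE,
                  main = "labels", ...)
  invisible(x)
}

#' Generate a deterministic phantom dataset
#'
#' `n` samples seeded `base_seed, base_seed + 1, ..., base_seed + n - 1`;
#' with overwhelming probability the geometries are pairwise distinct.
#'
#' @param n Number of samples, >= 1.
#' @param config A [phantom_config()]; its `seed` field is overridden per
#'   sample.
#' @param base_seed First seed of the run.
#' @return List of `n` [generate_phantom()] samples.
#' @export
generate_dataset <- function(n, config, base_seed = 0L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be at least 1", call. = FALSE)
  }
  lapply(seq_len(n) - 1L, function(i) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i)
    generate_phantom(cfg)
  })
}

#' Write a phantom sample as paired PNG files plus JSON metadata
#'
#' The image is linearly rescaled to 8-bit; the original range is stored
#' in the metadata.  Labels are stored losslessly (value / 255).
#'
#' @param sample A `phantom_sample`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem, e.g. `"sample_001"`.
#' @return Named character vector of the three paths written, invisibly.
#' @export
write_phantom <- function(sample, dir, stem) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(stem, "_image.png"))
  lab_path <- file.path(dir, paste0(stem, "_labels.png"))
  meta_path <- file.path(dir, paste0(stem, "_meta.json"))
  rng <- range(sample$image)
  scaled <- if (diff(rng) > 0) (sample$image - rng[1]) / diff(rng) else
    sample$image * 0
  png::writePNG(scaled, img_path)
  png::writePNG(sample$labels / 255, lab_path)
  meta <- sample$meta
  meta$intensity_range <- rng
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(image = img_path, labels = lab_path, meta = meta_path))
}

#' Read a label PNG written by [write_phantom()] or [write_mask()]
#'
#' @param path PNG file path.
#' @return Integer label matrix.
#' @export
read_label_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}
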