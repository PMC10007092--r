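# Readers/writers for NIfTI volumes and PNG slices, and slice iteration.
# Axis convention: 0-based concepts documented as (row, col, slice);
# arrays are 1-based R arrays in that order.  NIfTI metadata is passed
# through untouched — resampling is out of scope.

.is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
.is_png_path <- function(path) grepl("\\.png$", path, ignore.case = TRUE)

#' Read a volume from NIfTI or PNG
#'
#' NIfTI-1/2 files (`.nii`, `.nii.gz`) are read with their voxel spacing
#' and full header preserved; a PNG is treated as a single-slice volume
#' with unit spacing (multi-channel PNGs are averaged to grayscale).
#'
#' @param path File path.
#' @return Object of class `volume_handle`: list with `data` (3D numeric
#'   array `(rows, cols, slices)`), `spacing` (per-axis mm), `header`
#'   (NIfTI header or `NULL`) and `source`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read volume: '", path, "' does not exist", call. = FALSE)
  }
  if (.is_nifti_path(path)) {
    img <- tryCatch(RNifti::readNifti(path), error = function(e) {
      stop("failed to parse NIfTI file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
    dat <- as.array(img)
    if (length(dim(dat)) == 2L) dim(dat) <- c(dim(dat), 1L)
    if (length(dim(dat)) != 3L) {
      stop("'", path, "' has ", length(dim(dat)),
           " dimensions; expected a 2D/3D volume", call. = FALSE)
    }
    spacing <- RNifti::pixdim(img)
    if (length(spacing) < 3L) spacing <- c(spacing, rep(1, 3L - length(spacing)))
    structure(list(data = dat, spacing = spacing[1:3],
                   header = RNifti::niftiHeader(img), source = path),
              class = "volume_handle")
  } else if (.is_png_path(path)) {
    m <- tryCatch(png::readPNG(path), error = function(e) {
      stop("failed to parse PNG file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
    if (length(dim(m)) == 3L) m <- apply(m, c(1, 2), mean)
    structure(list(data = array(m, c(dim(m), 1L)), spacing = c(1, 1, 1),
                   header = NULL, source = path),
              class = "volume_handle")
  } else {
    stop("unsupported volume format: '", path,
         "' (expected .nii, .nii.gz or .png)", call. = FALSE)
  }
}

#' @export
print.volume_handle <- function(x, ...) {
  cat("<volume_handle> ", paste(dim(x$data), collapse = "x"),
      ", spacing ", paste(format(x$spacing, digits = 4), collapse = "x"),
      " mm\n", sep = "")
  invisible(x)
}

#' Iterate over the 2D planes of a volume
#'
#' @param volume A [read_volume()] handle (or 3D array).
#' @param axis Axis to slice along: 1 (rows), 2 (cols) or 3 (slices,
#'   default).
#' @return List of numeric matrices, one per plane; length equals the
#'   extent of `axis`.
#' @export
slice_iter <- function(volume, axis = 3L) {
  dat <- if (inherits(volume, "volume_handle")) volume$data else volume
  if (!is.array(dat) || length(dim(dat)) != 3L) {
    stop("volume must be 3D", call. = FALSE)
  }
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3", call. = FALSE)
  lapply(seq_len(dim(dat)[axis]), function(i) {
    switch(axis, dat[i, , ], dat[, i, ], dat[, , i])
  })
}

#' Write a label mask as NIfTI (uint8) or PNG
#'
#' Round-trips losslessly: reading the file back with [read_mask()]
#' reproduces the labels exactly.  When a reference volume is given for
#' NIfTI output, its header (affine, spacing) is attached untouched.
#'
#' @param labels Integer matrix or 3D array of class labels (0..255).
#' @param path Output path ending in `.nii`, `.nii.gz` or `.png` (PNG
#'   requires 2D labels).
#' @param reference Optional [read_volume()] handle supplying NIfTI
#'   metadata.
#' @return `path`, invisibly.
#' @export
write_mask <- function(labels, path, reference = NULL) {
  storage.mode(labels) <- "integer"
  if (any(labels < 0L | labels > 255L)) {
    stop("labels must lie in 0..255", call. = FALSE)
  }
  ok <- tryCatch({
    if (.is_nifti_path(path)) {
      img <- if (!is.null(reference) && !is.null(reference$header)) {
        RNifti::asNifti(labels, reference = reference$header)
      } else {
        RNifti::asNifti(labels)
      }
      RNifti::writeNifti(img, path, datatype = "uint8")
    } else if (.is_png_path(path)) {
      if (length(dim(labels)) == 3L && dim(labels)[3] == 1L) {
        labels <- labels[, , 1]
      }
      if (length(dim(labels)) != 2L) {
        stop("PNG masks must be 2D", call. = FALSE)
      }
      png::writePNG(labels / 255, path)
    } else {
      stop("unsupported mask format: '", path, "'", call. = FALSE)
    }
    TRUE
  }, error = function(e) {
    stop("failed to write mask to '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}

#' Read a label mask written by [write_mask()]
#'
#' @param path Mask path (`.nii`, `.nii.gz` or `.png`).
#' @return Integer label matrix (or 3D array for multi-slice NIfTI).
#' @export
read_mask <- function(path) {
  if (.is_png_path(path)) return(read_label_png(path))
  vol <- read_volume(path)
  dat <- vol$data
  out <- array(as.integer(round(dat)), dim(dat))
  if (dim(out)[3] == 1L) out <- out[, , 1]
  out
}

#' Restack 2D planes into a volume
#'
#' Inverse of [slice_iter()] for the same axis.
#'
#' @param planes List of matrices of one shape.
#' @param axis Axis along which they were sliced.
#' @return 3D array.
#' @export
stack_slices <- function(planes, axis = 3L) {
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3", call. = FALSE)
  d2 <- dim(planes[[1]])
  n <- length(planes)
  out <- switch(axis,
                array(0, c(n, d2)),
                array(0, c(d2[1], n, d2[2])),
                array(0, c(d2, n)))
  for (i in seq_len(n)) {
    switch(axis,
           out[i, , ] <- planes[[i]],
           out[, i, ] <- planes[[i]],
           out[, , i] <- planes[[i]])
  }
  out
}
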