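# Evaluation metric suite: confusion counts, classification rates,
# MSE/PSNR, per-class Dice, and report writers.

#' One-vs-rest pixel confusion counts
#'
#' Tallies true/false positive/negative pixels for one positive class of a
#' pair of integer label maps.  The four counts always sum to the total
#' pixel count.
#'
#' @param pred_labels,true_labels Integer label maps (matrices or arrays)
#'   of one shape.
#' @param positive_class Label value treated as positive.
#' @return Object of class `confusion_counts`: list with `tp`, `fp`, `tn`,
#'   `fn`, `total`.
#' @export
confusion <- function(pred_labels, true_labels, positive_class = 1L) {
  if (!identical(dim(pred_labels), dim(true_labels)) ||
      length(pred_labels) != length(true_labels)) {
    stop("pred_labels and true_labels must have identical shapes", call. = FALSE)
  }
  p <- pred_labels == positive_class
  t <- true_labels == positive_class
  counts <- list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t))
  counts$total <- counts$tp + counts$fp + counts$tn + counts$fn
  structure(counts, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> tp =", x$tp, " fp =", x$fp,
      " tn =", x$tn, " fn =", x$fn, "\n")
  invisible(x)
}

#' Classification rates from confusion counts
#'
#' Standard definitions: accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`,
#' recall = sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`.  A zero
#' denominator yields `NA` (an explicit undefined marker), never a silent
#' 0.  `paper_exact = TRUE` reproduces an alternative printed convention
#' in which sensitivity is `TP/(TP+FP)` and specificity `TN/(TP+FP)`;
#' the standard forms are the default and the documented behaviour.
#'
#' @param counts A [confusion()] result.
#' @param paper_exact Use the non-standard printed formulas for
#'   sensitivity and specificity (default `FALSE`).
#' @return Object of class `metrics_report`: list with `accuracy`,
#'   `precision`, `recall`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(counts, paper_exact = FALSE) {
  if (!inherits(counts, "confusion_counts")) {
    stop("counts must be a confusion_counts object", call. = FALSE)
  }
  if (counts$total <= 0) stop("confusion counts are empty", call. = FALSE)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  out <- list(
    accuracy = rate(tp + tn, tp + tn + fp + fn),
    precision = rate(tp, tp + fp),
    recall = rate(tp, tp + fn),
    sensitivity = if (paper_exact) rate(tp, tp + fp) else rate(tp, tp + fn),
    specificity = if (paper_exact) rate(tn, tp + fp) else rate(tn, tn + fp)
  )
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.numeric(v) && length(v) == 1L) {
      cat(sprintf("  %-12s %s\n", nm,
                  if (is.na(v)) "NA" else format(v, digits = 6)))
    } else if (is.numeric(v)) {
      cat(sprintf("  %-12s %s\n", nm,
                  paste(format(v, digits = 4), collapse = " ")))
    }
  }
  invisible(x)
}

#' Mean squared error between two images
#'
#' Mean of squared pixel differences over all `k` pixels; 0 iff the
#' images are identical.
#'
#' @param pred,actual Numeric matrices/arrays of one shape.
#' @return Non-negative scalar.
#' @export
mse <- function(pred, actual) {
  if (!identical(dim(pred), dim(actual)) || length(pred) != length(actual)) {
    stop("pred and actual must have identical shapes", call. = FALSE)
  }
  mean((pred - actual)^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in decibels; `+Inf` when the images are
#' identical (zero MSE).
#'
#' @param pred,ref Numeric matrices/arrays of one shape.
#' @param peak Positive peak signal value (default 1).
#' @return PSNR in dB, `Inf` for identical inputs.
#' @export
psnr <- function(pred, ref, peak = 1) {
  if (!is.numeric(peak) || length(peak) != 1L || !is.finite(peak) || peak <= 0) {
    stop("peak must be a single positive number", call. = FALSE)
  }
  m <- mse(pred, ref)
  if (m == 0) return(Inf)
  10 * log10(peak^2 / m)
}

#' Hard Dice coefficient of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; returns `NA` when both masks are
#' empty.
#'
#' @param pred_mask,true_mask Logical or 0/1 masks of one shape.
#' @return Scalar in `[0, 1]`, or `NA`.
#' @export
dice_coefficient <- function(pred_mask, true_mask) {
  if (!identical(dim(pred_mask), dim(true_mask))) {
    stop("masks must have identical shapes", call. = FALSE)
  }
  p <- as.logical(pred_mask)
  t <- as.logical(true_mask)
  den <- sum(p) + sum(t)
  if (den == 0) return(NA_real_)
  2 * sum(p & t) / den
}

#' Full segmentation evaluation report
#'
#' Computes one row of classification rates and the hard Dice coefficient
#' per requested class, plus optional reconstruction MSE/PSNR when a
#' predicted and reference image are supplied.
#'
#' @param pred_labels,true_labels Integer label maps of one shape.
#' @param classes Integer class labels to evaluate one-vs-rest; default:
#'   every non-background (`> 0`) label present in the truth.
#' @param image_pred,image_ref Optional numeric images for MSE/PSNR.
#' @param peak Peak value for PSNR (default: dynamic range of
#'   `image_ref`).
#' @param paper_exact Passed to [classification_metrics()].
#' @return A `data.frame` with one row per class: `class`, `dice`,
#'   `accuracy`, `precision`, `recall`, `sensitivity`, `specificity`, and
#'   (constant across rows, when images are given) `mse`, `psnr`.
#' @export
segmentation_report <- function(pred_labels, true_labels, classes = NULL,
                                image_pred = NULL, image_ref = NULL,
                                peak = NULL, paper_exact = FALSE) {
  if (is.null(classes)) {
    classes <- sort(setdiff(unique(as.vector(true_labels)), 0))
    if (length(classes) == 0L) classes <- 1L
  }
  rows <- lapply(classes, function(cl) {
    cm <- classification_metrics(confusion(pred_labels, true_labels, cl),
                                 paper_exact = paper_exact)
    data.frame(class = cl,
               dice = dice_coefficient(pred_labels == cl, true_labels == cl),
               accuracy = cm$accuracy, precision = cm$precision,
               recall = cm$recall, sensitivity = cm$sensitivity,
               specificity = cm$specificity)
  })
  out <- do.call(rbind, rows)
  if (!is.null(image_pred) && !is.null(image_ref)) {
    out$mse <- mse(image_pred, image_ref)
    if (is.null(peak)) peak <- diff(range(image_ref))
    out$psnr <- psnr(image_pred, image_ref, peak = peak)
  }
  out
}

#' Write a metrics report as JSON
#'
#' @param report A `metrics_report` or `data.frame` from
#'   [segmentation_report()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a metrics report as a flat TSV
#'
#' One row per class for data-frame reports, a single row otherwise.
#'
#' @inheritParams write_metrics_json
#' @export
write_metrics_tsv <- function(report, path) {
  df <- if (is.data.frame(report)) report else as.data.frame(unclass(report))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
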