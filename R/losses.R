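# Dice loss family and the regularized total loss.

.as_class_array <- function(x, what) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop(what, " must be a (height, width, classes) array", call. = FALSE)
  }
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  x
}

#' Multi-class soft Dice loss
#'
#' `1 - sum_l w_l * (2 * sum_g p(l,g) t(l,g) + eps) /
#' (sum_g p(l,g)^2 + sum_g t(l,g)^2 + eps)`, the squared-sum Dice overlap
#' per class, combined with class weights that must sum to one.  The
#' smoothing `eps` appears in numerator and denominator so that perfect
#' overlap gives a loss of exactly 0 and an empty class (absent from both
#' prediction and truth) contributes no loss.  Differentiable in `probs`.
#'
#' @param probs Predicted per-pixel class probabilities,
#'   `(height, width, classes)` (a matrix is treated as one class).
#' @param onehot Ground-truth one-hot labels, same shape.
#' @param weights Class weights, non-negative, summing to 1; default
#'   uniform `1/L`.
#' @param eps Smoothing constant (default `1e-6`).
#' @return Scalar in `[0, 1]`: 0 at perfect overlap, 1 for fully disjoint
#'   hard masks.
#' @export
dice_loss <- function(probs, onehot, weights = NULL, eps = 1e-6) {
  probs <- .as_class_array(probs, "probs")
  onehot <- .as_class_array(onehot, "onehot")
  if (!identical(dim(probs), dim(onehot))) {
    stop("probs and onehot must have identical shapes", call. = FALSE)
  }
  L <- dim(probs)[3]
  if (is.null(weights)) weights <- rep(1 / L, L)
  if (length(weights) != L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be ", L, " non-negative values summing to 1", call. = FALSE)
  }
  terms <- vapply(seq_len(L), function(l) {
    p <- probs[, , l]
    t <- onehot[, , l]
    (2 * sum(p * t) + eps) / (sum(p * p) + sum(t * t) + eps)
  }, numeric(1))
  1 - sum(weights * terms)
}

#' Total training loss: Dice plus L2 regularization
#'
#' `total = dice + lambda * sum(W^2)` over all weight arrays (biases are
#' excluded).  With `lambda = 0` the total equals the Dice term exactly.
#'
#' @param dice Scalar Dice loss value.
#' @param params Named list of parameter arrays; elements whose terminal
#'   name component starts with `"W"` count as weights (the convention
#'   used by [sswan_init()] and the block parameter constructors).
#' @param lambda Non-negative regularization coefficient (default `1e-4`).
#' @return Scalar total loss.
#' @export
total_loss <- function(dice, params, lambda = 1e-4) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("lambda must be a single non-negative number", call. = FALSE)
  }
  if (lambda == 0) return(dice)
  dice + lambda * .weight_sq_sum(params)
}

.is_weight_name <- function(nms) {
  leaf <- sub(".*\\.", "", nms)
  startsWith(leaf, "W")
}

.weight_sq_sum <- function(params) {
  flat <- .flatten_params(params)
  nms <- names(flat)
  sum(vapply(which(.is_weight_name(nms)),
             function(i) sum(flat[[i]]^2), numeric(1)))
}

# Flatten nested parameter lists into one level with dot-joined names.
.flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    el <- p[[nm]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(el)) {
      out <- c(out, .flatten_params(el, key))
    } else if (is.numeric(el)) {
      out[[key]] <- el
    }
  }
  out
}

#' Lesion-weighted binary Dice loss
#'
#' Binary (foreground/background) Dice loss in which the ground-truth sum
#' in the denominator is weighted 3:1 against the prediction sum:
#' `1 - 4 * sum(p t) / (sum(p^2) + 3 * sum(t^2))` (smoothed), the factor 4
#' renormalizing so that a perfect prediction still scores 0.  The 1:3
#' weighting penalizes under-segmentation of the lesion more than
#' over-segmentation.
#'
#' @param pred Predicted foreground map, values in `[0, 1]`.
#' @param truth Ground-truth foreground mask, strictly binary (0/1).
#' @param eps Smoothing constant (default `1e-6`).
#' @return Scalar in `[0, 1]`.
#' @export
weighted_dice_loss <- function(pred, truth, eps = 1e-6) {
  if (!is.numeric(pred) || !is.numeric(truth) ||
      !identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    stop("pred and truth must be numeric objects of one shape", call. = FALSE)
  }
  if (any(!is.finite(pred)) || any(pred < 0 | pred > 1)) {
    stop("pred must lie in [0, 1]", call. = FALSE)
  }
  if (!all(truth %in% c(0, 1))) {
    stop("truth must be a binary (0/1) mask", call. = FALSE)
  }
  num <- 4 * sum(pred * truth) + eps
  den <- sum(pred^2) + 3 * sum(truth^2) + eps
  1 - num / den
}
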