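# Training loop: full-batch Adam on the joint Dice + reconstruction loss.

#' Train an SSW-AN on a set of labelled 2D samples
#'
#' Full-batch gradient descent with Adam on the joint objective
#' `dice_weight * Dice + recon_weight * MSE(reconstruction) +
#' lambda * ||W||^2`.  The Dice term is the per-sample multi-class soft
#' Dice loss (uniform class weights) averaged over the batch; the
#' reconstruction term ties the wavelet-residual trunk to the z-scored
#' input images.  Deterministic given `config$seed`.
#'
#' @param samples List of samples, each with `$image` (even-sized numeric
#'   matrix) and `$labels` (integer matrix, `0..L-1`), e.g. from
#'   [generate_dataset()].
#' @param config A [sswan_config()].
#' @param epochs Number of full-batch epochs (default 200).
#' @param lr Adam learning rate (default 1e-3).
#' @param dice_weight,recon_weight Loss term weights (defaults 1, 1).
#' @param lambda L2 regularization coefficient on weights (default 1e-4).
#' @param params Optional warm-start parameters; default [sswan_init()].
#' @param verbose Print a log line every `log_every` epochs.
#' @param log_every Logging stride (default 20).
#' @return Object of class `sswan_fit`: list with `params`, `config`,
#'   `history` (data.frame: epoch, loss, loss_dice, loss_recon,
#'   mean_fg_dice) and `epochs_run`.
#' @export
sswan_train <- function(samples, config, epochs = 200L, lr = 1e-3,
                        dice_weight = 1, recon_weight = 1, lambda = 1e-4,
                        params = NULL, verbose = FALSE, log_every = 20L) {
  stopifnot(inherits(config, "sswan_config"))
  if (length(samples) < 1L) stop("need at least one training sample", call. = FALSE)
  batch <- .sswan_batch(samples, config)
  if (is.null(params)) params <- sswan_init(config)
  mstate <- lapply(params, function(a) a * 0)
  vstate <- lapply(params, function(a) a * 0)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    res <- .sswan_loss_and_grads(params, batch, config,
                                 dice_weight = dice_weight,
                                 recon_weight = recon_weight,
                                 lambda = lambda, want_grads = TRUE)
    for (nm in names(params)) {
      gv <- res$grads[[nm]]
      mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gv
      vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gv^2
      mhat <- mstate[[nm]] / (1 - b1^ep)
      vhat <- vstate[[nm]] / (1 - b2^ep)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + adam_eps)
    }
    fg <- .batch_hard_dice(res$probs, batch$LAB, batch$L)
    history[[ep]] <- data.frame(epoch = ep, loss = res$loss,
                                loss_dice = res$loss_dice,
                                loss_recon = res$loss_rec,
                                mean_fg_dice = fg)
    if (verbose && (ep %% log_every == 0L || ep == 1L)) {
      message(sprintf("%s [sswan] epoch %4d  loss %.5f  dice-loss %.5f  recon %.5f  fg-dice %.4f",
                      format(Sys.time(), "%H:%M:%S"), ep, res$loss,
                      res$loss_dice, res$loss_rec, fg))
    }
  }
  structure(list(params = params, config = config,
                 history = do.call(rbind, history), epochs_run = epochs),
            class = "sswan_fit")
}

#' @export
print.sswan_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat("<sswan_fit> T = ", x$config$num_blocks, ", w = ", x$config$width,
      ", ", x$epochs_run, " epochs; final loss ",
      format(last$loss, digits = 5), ", mean foreground Dice ",
      format(last$mean_fg_dice, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Segment new images with a trained network
#'
#' @param fit A [sswan_train()] result.
#' @param image Numeric matrix (one slice).
#' @return A `sswan_segmentation`, see [segment()].
#' @export
sswan_predict <- function(fit, image) {
  stopifnot(inherits(fit, "sswan_fit"))
  segment(image, fit$params, fit$config)
}

#' Evaluate a trained network on labelled samples
#'
#' Runs [segment()] on every sample and reports the mean hard foreground
#' Dice plus mean reconstruction PSNR (peak = dynamic range of each
#' input image).
#'
#' @param fit A [sswan_train()] result.
#' @param samples List of samples with `$image` and `$labels`.
#' @return List with `mean_fg_dice`, `mean_psnr`, and `per_sample`
#'   (data.frame: sample, fg_dice, psnr).
#' @export
sswan_evaluate <- function(fit, samples) {
  L <- fit$config$num_classes
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    seg <- sswan_predict(fit, s$image)
    ds <- vapply(seq_len(L - 1L), function(l) {
      dice_coefficient(seg$label_map == l, s$labels == l)
    }, numeric(1))
    pk <- diff(range(s$image))
    if (pk == 0) pk <- 1
    data.frame(sample = i, fg_dice = mean(ds, na.rm = TRUE),
               psnr = psnr(seg$reconstructed, s$image, peak = pk))
  })
  per <- do.call(rbind, rows)
  list(mean_fg_dice = mean(per$fg_dice), mean_psnr = mean(per$psnr),
       per_sample = per)
}
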