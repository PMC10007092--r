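# The desk-scale overfit protocol shared by the functional smoke tests:
# 16 two-class 64x64 phantoms (noise sd 0.05, seeds 0..15), SSW-AN with
# T = 2 blocks, reduction 4, Adam 1e-3, 200 full-batch epochs.  Training
# is deterministic given the seed, so runs are cached per width.
.overfit_cache <- new.env(parent = emptyenv())

overfit_protocol <- function(width) {
  key <- paste0("w", width)
  hit <- .overfit_cache[[key]]
  if (!is.null(hit)) return(hit)
  cfg <- sswan_config(num_blocks = 2L, width = as.integer(width),
                      reduction = 4L, num_classes = 2L, seed = 0L)
  samples <- generate_dataset(16, phantom_config(size = c(64, 64),
                                                 num_classes = 2,
                                                 noise_sigma = 0.05),
                              base_seed = 0)
  elapsed <- system.time(
    fit <- sswan_train(samples, cfg, epochs = 200L, lr = 1e-3)
  )[["elapsed"]]
  res <- list(fit = fit, samples = samples,
              eval = sswan_evaluate(fit, samples), elapsed = elapsed)
  .overfit_cache[[key]] <- res
  res
}
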