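# Checkpoints: one JSON file holding the config echo and every named
# parameter group (full double precision).

#' Save network parameters and config to a JSON checkpoint
#'
#' @param fit A [sswan_train()] fit, or a list with `params`
#'   ([sswan_init()] output) and `config` ([sswan_config()]).
#' @param path Output file path (`.json`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  params <- fit$params
  obj <- list(
    format = "sswan-checkpoint-1",
    config = unclass(fit$config),
    params = lapply(unclass(params), function(a) {
      list(dim = if (is.null(dim(a))) length(a) else dim(a),
           data = as.vector(a))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a JSON checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint file path.
#' @return List with `params` (class `sswan_params`) and `config`
#'   (class `sswan_config`).
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint '", path, "' not found", call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "sswan-checkpoint-1")) {
    stop("'", path, "' is not an sswan checkpoint", call. = FALSE)
  }
  cfg <- do.call(sswan_config, obj$config)
  params <- lapply(obj$params, function(el) {
    a <- as.numeric(el$data)
    if (length(el$dim) > 1L) dim(a) <- el$dim
    a
  })
  class(params) <- "sswan_params"
  list(params = params, config = cfg)
}
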