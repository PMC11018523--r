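#' Save model weights and configuration
#'
#' Writes a self-describing checkpoint: all layer weights keyed by layer
#' name (RDS container at \code{path}) plus a plain-text YAML sidecar
#' (\code{path.yaml}) holding the model/encoder configuration.
#'
#' @param model an \code{rs_model}.
#' @param path destination file (e.g. \code{"model.rds"}).
#' @return \code{path}, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  layers <- rs_layers(model)
  weights <- lapply(layers, function(l) l$params)
  names(weights) <- vapply(layers, function(l) l$name, "")
  bns <- lapply(layers, function(l)
    if (!is.null(l$run_mean)) list(mean = l$run_mean, var = l$run_var))
  saveRDS(list(weights = weights, bn_stats = bns), path)
  cfg <- model$encoder$config
  yaml::write_yaml(list(
    package = "rootseg",
    variant = model$variant, size_tag = model$size_tag,
    n_classes = model$n_classes, seed = model$seed,
    encoder = list(stage_channels = cfg$stage_channels,
                   stage_depths = cfg$stage_depths,
                   stage_heads = cfg$stage_heads,
                   stage_reduction = cfg$stage_reduction,
                   mlp_ratio = cfg$mlp_ratio)),
    paste0(path, ".yaml"))
  invisible(path)
}

#' Load a model from a checkpoint
#'
#' Rebuilds the architecture from the YAML sidecar and restores all
#' weights (and batch-norm running statistics).
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @return An \code{rs_model}.
#' @export
load_checkpoint <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  blob <- readRDS(path)
  model <- build_model(meta$variant, meta$size_tag, meta$n_classes,
                       meta$seed)
  layers <- rs_layers(model)
  stopifnot(length(layers) == length(blob$weights))
  for (i in seq_along(layers)) {
    stopifnot(identical(layers[[i]]$name, names(blob$weights)[i]))
    layers[[i]]$params <- blob$weights[[i]]
    if (!is.null(blob$bn_stats[[i]])) {
      layers[[i]]$run_mean <- blob$bn_stats[[i]]$mean
      layers[[i]]$run_var <- blob$bn_stats[[i]]$var
    }
  }
  model
}
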