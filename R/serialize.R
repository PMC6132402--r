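# Checkpointing: weights in R's native serialization (.rds) with a
# human-readable architecture JSON sidecar.

#' Save / load a trained model
#'
#' Writes the model to `path` (RDS) and an architecture summary to
#' `paste0(path, ".json")`.
#'
#' @param model A `patch_model`, `fcn_model`, `patch_fit` or `fcn_fit`.
#' @param path Checkpoint path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (inherits(model, c("patch_fit", "fcn_fit"))) model <- model$model
  arch <- if (inherits(model, "patch_model")) {
    list(type = "patch", variant = model$cfg$variant,
         conv_filters = model$cfg$conv_filters, kernel = model$cfg$kernel,
         fc_sizes = model$cfg$fc_sizes, half_size = model$cfg$half_size,
         conv_parameters = count_conv_parameters(model$cfg))
  } else if (inherits(model, "fcn_model")) {
    list(type = "fcn", width_scale = model$cfg$width_scale,
         channels = model$cfg$channels, dec_channels = model$cfg$dec_channels,
         unpool_factors = model$cfg$unpool_factors,
         final_upsample = model$cfg$final_upsample)
  } else abort("not a model object")
  saveRDS(model, path)
  jsonlite::write_json(arch, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    abort(paste0("model checkpoint not found: ", path))
  m <- readRDS(path)
  if (!inherits(m, c("patch_model", "fcn_model")))
    abort(paste0("not a model checkpoint: ", path))
  m
}

# 32-bit FNV-1a hash of an R object's serialized bytes, for provenance
# stamps in run reports.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
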