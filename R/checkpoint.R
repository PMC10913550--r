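# Checkpointing: weights in RDS (bit-exact), config and vocabulary as JSON
# sidecars for inspection and exact vocabulary reload.

#' Save / load an autoencoder checkpoint
#'
#' Writes `model.rds` (all weights, bit-exact), `vocab.json` (ordered token
#' list for exact reload) and `config.json` (architecture, representation,
#' maxLen, init seed) into `dir`.
#'
#' @param model a [MolAutoencoder-class].
#' @param dir checkpoint directory (created if missing).
#' @return `saveCheckpoint` the directory path; `loadCheckpoint` the model.
#' @export
saveCheckpoint <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  writeVocabulary(model@vocab, file.path(dir, "vocab.json"))
  cfg <- model@config
  jsonlite::write_json(list(
    cell = cfg@cell, hiddenSize = cfg@hiddenSize,
    latentSize = cfg@latentSize, numLayers = cfg@numLayers,
    attention = cfg@attention, variational = cfg@variational,
    klWeight = cfg@klWeight, representation = model@representation,
    maxLen = model@maxLen, seed = model@seed),
    file.path(dir, "config.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path)) stop("no checkpoint at ", dir)
  readRDS(path)
}
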