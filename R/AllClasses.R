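#' @import methods
#' @importFrom stats rnorm runif var prcomp dist setNames median
#' @importFrom utils adist head tail
NULL

#' Vocabulary of string tokens with reserved specials
#'
#' An ordered token set shared between the encoder input and the decoder
#' output.  The three special tokens PAD, SOS and EOS always occupy indices
#' 0, 1 and 2; chemistry tokens follow in lexicographic order, so encodings
#' are bit-reproducible across runs.  Indices are 0-based (see
#' [tokenIndex()]).
#'
#' @slot tokens character vector of all tokens, specials first.
#' @slot specials named character vector with elements `pad`, `sos`, `eos`.
#' @export
setClass("Vocabulary",
  representation(tokens = "character", specials = "character"))

setValidity("Vocabulary", function(object) {
  msg <- character()
  sp <- object@specials
  if (!identical(sort(names(sp)), c("eos", "pad", "sos")))
    msg <- c(msg, "specials must be named pad, sos, eos")
  if (anyDuplicated(object@tokens))
    msg <- c(msg, "tokens must be distinct")
  if (length(sp) == 3L && !identical(unname(object@tokens[1:3]),
                                     unname(sp[c("pad", "sos", "eos")])))
    msg <- c(msg, "tokens must start with pad, sos, eos")
  if (length(msg)) msg else TRUE
})

#' A set of molecules with canonical SMILES and optional companions
#'
#' Container for a molecule corpus: one canonical SMILES per molecule, an
#' optional SELFIES translation and an optional list of non-canonical
#' (enumerated) SMILES per molecule.  Every enumeration canonicalizes to
#' its molecule's canonical SMILES.
#'
#' @slot smiles character vector of canonical SMILES.
#' @slot selfies character vector of SELFIES strings (or `NA`), parallel to
#'   `smiles`.
#' @slot enumerations list of character vectors of non-canonical SMILES,
#'   parallel to `smiles` (possibly empty vectors).
#' @export
setClass("MoleculeSet",
  representation(smiles = "character", selfies = "character",
                 enumerations = "list"))

setValidity("MoleculeSet", function(object) {
  n <- length(object@smiles)
  if (length(object@selfies) != n)
    return("selfies must be parallel to smiles")
  if (length(object@enumerations) != n)
    return("enumerations must be parallel to smiles")
  TRUE
})

#' Autoencoder architecture configuration
#'
#' Describes one member of the architecture family: recurrent cell type,
#' hidden size, latent size, layer count, additive encoder attention and an
#' optional variational head with Kullback-Leibler weight.  The reference
#' base configuration is a single-layer cell with hidden and latent size 64
#' and no attention.
#'
#' @slot cell `"gru"` or `"lstm"`.
#' @slot hiddenSize positive integer, recurrent state width H.
#' @slot latentSize positive integer, latent width L.
#' @slot numLayers integer in 1..3.
#' @slot attention logical, additive self-attention over encoder steps.
#' @slot variational logical, diagonal-Gaussian variational head.
#' @slot klWeight non-negative KL weight (used only when variational).
#' @export
setClass("ModelConfig",
  representation(cell = "character", hiddenSize = "integer",
                 latentSize = "integer", numLayers = "integer",
                 attention = "logical", variational = "logical",
                 klWeight = "numeric"))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (!object@cell %in% c("gru", "lstm"))
    msg <- c(msg, "cell must be 'gru' or 'lstm'")
  if (object@hiddenSize < 1L) msg <- c(msg, "hiddenSize must be positive")
  if (object@latentSize < 1L) msg <- c(msg, "latentSize must be positive")
  if (!object@numLayers %in% 1:3) msg <- c(msg, "numLayers must be 1, 2 or 3")
  if (object@klWeight < 0) msg <- c(msg, "klWeight must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Training protocol configuration
#'
#' Optimizer and early-stopping settings: Adam with learning rate 0.005,
#' a minimum of 50 and maximum of 500 epochs, early stopping on validation
#' loss with minimum delta 0.01 and patience 5, three seeds by default, and
#' an enumeration pairing mode (`can2can`, `enum2can`, `can2enum`).
#'
#' @slot learningRate Adam learning rate.
#' @slot minEpochs,maxEpochs epoch bounds honoured by early stopping.
#' @slot minDelta minimum validation-loss improvement that counts.
#' @slot patience epochs without improvement tolerated after `minEpochs`.
#' @slot seeds integer vector of training seeds.
#' @slot batchSize minibatch size.
#' @slot enumMode one of `"can2can"`, `"enum2can"`, `"can2enum"`.
#' @slot validationFraction held-out fraction of the corpus in (0, 1).
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", minEpochs = "integer",
                 maxEpochs = "integer", minDelta = "numeric",
                 patience = "integer", seeds = "integer",
                 batchSize = "integer", enumMode = "character",
                 validationFraction = "numeric"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@minEpochs > object@maxEpochs)
    msg <- c(msg, "minEpochs must not exceed maxEpochs")
  if (object@patience < 1L) msg <- c(msg, "patience must be >= 1")
  if (!object@enumMode %in% c("can2can", "enum2can", "can2enum"))
    msg <- c(msg, "enumMode must be can2can, enum2can or can2enum")
  if (object@validationFraction <= 0 || object@validationFraction >= 1)
    msg <- c(msg, "validationFraction must be in (0, 1)")
  if (length(object@seeds) < 1L) msg <- c(msg, "at least one seed required")
  if (length(msg)) msg else TRUE
})

#' Reconstruction quality report
#'
#' Per-molecule Mean Similarity, Levenshtein similarity and exact-match
#' flags, with aggregate means and the Full Reconstruction rate (percent of
#' molecules reconstructed without a single token mismatch).
#'
#' @slot perMolecule data.frame with columns `input`, `reconstruction`,
#'   `meanSimilarity`, `levenshteinSimilarity`, `exactMatch`.
#' @slot meanSimilarity aggregate mean of per-molecule Mean Similarity.
#' @slot levenshteinSimilarity aggregate mean of Levenshtein similarity.
#' @slot fullReconstruction Full Reconstruction rate in percent.
#' @slot nSkipped molecules skipped (e.g. out-of-vocabulary).
#' @export
setClass("ReconstructionReport",
  representation(perMolecule = "data.frame", meanSimilarity = "numeric",
                 levenshteinSimilarity = "numeric",
                 fullReconstruction = "numeric", nSkipped = "integer"))

#' Latent-space utilization report
#'
#' Min-max-scaled latent matrix, per-dimension variances of the scaled
#' values, the fraction of low-variance dimensions and the resulting
#' utilization class (`posterior_collapse`, `selective` or
#' `high_utilization`), together with the thresholds used.
#'
#' @slot scaled numeric matrix in [0, 1], molecules by latent dimensions.
#' @slot dimVariances per-dimension variance of the scaled matrix.
#' @slot fractionLow share of dimensions with variance below `tauLow`.
#' @slot label utilization class label.
#' @slot thresholds named numeric: `tauLow`, `collapseFrac`, `selectiveFrac`.
#' @export
setClass("UtilizationReport",
  representation(scaled = "matrix", dimVariances = "numeric",
                 fractionLow = "numeric", label = "character",
                 thresholds = "numeric"))

# ---- constructors -----------------------------------------------------------

#' Create a molecule set
#'
#' @param smiles character vector of canonical SMILES.
#' @param selfies optional character vector of SELFIES strings.
#' @param enumerations optional list of character vectors of non-canonical
#'   SMILES, one element per molecule.
#' @return A [MoleculeSet-class] object.
#' @export
MoleculeSet <- function(smiles, selfies = NULL, enumerations = NULL) {
  n <- length(smiles)
  if (is.null(selfies)) selfies <- rep(NA_character_, n)
  if (is.null(enumerations)) enumerations <- rep(list(character()), n)
  new("MoleculeSet", smiles = as.character(smiles),
      selfies = as.character(selfies), enumerations = enumerations)
}

#' Create a model configuration
#'
#' @param cell `"gru"` or `"lstm"`.
#' @param hiddenSize recurrent hidden width H (default 64, the base model).
#' @param latentSize latent width L (default 64).
#' @param numLayers recurrent layers, 1 to 3.
#' @param attention add additive self-attention over encoder step outputs.
#' @param variational use a diagonal-Gaussian variational head.
#' @param klWeight weight of the KL term in the variational loss.
#' @return A [ModelConfig-class] object.
#' @examples
#' ModelConfig("gru")                      # the GRU base architecture
#' ModelConfig("lstm", 128, 128, numLayers = 2, attention = TRUE)
#' @export
ModelConfig <- function(cell = c("gru", "lstm"), hiddenSize = 64L,
                        latentSize = 64L, numLayers = 1L,
                        attention = FALSE, variational = FALSE,
                        klWeight = 0.3) {
  cell <- match.arg(tolower(cell[1L]), c("gru", "lstm"))
  new("ModelConfig", cell = cell, hiddenSize = as.integer(hiddenSize),
      latentSize = as.integer(latentSize), numLayers = as.integer(numLayers),
      attention = isTRUE(attention), variational = isTRUE(variational),
      klWeight = as.numeric(klWeight))
}

#' Create a training configuration
#'
#' Defaults follow the training protocol used throughout the package:
#' Adam with learning rate 0.005, at least 50 and at most 500 epochs,
#' early stopping with a validation-loss minimum delta of 0.01 and a
#' patience of 5, and three seeds.
#'
#' @param learningRate Adam learning rate.
#' @param minEpochs,maxEpochs epoch bounds.
#' @param minDelta minimum validation-loss improvement that counts.
#' @param patience epochs without improvement tolerated.
#' @param seeds integer vector of training seeds.
#' @param batchSize minibatch size.
#' @param enumMode enumeration pairing mode.
#' @param validationFraction held-out validation fraction.
#' @return A [TrainConfig-class] object.
#' @export
TrainConfig <- function(learningRate = 0.005, minEpochs = 50L,
                        maxEpochs = 500L, minDelta = 0.01, patience = 5L,
                        seeds = c(1L, 2L, 3L), batchSize = 128L,
                        enumMode = c("can2can", "enum2can", "can2enum"),
                        validationFraction = 0.1) {
  enumMode <- match.arg(enumMode)
  new("TrainConfig", learningRate = learningRate,
      minEpochs = as.integer(minEpochs), maxEpochs = as.integer(maxEpochs),
      minDelta = minDelta, patience = as.integer(patience),
      seeds = as.integer(seeds), batchSize = as.integer(batchSize),
      enumMode = enumMode, validationFraction = validationFraction)
}

# ---- accessors --------------------------------------------------------------

#' @describeIn MoleculeSet-class number of molecules.
#' @param x,object a `MoleculeSet`.
#' @export
setMethod("length", "MoleculeSet", function(x) length(x@smiles))

#' Canonical SMILES of a molecule set
#' @param x a [MoleculeSet-class].
#' @return character vector of canonical SMILES.
#' @export
canonicalSmiles <- function(x) x@smiles

#' SELFIES strings of a molecule set
#' @param x a [MoleculeSet-class].
#' @return character vector (may contain `NA` where not yet translated).
#' @export
selfiesStrings <- function(x) x@selfies

#' Enumerated (non-canonical) SMILES of a molecule set
#' @param x a [MoleculeSet-class].
#' @return list of character vectors, one per molecule.
#' @export
enumerations <- function(x) x@enumerations

#' Subset a molecule set
#' @param x a `MoleculeSet`; @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "MoleculeSet", function(x, i, j, ..., drop = TRUE) {
  new("MoleculeSet", smiles = x@smiles[i], selfies = x@selfies[i],
      enumerations = x@enumerations[i])
})

#' @describeIn Vocabulary-class number of tokens including specials.
#' @param x a `Vocabulary`.
#' @export
setMethod("length", "Vocabulary", function(x) length(x@tokens))

#' Size of a vocabulary (tokens incl. specials)
#' @param vocab a [Vocabulary-class].
#' @return integer.
#' @export
vocabSize <- function(vocab) length(vocab@tokens)

#' 0-based index of tokens in a vocabulary
#'
#' PAD, SOS, EOS always map to 0, 1, 2.
#'
#' @param vocab a [Vocabulary-class].
#' @param tokens character vector of tokens.
#' @return integer vector of 0-based indices; errors on unknown tokens.
#' @export
tokenIndex <- function(vocab, tokens) {
  idx <- match(tokens, vocab@tokens)
  if (anyNA(idx)) {
    bad <- unique(tokens[is.na(idx)])
    stop("token(s) not in vocabulary: ", paste(bad, collapse = ", "))
  }
  idx - 1L
}

#' Special-token names of a vocabulary
#' @param vocab a [Vocabulary-class].
#' @return named character vector (`pad`, `sos`, `eos`).
#' @export
specialTokens <- function(vocab) vocab@specials

# ---- show methods -----------------------------------------------------------

setMethod("show", "Vocabulary", function(object) {
  cat("Vocabulary of", length(object@tokens), "tokens",
      "(3 specials +", length(object@tokens) - 3L, "chemistry tokens)\n")
  chem <- setdiff(object@tokens, object@specials)
  cat("  ", paste(head(chem, 12L), collapse = " "),
      if (length(chem) > 12L) "..." else "", "\n")
})

setMethod("show", "MoleculeSet", function(object) {
  n <- length(object@smiles)
  cat("MoleculeSet with", n, "molecules\n")
  if (n) {
    cat("  SMILES:", paste(head(object@smiles, 3L), collapse = ", "),
        if (n > 3L) "..." else "", "\n")
    cat("  SELFIES present:", sum(!is.na(object@selfies)),
        "| enumerated:", sum(lengths(object@enumerations) > 0L), "\n")
  }
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig: %s, H=%d, L=%d, layers=%d, attention=%s%s\n",
              toupper(object@cell), object@hiddenSize, object@latentSize,
              object@numLayers, object@attention,
              if (object@variational)
                sprintf(", variational (beta=%g)", object@klWeight) else ""))
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(paste0("TrainConfig: adam lr=%g, epochs %d..%d, ",
                     "minDelta=%g, patience=%d, batch=%d, %s, %d seed(s)\n"),
              object@learningRate, object@minEpochs, object@maxEpochs,
              object@minDelta, object@patience, object@batchSize,
              object@enumMode, length(object@seeds)))
})

setMethod("show", "ReconstructionReport", function(object) {
  cat(sprintf(paste0("ReconstructionReport on %d molecules",
                     " (%d skipped)\n  Mean Similarity        %.4f\n",
                     "  Levenshtein similarity %.4f\n",
                     "  Full Reconstruction    %.1f%%\n"),
              nrow(object@perMolecule), object@nSkipped,
              object@meanSimilarity, object@levenshteinSimilarity,
              object@fullReconstruction))
})

setMethod("show", "UtilizationReport", function(object) {
  cat(sprintf(paste0("UtilizationReport: %s\n  %d molecules x %d dims, ",
                     "fraction of low-variance dims %.3f ",
                     "(tauLow=%g, collapse>=%g, selective>=%g)\n"),
              object@label, nrow(object@scaled), ncol(object@scaled),
              object@fractionLow, object@thresholds[["tauLow"]],
              object@thresholds[["collapseFrac"]],
              object@thresholds[["selectiveFrac"]]))
})

#' @describeIn ReconstructionReport-class per-molecule rows as a data.frame.
#' @param x a `ReconstructionReport`.
#' @param row.names,optional,... passed through.
#' @export
setMethod("as.data.frame", "ReconstructionReport",
  function(x, row.names = NULL, optional = FALSE, ...) x@perMolecule)
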