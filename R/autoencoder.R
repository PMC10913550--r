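# The user-facing autoencoder object and its encode/decode methods.

#' A molecular string autoencoder
#'
#' Bundles a [ModelConfig-class], a [Vocabulary-class], the trainable
#' parameters, the string representation it was built for and the maximum
#' decode length.
#'
#' @slot config a [ModelConfig-class].
#' @slot vocab a [Vocabulary-class].
#' @slot params named list of weight matrices / bias vectors.
#' @slot representation `"smiles"` or `"selfies"`.
#' @slot maxLen maximum sequence length incl. EOS used for decoding.
#' @slot seed the initialization seed.
#' @export
setClass("MolAutoencoder",
  representation(config = "ModelConfig", vocab = "Vocabulary",
                 params = "list", representation = "character",
                 maxLen = "integer", seed = "integer"))

setMethod("show", "MolAutoencoder", function(object) {
  cat("MolAutoencoder (", object@representation, ")\n", sep = "")
  show(object@config)
  cat("  vocab size", vocabSize(object@vocab),
      "| maxLen", object@maxLen,
      "| parameters", countParameters(object@config,
                                      vocabSize(object@vocab)), "\n")
})

#' Build an untrained autoencoder
#'
#' @param config a [ModelConfig-class].
#' @param vocab a [Vocabulary-class] over the training representation.
#' @param representation `"smiles"` or `"selfies"`.
#' @param maxLen maximum sequence length including EOS; choose at least
#'   the longest training sequence + 1.
#' @param seed initialization seed.
#' @return a [MolAutoencoder-class].
#' @export
buildAutoencoder <- function(config, vocab,
                             representation = c("smiles", "selfies"),
                             maxLen, seed = 1L) {
  representation <- match.arg(representation)
  new("MolAutoencoder", config = config, vocab = vocab,
      params = initParams(config, vocabSize(vocab), seed = seed),
      representation = representation, maxLen = as.integer(maxLen),
      seed = as.integer(seed))
}

#' Parameters of an autoencoder
#' @param model a [MolAutoencoder-class].
#' @return named list of parameter arrays.
#' @export
modelParameters <- function(model) model@params

#' Model configuration of an autoencoder
#' @param model a [MolAutoencoder-class].
#' @return the [ModelConfig-class].
#' @export
modelConfig <- function(model) model@config

#' Vocabulary of an autoencoder
#' @param model a [MolAutoencoder-class].
#' @return the [Vocabulary-class].
#' @export
modelVocabulary <- function(model) model@vocab

tokenizeFor <- function(representation, s) {
  if (representation == "smiles") tokenizeSmiles(s) else tokenizeSelfies(s)
}

#' Encode molecule strings to latent vectors
#'
#' Tokenizes the strings in the model's representation, one-hot encodes
#' them and runs the encoder.  For variational models the mean head's
#' output is returned (deterministic encoding).
#'
#' @param model a [MolAutoencoder-class].
#' @param strings character vector of molecule strings in the model's
#'   representation.
#' @return numeric matrix, molecules by latent dimensions.
#' @export
encodeMolecules <- function(model, strings) {
  stopifnot(length(strings) >= 1L)
  seqs <- lapply(strings, tokenizeFor, representation = model@representation)
  batch <- oneHotEncode(seqs, model@vocab, maxLen = max(lengths(seqs)) + 1L)
  enc <- encoderForward(model@params, model@config, batch$array,
                        batch$lengths)
  lat <- latentForward(model@params, model@config, enc)
  z <- lat$z
  if (ncol(z) != model@config@latentSize)
    stop("latent width mismatch")                      # defensive
  rownames(z) <- NULL
  z
}

#' Greedy-decode latent vectors to strings
#'
#' Free-running decoding: starting from SOS, each step consumes the argmax
#' token of the previous step, until EOS or `maxLen`.  Deterministic given
#' weights and latents.
#'
#' @param model a [MolAutoencoder-class].
#' @param z numeric matrix, molecules by latent dimensions.
#' @param maxLen decode length cap (default: the model's).
#' @return character vector of decoded strings (EOS/PAD stripped).
#' @export
decodeLatents <- function(model, z, maxLen = model@maxLen) {
  stopifnot(is.matrix(z), ncol(z) == model@config@latentSize)
  P <- model@params; cfg <- model@config
  vocab <- model@vocab; V <- vocabSize(vocab)
  B <- nrow(z)
  sosIdx <- tokenIndex(vocab, vocab@specials[["sos"]])
  eosIdx <- tokenIndex(vocab, vocab@specials[["eos"]])
  init <- decoderInit(P, cfg, z)
  h <- init$h; cst <- init$c
  H <- cfg@hiddenSize; m <- cfg@numLayers; cell <- cfg@cell
  inp <- matrix(0, B, V); inp[cbind(seq_len(B), sosIdx + 1L)] <- 1
  outIdx <- matrix(eosIdx, B, maxLen)
  finished <- rep(FALSE, B)
  for (t in seq_len(maxLen)) {
    x <- inp
    for (l in seq_len(m)) {
      cf <- cellForward(cell, x, h[[l]],
                        if (cell == "lstm") cst[[l]] else NULL,
                        P[[paste0("dec.Wx.", l)]], P[[paste0("dec.Wh.", l)]],
                        P[[paste0("dec.bx.", l)]], P[[paste0("dec.bh.", l)]],
                        H)
      h[[l]] <- cf$h
      if (cell == "lstm") cst[[l]] <- cf$c
      x <- cf$h
    }
    logits <- .addb(h[[m]] %*% P$out.W, P$out.b)
    idx <- max.col(logits, ties.method = "first") - 1L   # 0-based
    outIdx[!finished, t] <- idx[!finished]
    finished <- finished | idx == eosIdx
    if (all(finished)) { outIdx <- outIdx[, seq_len(t), drop = FALSE]; break }
    inp <- matrix(0, B, V); inp[cbind(seq_len(B), idx + 1L)] <- 1
  }
  out <- vapply(seq_len(B), function(i) decodeIndices(outIdx[i, ], vocab), "")
  # emitted token sequences (pre-concatenation), for token-level metrics
  attr(out, "tokens") <- lapply(seq_len(B), function(i) {
    toks <- vocab@tokens[outIdx[i, ] + 1L]
    eos <- which(toks == vocab@specials[["eos"]])
    if (length(eos)) toks <- toks[seq_len(eos[1L] - 1L)]
    toks[!toks %in% vocab@specials]
  })
  out
}

#' Per-step decoder probabilities
#'
#' Runs the decoder from latent vectors and returns the full
#' `B x T x V` block of per-step token probabilities together with the
#' predicted strings.  With `teacher` strings supplied, step `t` consumes
#' the ground-truth token `t - 1` (teacher forcing, `T` = target length);
#' without, decoding is free-running greedy as in [decodeLatents()].
#'
#' @param model a [MolAutoencoder-class].
#' @param z latent matrix, molecules by latent dimensions.
#' @param maxLen decode length cap (free-running mode).
#' @param teacher optional character vector of ground-truth strings.
#' @return list with `probs` (`B x T x V` array, each row a distribution),
#'   `strings` (predicted strings), and `targets` (0-based target index
#'   matrix; teacher mode only).
#' @export
decoderProbabilities <- function(model, z, maxLen = model@maxLen,
                                 teacher = NULL) {
  stopifnot(is.matrix(z), ncol(z) == model@config@latentSize)
  P <- model@params; cfg <- model@config; vocab <- model@vocab
  V <- vocabSize(vocab)
  B <- nrow(z)
  freeRunning <- is.null(teacher)
  if (freeRunning) {
    # greedy decode, then re-run the decoder on its own predictions: the
    # inputs match step for step, so these are the free-running rows
    strings <- decodeLatents(model, z, maxLen = maxLen)
    seqs <- attr(strings, "tokens")
    strings <- as.character(strings)
  } else {
    stopifnot(length(teacher) == B)
    seqs <- lapply(teacher, tokenizeFor,
                   representation = model@representation)
  }
  Tn <- max(lengths(seqs)) + 1L
  Yidx <- indexEncode(seqs, vocab, Tn)
  dec <- decoderForward(P, cfg, decoderInit(P, cfg, z),
                        decoderInputs(Yidx, V, 1L))
  probs <- array(0, dim = c(B, Tn, V))
  for (t in seq_len(Tn)) probs[, t, ] <- softmaxRows(dec$logits[[t]])
  if (!freeRunning)
    strings <- vapply(seq_len(B), function(i) {
      idx <- apply(probs[i, , , drop = TRUE], 1L, which.max) - 1L
      decodeIndices(idx, vocab)
    }, "")
  list(probs = probs, strings = strings, targets = Yidx)
}

#' Reconstruct molecule strings through the autoencoder
#'
#' Convenience round trip: encode then greedy-decode.
#'
#' @param model a [MolAutoencoder-class].
#' @param strings character vector of molecule strings.
#' @param maxLen decode length cap.
#' @return character vector of reconstructions.
#' @export
reconstructMolecules <- function(model, strings, maxLen = model@maxLen) {
  decodeLatents(model, encodeMolecules(model, strings), maxLen = maxLen)
}
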