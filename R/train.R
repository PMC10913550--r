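# Training protocol: pairing modes, Adam, early stopping, multi-seed runs.

#' Build (input, target) training pairs for an enumeration mode
#'
#' `can2can` pairs every canonical string with itself; `enum2can` pairs a
#' sampled enumeration with the canonical string; `can2enum` pairs the
#' canonical string with a sampled enumeration.  Sampling is seeded, so
#' resampling per epoch (with an epoch-derived seed) exposes different
#' enumerations across epochs.
#'
#' @param mset a [MoleculeSet-class]; must carry enumerations unless
#'   `enumMode = "can2can"`.
#' @param enumMode `"can2can"`, `"enum2can"` or `"can2enum"`.
#' @param seed integer sampling seed.
#' @param representation `"smiles"` or `"selfies"`; for SELFIES the
#'   canonical and sampled strings are translated with the codec.
#' @return data.frame with columns `input` and `target`.
#' @export
makeTrainingPairs <- function(mset, enumMode = c("can2can", "enum2can",
                                                 "can2enum"),
                              seed = 1L,
                              representation = c("smiles", "selfies")) {
  enumMode <- match.arg(enumMode)
  representation <- match.arg(representation)
  can <- canonicalSmiles(mset)
  if (enumMode != "can2can" && any(lengths(enumerations(mset)) == 0L))
    stop("enumMode '", enumMode, "' requires enumerations on every molecule")
  sampled <- can
  if (enumMode != "can2can")
    sampled <- withr::with_seed(as.integer(seed),
      vapply(enumerations(mset), function(e) e[sample.int(length(e), 1L)],
             ""))
  if (representation == "selfies") {
    canS <- selfiesStrings(mset)
    if (anyNA(canS)) canS <- vapply(can, smilesToSelfies, "")
    sampledS <- if (enumMode == "can2can") canS else
      vapply(sampled, smilesToSelfies, "")
    can <- canS; sampled <- sampledS
  }
  switch(enumMode,
    can2can  = data.frame(input = can, target = can),
    enum2can = data.frame(input = sampled, target = can),
    can2enum = data.frame(input = can, target = sampled))
}

#' Early-stopping decision
#'
#' Implements the rule used throughout the package: training never stops
#' before `minEpochs`; it stops once the validation loss has not improved
#' on its best value by more than `minDelta` for `patience` consecutive
#' epochs; and it always stops at `maxEpochs`.
#'
#' @param valLosses numeric vector of per-epoch validation losses so far.
#' @param config a [TrainConfig-class].
#' @return `"stop"` or `"continue"`, with attribute `reason`.
#' @export
checkEarlyStop <- function(valLosses, config) {
  n <- length(valLosses)
  stopifnot(n >= 1L)
  if (n >= config@maxEpochs)
    return(structure("stop", reason = "max_epochs"))
  if (n < config@minEpochs)
    return(structure("continue", reason = "min_epochs"))
  # epochs since the last improvement of the running best by > minDelta
  best <- valLosses[1L]
  sinceImprove <- 0L
  for (i in seq_len(n)[-1L]) {
    if (valLosses[i] < best - config@minDelta) {
      best <- valLosses[i]
      sinceImprove <- 0L
    } else sinceImprove <- sinceImprove + 1L
  }
  if (sinceImprove >= config@patience)
    structure("stop", reason = "early_stopping")
  else structure("continue", reason = "improving")
}

adamInit <- function(P) {
  list(m = lapply(P, function(x) x * 0), v = lapply(P, function(x) x * 0),
       t = 0L)
}

adamStep <- function(P, G, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (nm in names(G)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * G[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * G[[nm]]^2
    P[[nm]] <- P[[nm]] - lr * (st$m[[nm]] / c1) /
      (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(P = P, st = st)
}

# tokenized corpus -> encoder block + target indices for a pair table
.prepareBatchData <- function(pairs, vocab, representation, maxLen) {
  inSeqs <- lapply(pairs$input, tokenizeFor, representation = representation)
  tgSeqs <- lapply(pairs$target, tokenizeFor, representation = representation)
  X <- oneHotEncode(inSeqs, vocab, maxLen = maxLen)
  Yidx <- indexEncode(tgSeqs, vocab, maxLen)
  tgLens <- lengths(tgSeqs) + 1L
  maskY <- outer(seq_along(tgSeqs), seq_len(maxLen),
                 function(i, t) t <= tgLens[i])
  list(X = X$array, encLens = X$lengths, Yidx = Yidx, maskY = maskY)
}

# one seed's training run; returns model + history
trainOne <- function(config, trainConfig, mset, representation, seed,
                     vocab, maxLen, verbose = FALSE) {
  n <- length(mset)
  tc <- trainConfig
  model <- buildAutoencoder(config, vocab, representation, maxLen,
                            seed = seed)
  P <- model@params
  adam <- adamInit(P)
  # seeded validation split; a fraction rounding to zero molecules means
  # "train on everything, monitor loss on a training sample" (memorization)
  nVal <- round(tc@validationFraction * n)
  if (nVal >= 1L) {
    valIdx <- withr::with_seed(seed, sample.int(n, nVal))
    trainIdx <- setdiff(seq_len(n), valIdx)
  } else {
    valIdx <- withr::with_seed(seed, sample.int(n, min(n, 8L)))
    trainIdx <- seq_len(n)
  }
  if (length(trainIdx) == 0L) stop("corpus too small for a validation split")

  valPairs <- makeTrainingPairs(mset[valIdx], tc@enumMode,
                                seed = seed, representation = representation)
  valData <- .prepareBatchData(valPairs, vocab, representation, maxLen)

  trainLoss <- numeric(0L)
  valLoss <- numeric(0L)
  epoch <- 0L
  repeat {
    epoch <- epoch + 1L
    epochSeed <- (seed * 10007L + epoch) %% .Machine$integer.max
    pairs <- makeTrainingPairs(mset[trainIdx], tc@enumMode,
                               seed = epochSeed,
                               representation = representation)
    ord <- withr::with_seed(epochSeed, sample.int(nrow(pairs)))
    pairs <- pairs[ord, , drop = FALSE]
    dat <- .prepareBatchData(pairs, vocab, representation, maxLen)
    nb <- ceiling(nrow(pairs) / tc@batchSize)
    epLoss <- 0; epN <- 0L
    for (b in seq_len(nb)) {
      rows <- ((b - 1L) * tc@batchSize + 1L):min(b * tc@batchSize,
                                                 nrow(pairs))
      res <- trainStep(P, config,
                       dat$X[rows, , , drop = FALSE], dat$encLens[rows],
                       dat$Yidx[rows, , drop = FALSE],
                       dat$maskY[rows, , drop = FALSE],
                       sampleSeed = epochSeed + b)
      upd <- adamStep(P, res$grads, adam, tc@learningRate)
      P <- upd$P; adam <- upd$st
      epLoss <- epLoss + res$loss * length(rows)
      epN <- epN + length(rows)
    }
    trainLoss <- c(trainLoss, epLoss / epN)
    vres <- trainStep(P, config, valData$X, valData$encLens, valData$Yidx,
                      valData$maskY, sampleSeed = epoch, wantGrads = FALSE)
    valLoss <- c(valLoss, vres$loss)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      tail(trainLoss, 1L), tail(valLoss, 1L)))
    decision <- checkEarlyStop(valLoss, tc)
    if (identical(as.character(decision), "stop")) {
      stopReason <- attr(decision, "reason")
      break
    }
  }
  model@params <- P
  list(model = model,
       history = list(trainLoss = trainLoss, valLoss = valLoss,
                      epochs = epoch, stopReason = stopReason, seed = seed))
}

#' Train autoencoders across seeds
#'
#' Runs the full training protocol (teacher forcing on every training step,
#' Adam, seeded validation split, early stopping) once per seed in
#' `trainConfig@seeds`, then evaluates each trained model on `evalSet`
#' (default: the training corpus) with free-running greedy decoding and
#' aggregates the metrics as mean with min/max across seeds.
#'
#' @param config a [ModelConfig-class].
#' @param trainConfig a [TrainConfig-class].
#' @param mset training [MoleculeSet-class] (>= 2 molecules).
#' @param representation `"smiles"` or `"selfies"`.
#' @param evalSet molecule set for the reconstruction report.
#' @param maxEpochsOverride optional hard epoch cap (budget experiments).
#' @param verbose print per-epoch losses.
#' @return list with `models`, `histories`, `reports` (per seed) and
#'   `aggregate` (mean/min/max of each metric across seeds).
#' @export
trainAutoencoder <- function(config, trainConfig, mset,
                             representation = c("smiles", "selfies"),
                             evalSet = mset, maxEpochsOverride = NULL,
                             verbose = FALSE) {
  representation <- match.arg(representation)
  if (length(mset) < 2L) stop("corpus must contain at least 2 molecules")
  tc <- trainConfig
  if (!is.null(maxEpochsOverride)) {
    tc@minEpochs <- min(tc@minEpochs, as.integer(maxEpochsOverride))
    tc@maxEpochs <- as.integer(maxEpochsOverride)
  }
  strings <- trainingStrings(mset, representation, tc@enumMode)
  seqs <- lapply(strings, tokenizeFor, representation = representation)
  # always include the structural tokens, so enumerated variants of the
  # training molecules stay encodable at evaluation/diagnostics time
  vocab <- buildVocabulary(c(seqs, list(structuralTokens(representation))))
  maxLen <- max(lengths(seqs)) + 1L
  runs <- lapply(tc@seeds, function(s)
    trainOne(config, tc, mset, representation, s, vocab, maxLen,
             verbose = verbose))
  reports <- lapply(runs, function(r) evaluateModel(r$model, evalSet))
  metric <- function(f) {
    v <- vapply(reports, f, 0)
    list(mean = mean(v), min = min(v), max = max(v))
  }
  list(models = lapply(runs, `[[`, "model"),
       histories = lapply(runs, `[[`, "history"),
       reports = reports,
       aggregate = list(
         meanSimilarity = metric(function(r) r@meanSimilarity),
         levenshteinSimilarity = metric(function(r) r@levenshteinSimilarity),
         fullReconstruction = metric(function(r) r@fullReconstruction)))
}

# structural tokens any same-molecule variant can introduce
structuralTokens <- function(representation) {
  if (representation == "smiles")
    c("(", ")", "=", "#", as.character(1:6))
  else
    c("[Branch1]", "[Branch2]", "[Ring1]", "[Ring2]", "[=Ring1]")
}

# all strings the vocabulary must cover for a given mode
trainingStrings <- function(mset, representation, enumMode) {
  can <- canonicalSmiles(mset)
  extra <- character(0L)
  if (enumMode != "can2can")
    extra <- unlist(enumerations(mset), use.names = FALSE)
  if (representation == "selfies") {
    canS <- selfiesStrings(mset)
    if (anyNA(canS)) canS <- vapply(can, smilesToSelfies, "")
    extraS <- if (length(extra)) vapply(extra, smilesToSelfies, "") else
      character(0L)
    c(canS, extraS)
  } else c(can, extra)
}
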