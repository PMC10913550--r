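# Training protocol: pairing modes, loss composition, early stopping,
# multi-seed training

test_that("pairing modes honour the enumeration contracts", {
  mset <- tinyCorpus(6L, enumerate = 2L)
  p0 <- makeTrainingPairs(mset, "can2can", seed = 1L)
  expect_identical(p0$input, p0$target)
  expect_equal(nrow(p0), 6L)
  p1 <- makeTrainingPairs(mset, "enum2can", seed = 1L)
  expect_identical(canonicalizeSmiles(p1$input), p1$target)
  expect_false(all(p1$input == p1$target))
  p2 <- makeTrainingPairs(mset, "can2enum", seed = 1L)
  expect_identical(canonicalizeSmiles(p2$target), p2$input)
  # resampling with another seed draws different enumerations
  expect_false(identical(p1$input,
                         makeTrainingPairs(mset, "enum2can", seed = 9L)$input))
  bare <- tinyCorpus(6L)
  expect_error(makeTrainingPairs(bare, "enum2can"), "requires enumerations")
})

test_that("loss is masked cross-entropy plus the weighted KL term", {
  V <- 5L
  # perfect predictions: zero loss
  probs <- array(0, dim = c(1L, 3L, V))
  tgt <- matrix(c(3L, 4L, 2L), 1L)
  for (t in 1:3) probs[1L, t, tgt[1L, t] + 1L] <- 1
  expect_equal(autoencoderLoss(probs, tgt), 0)
  # uniform predictions: ln V per position
  probs[] <- 1 / V
  expect_equal(autoencoderLoss(probs, tgt), log(V))
  # CE = 1 and KL = 2 with beta 0.3 compose to 1.6
  probs[] <- 0; for (t in 1:3) probs[1L, t, tgt[1L, t] + 1L] <- exp(-1)
  expect_equal(autoencoderLoss(probs, tgt, mu = c(2, 0), logvar = c(0, 0),
                               klWeight = 0.3), 1 + 0.3 * 2)
  # PAD positions excluded via the mask
  probs[1L, 3L, ] <- 1 / V
  mask <- matrix(c(TRUE, TRUE, FALSE), 1L)
  expect_equal(autoencoderLoss(probs, tgt, mask = mask), 1)
})

test_that("early stopping follows the min/patience/max rule exactly", {
  tc <- TrainConfig(minEpochs = 50L, maxEpochs = 500L, minDelta = 0.01,
                    patience = 5L)
  expect_identical(as.character(checkEarlyStop(rep(1, 10L), tc)),
                   "continue")
  # plateau at epoch 50 stops at 55
  pl <- generateLossTrace("plateau_after_k", length = 70L, k = 50L,
                          seed = 2L)
  stopAt <- NA_integer_
  for (e in seq_along(pl))
    if (as.character(checkEarlyStop(pl[seq_len(e)], tc)) == "stop") {
      stopAt <- e; break
    }
  expect_identical(stopAt, 55L)
  # strictly improving: only the epoch cap stops it
  im <- generateLossTrace("improving", length = 500L, seed = 2L)
  for (e in c(50L, 200L, 499L))
    expect_identical(as.character(checkEarlyStop(im[seq_len(e)], tc)),
                     "continue")
  d <- checkEarlyStop(im, tc)
  expect_identical(as.character(d), "stop")
  expect_identical(attr(d, "reason"), "max_epochs")
})

test_that("early stopping bounds hold for arbitrary random traces", {
  tc <- TrainConfig(minEpochs = 20L, maxEpochs = 60L, minDelta = 0.01,
                    patience = 3L)
  set.seed(31)
  for (rep in 1:25) {
    tr <- cumsum(rnorm(60L, sd = 0.2)) + 3
    stopAt <- NA_integer_
    for (e in seq_along(tr))
      if (as.character(checkEarlyStop(tr[seq_len(e)], tc)) == "stop") {
        stopAt <- e; break
      }
    expect_gte(stopAt, tc@minEpochs)
    expect_lte(stopAt, tc@maxEpochs)
  }
})

test_that("multi-seed training returns per-seed runs and aggregates", {
  mset <- tinyCorpus(10L, seed = 21L)
  tc <- TrainConfig(seeds = c(1L, 2L, 3L), minEpochs = 2L, maxEpochs = 2L,
                    batchSize = 8L, validationFraction = 0.2)
  res <- trainAutoencoder(ModelConfig("gru", 16, 16, 1), tc, mset,
                          representation = "smiles")
  expect_length(res$models, 3L)
  expect_length(res$histories, 3L)
  expect_length(res$reports, 3L)
  agg <- res$aggregate$fullReconstruction
  expect_named(agg, c("mean", "min", "max"))
  expect_gte(agg[["max"]], agg[["mean"]])
  expect_gte(agg[["mean"]], agg[["min"]])
  # determinism: the same configuration reproduces identical losses
  res2 <- trainAutoencoder(ModelConfig("gru", 16, 16, 1), tc, mset,
                           representation = "smiles")
  expect_identical(res$histories[[1L]]$trainLoss,
                   res2$histories[[1L]]$trainLoss)
  # histories carry both losses per epoch and a stop reason
  h <- res$histories[[1L]]
  expect_length(h$trainLoss, h$epochs)
  expect_length(h$valLoss, h$epochs)
  expect_identical(h$stopReason, "max_epochs")
})

test_that("a model trained to memorize a tiny corpus reproduces it", {
  mset <- tinyCorpus(4L, seed = 33L)
  tc <- TrainConfig(seeds = 1L, minEpochs = 300L, maxEpochs = 300L,
                    batchSize = 4L, validationFraction = 0.01,
                    learningRate = 0.005)
  res <- trainAutoencoder(ModelConfig("gru", 32, 32, 1), tc, mset,
                          representation = "smiles")
  rep <- res$reports[[1L]]
  expect_equal(rep@fullReconstruction, 100)
  expect_equal(rep@meanSimilarity, 1)
  # teacher-forced loss collapsed towards zero
  expect_lt(tail(res$histories[[1L]]$trainLoss, 1L), 0.05)
})

test_that("SELFIES-representation training runs end to end", {
  mset <- tinyCorpus(6L, seed = 44L)
  tc <- TrainConfig(seeds = 1L, minEpochs = 2L, maxEpochs = 2L,
                    batchSize = 4L, validationFraction = 0.2)
  res <- trainAutoencoder(ModelConfig("gru", 12, 12, 1), tc, mset,
                          representation = "selfies")
  expect_s4_class(res$reports[[1L]], "ReconstructionReport")
})
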