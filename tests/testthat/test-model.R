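# Architecture wiring, gradients, attention, variational utilities

test_that("analytic gradients match finite differences across cells", {
  cfgs <- list(ModelConfig("gru", 5, 5, 1),
               ModelConfig("gru", 6, 4, 2, attention = TRUE),
               ModelConfig("lstm", 5, 5, 1),
               ModelConfig("lstm", 5, 4, 2, variational = TRUE,
                           klWeight = 0.3))
  for (cfg in cfgs)
    expect_lt(gradCheckWorst(cfg), 1e-3)
})

test_that("plain GRU with H = L and one layer has no bridge parameters", {
  tb <- tinyBatch()
  V <- vocabSize(tb$vocab)
  cfg <- ModelConfig("gru", 16, 16, 1)
  P <- molae:::initParams(cfg, V, seed = 2L)
  expect_false(any(grepl("^br\\.|^dec0|^vae", names(P))))
  # encode output is bitwise the final hidden state
  enc <- molae:::encoderForward(P, cfg, tb$batch$array, tb$batch$lengths)
  lat <- molae:::latentForward(P, cfg, enc)
  expect_identical(lat$z, enc$hT[[1L]])
})

test_that("bridge linear maps appear exactly when the wiring requires them", {
  V <- 10L
  # GRU with reduced latent: exactly one extra projection of shape H x L
  p1 <- molae:::initParams(ModelConfig("gru", 64, 32, 1), V, seed = 1L)
  expect_identical(dim(p1$br.W), c(64L, 32L))
  extra <- setdiff(names(p1),
                   names(molae:::initParams(ModelConfig("gru", 64, 64, 1),
                                            V, seed = 1L)))
  expect_identical(sort(extra), c("br.W", "br.b", "dec0.W", "dec0.b"))
  # LSTM concatenates hidden and cell state: bridge input width 2*H*m
  p2 <- molae:::initParams(ModelConfig("lstm", 64, 64, 1), V, seed = 1L)
  expect_identical(nrow(p2$br.W), 128L)
  p3 <- molae:::initParams(ModelConfig("lstm", 32, 16, 2), V, seed = 1L)
  expect_identical(nrow(p3$br.W), 2L * 32L * 2L)
  # attention widens the bridge input by H
  p4 <- molae:::initParams(ModelConfig("gru", 32, 32, 1, attention = TRUE),
                           V, seed = 1L)
  expect_identical(nrow(p4$br.W), 64L)
})

test_that("parameter count matches a hand-summed tally for the GRU base", {
  V <- 23L; H <- 64L
  # encoder GRU: Wx (V x 3H) + Wh (H x 3H) + two biases (3H each);
  # decoder mirrors it; output layer H x V + V; no bridge, identity init
  byHand <- (V * 3 * H + H * 3 * H + 6 * H) * 2 + H * V + V
  expect_equal(countParameters(ModelConfig("gru", 64, 64, 1), V), byHand)
  expect_gt(countParameters(ModelConfig("lstm", 64, 64, 1), V),
            countParameters(ModelConfig("gru", 64, 64, 1), V))
  expect_gt(countParameters(ModelConfig("gru", 96, 96, 1), V),
            countParameters(ModelConfig("gru", 64, 64, 1), V))
})

test_that("attention weights normalize, localize and respect symmetry", {
  set.seed(9)
  steps <- lapply(1:5, function(t) matrix(rnorm(12), 3, 4))
  att <- attentionContext(steps, seed = 2L)
  expect_equal(colSums(att$weights), rep(1, 3), tolerance = 1e-12)
  # single step: context equals that step's output
  one <- attentionContext(steps[1L], seed = 2L)
  expect_equal(one$context, steps[[1L]])
  # two identical steps: permutation leaves the context unchanged
  two <- attentionContext(list(steps[[1L]], steps[[1L]]), seed = 2L)
  expect_equal(two$context, steps[[1L]])
  expect_error(attentionContext(steps, mask = matrix(FALSE, 5, 3)),
               "masked")
})

test_that("reparameterization and KL divergence follow the closed forms", {
  mu <- matrix(c(1, 0), 1L)
  expect_equal(klDivergence(c(0, 0), c(0, 0)), 0)
  expect_equal(klDivergence(c(1, 0), c(0, 0)), 0.5)
  expect_equal(reparameterize(mu, mu * 0, eps = mu * 0), mu)
  z1 <- reparameterize(mu, mu * 0, seed = 4L)
  expect_identical(z1, reparameterize(mu, mu * 0, seed = 4L))
})

test_that("variational model with beta = 0 and eps = 0 reduces to the AE", {
  V <- 6L
  cfgA <- ModelConfig("gru", 5, 4, 1)                 # has a bridge
  cfgV <- ModelConfig("gru", 5, 4, 1, variational = TRUE, klWeight = 0)
  P <- molae:::initParams(cfgA, V, seed = 8L)
  PV <- molae:::initParams(cfgV, V, seed = 8L)
  for (nm in setdiff(names(P), c("br.W", "br.b"))) PV[[nm]] <- P[[nm]]
  PV$vae.Wmu <- P$br.W; PV$vae.bmu <- P$br.b
  set.seed(1)
  X <- array(0, dim = c(2L, 3L, V))
  for (b in 1:2) for (t in 1:3) X[b, t, sample(3:V, 1L)] <- 1
  Yidx <- matrix(sample(0:(V - 1L), 8L, replace = TRUE), 2L, 4L)
  maskY <- matrix(TRUE, 2L, 4L)
  lens <- c(3L, 2L)
  eps0 <- matrix(0, 2L, 4L)
  lA <- molae:::trainStep(P, cfgA, X, lens, Yidx, maskY,
                          wantGrads = FALSE)$loss
  lV <- molae:::trainStep(PV, cfgV, X, lens, Yidx, maskY, eps = eps0,
                          wantGrads = FALSE)$loss
  expect_equal(lV, lA, tolerance = 1e-12)
})

test_that("greedy decoding is deterministic and honours the EOS rule", {
  tb <- tinyBatch()
  cfg <- ModelConfig("gru", 12, 12, 1)
  model <- buildAutoencoder(cfg, tb$vocab, "smiles", maxLen = 12L,
                            seed = 5L)
  z <- encodeMolecules(model, c("CCO", "CC(=O)O"))
  expect_identical(dim(z), c(2L, 12L))
  d1 <- decodeLatents(model, z)
  expect_identical(as.character(d1),
                   as.character(decodeLatents(model, z)))
  # force EOS as the first prediction: empty reconstruction
  model@params$out.W[] <- 0
  model@params$out.b[] <- -10
  model@params$out.b[tokenIndex(tb$vocab, "<eos>") + 1L] <- 10
  expect_identical(as.character(decodeLatents(model, z)), c("", ""))
})

test_that("decoder probability blocks agree with both decoding modes", {
  tb <- tinyBatch()
  model <- buildAutoencoder(ModelConfig("gru", 10, 10, 1), tb$vocab,
                            "smiles", maxLen = 12L, seed = 7L)
  z <- encodeMolecules(model, c("CCO", "CC(=O)O"))
  # free-running rows are the distributions behind the greedy predictions
  fr <- decoderProbabilities(model, z)
  expect_identical(fr$strings,
                   as.character(decodeLatents(model, z)))
  expect_equal(apply(fr$probs, c(1, 2), sum),
               matrix(1, 2L, dim(fr$probs)[2L]), tolerance = 1e-12)
  # teacher mode consumes the ground truth and scores every position
  tf <- decoderProbabilities(model, z, teacher = c("CCO", "CC(=O)O"))
  expect_identical(dim(tf$probs)[2L], 8L)          # longest target + EOS
  expect_identical(dim(tf$targets), c(2L, 8L))
})

test_that("decoder step probabilities are a distribution at every step", {
  tb <- tinyBatch()
  cfg <- ModelConfig("lstm", 10, 8, 2)
  P <- molae:::initParams(cfg, vocabSize(tb$vocab), seed = 3L)
  enc <- molae:::encoderForward(P, cfg, tb$batch$array, tb$batch$lengths)
  lat <- molae:::latentForward(P, cfg, enc)
  init <- molae:::decoderInit(P, cfg, lat$z)
  Yin <- molae:::decoderInputs(matrix(3L, 3L, 5L), vocabSize(tb$vocab), 1L)
  dec <- molae:::decoderForward(P, cfg, init, Yin)
  for (lg in dec$logits)
    expect_equal(rowSums(molae:::softmaxRows(lg)), rep(1, 3L),
                 tolerance = 1e-12)
})
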