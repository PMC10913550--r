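# Latent-space utilization typing and chemical-similarity diagnostics

test_that("min-max scaling maps columns to [0, 1] with constant -> zeros", {
  m <- cbind(c(1, 3, 5), c(2, 2, 2), c(-1, 0, 3))
  s <- minmaxScale(m)
  expect_equal(s[, 1L], c(0, 0.5, 1))
  expect_equal(s[, 2L], c(0, 0, 0))
  expect_equal(range(s[, 3L]), c(0, 1))
})

test_that("utilization typing separates collapse, high and selective", {
  set.seed(5)
  n <- 400L; L <- 32L
  # collapse: every molecule encoded (almost) identically -- per-dimension
  # constants (the heatmap's stripes) plus tiny jitter
  stripes <- rnorm(L)
  collapse <- matrix(stripes, n, L, byrow = TRUE) +
    matrix(rnorm(n * L, sd = 1e-4), n, L)
  high <- matrix(runif(n * L), n, L)
  # selective: half fully used dimensions, half near-dead stripes on the
  # same scale as the data
  selective <- cbind(matrix(runif(n * L / 2), n),
                     matrix(runif(L / 2), n, L / 2, byrow = TRUE) +
                       matrix(rnorm(n * L / 2, sd = 1e-5), n))
  expect_identical(classifyUtilization(collapse)@label, "posterior_collapse")
  expect_identical(classifyUtilization(high)@label, "high_utilization")
  rs <- classifyUtilization(selective)
  expect_identical(rs@label, "selective")
  expect_equal(rs@fractionLow, 0.5)
  # thresholds are recorded in the report
  expect_named(rs@thresholds, c("tauLow", "collapseFrac", "selectiveFrac"))
  expect_true(all(rs@scaled >= 0 & rs@scaled <= 1))
})

test_that("utilization typing is invariant to affine maps of the latents", {
  set.seed(6)
  m <- matrix(runif(200L * 16L), 200L)
  shifted <- 5.5 * m - 17
  expect_identical(classifyUtilization(m)@label,
                   classifyUtilization(shifted)@label)
  expect_equal(classifyUtilization(m)@dimVariances,
               classifyUtilization(shifted)@dimVariances, tolerance = 1e-10)
})

test_that("co-localization reports PCA variance and group distances", {
  mset <- tinyCorpus(12L)
  # vocabulary over the corpus plus structural tokens enumerations may add
  vocab <- buildVocabulary(c(lapply(canonicalSmiles(mset), tokenizeSmiles),
                             list(c("(", ")", "1", "2", "3"))))
  model <- buildAutoencoder(ModelConfig("gru", 12, 12, 1), vocab,
                            "smiles", maxLen = 20L, seed = 6L)
  expect_warning(
    rep <- enumerationColocalization(model, mset, nBackground = 50L,
                                     nTest = 2L, kEnum = 2L, seed = 3L),
    "using all")
  ev <- rep$explainedVariance
  expect_equal(sum(ev), 100, tolerance = 1e-6)
  expect_true(all(diff(ev) <= 1e-9))               # PC1 >= PC2 >= ...
  expect_length(rep$groupMeanDistance, 2L)
  expect_true(all(rep$groupMeanDistance >= 0))
  expect_equal(nrow(rep$test), 2L * 3L)
  # a degenerate encoder maps every string to one point
  degen <- model
  for (nm in names(degen@params)) degen@params[[nm]][] <- 0
  expect_warning(
    r0 <- enumerationColocalization(degen, mset, nBackground = 50L,
                                    nTest = 2L, kEnum = 2L, seed = 3L),
    "using all")
  expect_equal(unname(r0$groupMeanDistance), c(0, 0), tolerance = 1e-12)
})

test_that("distance separation returns the full pairwise set and medians", {
  mset <- tinyCorpus(12L)
  vocab <- buildVocabulary(lapply(canonicalSmiles(mset), tokenizeSmiles))
  model <- buildAutoencoder(ModelConfig("gru", 10, 10, 1), vocab, "smiles",
                            maxLen = 20L, seed = 2L)
  res <- distanceSeparation(model, mset, nRandom = 3L, seed = 1L)
  expect_length(res$pairwiseDistances, 3L)          # 3*(3-1)/2
  expect_true(all(res$pairwiseDistances >= 0))
  res2 <- distanceSeparation(model, mset, nRandom = 8L,
                             testGroups = list(canonicalSmiles(mset)[1:2]),
                             seed = 1L)
  expect_length(res2$pairwiseDistances, 28L)
  expect_length(res2$groupMeanDistance, 1L)
  expect_identical(res2$backgroundMedian, median(res2$pairwiseDistances))
})
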