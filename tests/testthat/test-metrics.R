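# Reconstruction metrics

test_that("Mean Similarity applies the positional-match formula", {
  expect_equal(meanSimilarity(c("C", "C", "O"), c("C", "C", "O")), 1)
  expect_equal(meanSimilarity(c("C", "C", "O"), c("C", "C", "N")), 2 / 3)
  expect_equal(meanSimilarity(c("C", "C", "O"), "C"), 1 / 3)
  # reconstruction tokens beyond n are ignored
  expect_equal(meanSimilarity(c("C", "O"), c("C", "O", "N", "N")), 1)
  expect_error(meanSimilarity(character(0L), "C"), "non-empty")
})

test_that("DP Levenshtein equals the recursive oracle", {
  expect_equal(levenshteinDistance(c("C", "C", "O"), c("C", "C", "O")), 0L)
  expect_equal(levenshteinDistance(c("C", "C", "O"), c("C", "O")), 1L)
  expect_equal(levenshteinDistance(c("C", "O"), character(0L)), 2L)
  al <- c("C", "N", "O")
  # exhaustive over all pairs of strings up to length 3
  short <- allTokenStrings(al, 3L)
  for (a in short) for (b in short)
    expect_equal(levenshteinDistance(a, b), recursiveLevenshtein(a, b))
  # random pairs up to length 8
  set.seed(13)
  for (i in 1:300) {
    a <- sample(al, sample.int(8L, 1L), replace = TRUE)
    b <- sample(al, sample.int(8L, 1L), replace = TRUE)
    expect_equal(levenshteinDistance(a, b), recursiveLevenshtein(a, b))
  }
})

test_that("Levenshtein similarity is 1 - LD/n clamped at zero", {
  expect_equal(levenshteinSimilarity(c("C", "N", "O"), c("C", "N", "O")), 1)
  expect_equal(levenshteinSimilarity(c("C", "C", "O"), c("C", "O")),
               1 - 1 / 3)
  long <- rep("N", 12L)
  expect_equal(levenshteinSimilarity(c("C", "O"), long), 0)  # clamped
})

test_that("Full Reconstruction rate is the percent of exact matches", {
  p <- function(a, b) list(a, b)
  pairs <- list(p(c("C"), c("C")), p(c("C", "O"), c("C", "O")),
                p(c("C"), c("N")), p(c("O"), c("C", "O")))
  expect_equal(fullReconstructionRate(pairs), 50)
  expect_equal(fullReconstructionRate(pairs[1:2]), 100)
  expect_equal(fullReconstructionRate(pairs[3:4]), 0)
  expect_error(fullReconstructionRate(list()), "non-empty")
})

test_that("equal-length pairs give Levenshtein similarity >= Mean Similarity", {
  # edit distance <= Hamming distance; substitution-only perturbations
  set.seed(7)
  al <- c("C", "N", "O", "F")
  for (i in 1:100) {
    n <- sample(3:12, 1L)
    a <- sample(al, n, replace = TRUE)
    b <- a
    nSub <- sample.int(n, 1L)
    pos <- sample.int(n, nSub)
    b[pos] <- sample(al, nSub, replace = TRUE)
    expect_gte(levenshteinSimilarity(a, b), meanSimilarity(a, b) - 1e-12)
  }
})

test_that("evaluateModel reports consistent metrics and skips OOV input", {
  tb <- tinyBatch()
  model <- buildAutoencoder(ModelConfig("gru", 10, 10, 1), tb$vocab,
                            "smiles", maxLen = 12L, seed = 4L)
  rep <- evaluateModel(model, c("CCO", "CC(=O)O"))
  df <- as.data.frame(rep)
  expect_equal(nrow(df), 2L)
  expect_true(all(df$meanSimilarity >= 0 & df$meanSimilarity <= 1))
  expect_true(all(df$levenshteinSimilarity >= 0 &
                  df$levenshteinSimilarity <= 1))
  expect_gte(rep@fullReconstruction, 0)
  expect_lte(rep@fullReconstruction, 100)
  # exactMatch implies both similarities are exactly 1
  expect_true(all(df$meanSimilarity[df$exactMatch] == 1))
  expect_true(all(df$levenshteinSimilarity[df$exactMatch] == 1))
  # out-of-vocabulary molecules are skipped with a warning and counted
  expect_warning(r2 <- evaluateModel(model, c("CCO", "CCS")), "1 molecule")
  expect_identical(r2@nSkipped, 1L)
  expect_equal(nrow(as.data.frame(r2)), 1L)
})
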