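# Tokenization, vocabulary, canonicalization, enumeration, one-hot, .smi I/O

test_that("SMILES tokenizer splits standard constructs and round-trips", {
  expect_identical(tokenizeSmiles("CCO"), c("C", "C", "O"))
  expect_identical(tokenizeSmiles("CCl"), c("C", "Cl"))
  expect_identical(tokenizeSmiles("BrCC[N+](C)C"),
                   c("Br", "C", "C", "[N+]", "(", "C", ")", "C"))
  aro <- tokenizeSmiles("c1ccccc1")
  expect_length(aro, 8L)
  expect_true(all(nchar(aro) == 1L))
  expect_identical(tokenizeSmiles("C%12CC%12"), c("C", "%12", "C", "C", "%12"))
  # concatenation identity over a generated corpus
  for (s in canonicalSmiles(tinyCorpus()))
    expect_identical(paste0(tokenizeSmiles(s), collapse = ""), s)
})

test_that("SMILES tokenizer reports the offending position", {
  err <- expect_error(tokenizeSmiles("CC!O"), "position 3")
  expect_error(tokenizeSmiles(""), "non-empty")
})

test_that("SELFIES tokenizer splits bracket tokens and round-trips", {
  expect_identical(tokenizeSelfies("[C][C][O]"), c("[C]", "[C]", "[O]"))
  expect_identical(tokenizeSelfies("[C][=O]"), c("[C]", "[=O]"))
  expect_length(tokenizeSelfies("[C][Branch1][C][F]"), 4L)
  expect_error(tokenizeSelfies("[C][C"), "malformed")
  for (s in selfiesStrings(tinyCorpus()))
    expect_identical(paste0(tokenizeSelfies(s), collapse = ""), s)
})

test_that("vocabulary puts specials first and indexes a bijection", {
  v <- buildVocabulary(list(c("C", "C", "O")))
  expect_equal(vocabSize(v), 5L)
  expect_identical(tokenIndex(v, c("<pad>", "<sos>", "<eos>")), 0:2)
  v2 <- buildVocabulary(list(c("O", "N"), c("C", "N")))
  idx <- tokenIndex(v2, v2@tokens)
  expect_identical(sort(idx), 0:5)                  # contiguous bijection
  expect_identical(v2@tokens[4:6], c("C", "N", "O"))  # sorted chemistry
  expect_error(buildVocabulary(list()), "non-empty")
  expect_error(tokenIndex(v, "Zz"), "Zz")
})

test_that("vocabulary JSON round trip preserves exact indices", {
  v <- buildVocabulary(lapply(canonicalSmiles(tinyCorpus()), tokenizeSmiles))
  path <- withr::local_tempfile(fileext = ".json")
  writeVocabulary(v, path)
  v2 <- readVocabulary(path)
  expect_identical(v2@tokens, v@tokens)
  expect_identical(tokenIndex(v2, v@tokens), tokenIndex(v, v@tokens))
})

test_that("canonicalization is idempotent and merges equivalent SMILES", {
  expect_identical(canonicalizeSmiles("OCC"), canonicalizeSmiles("CCO"))
  for (s in c("CC(=O)O", "C1CCNCC1", "N#Cc1ccccc1")) {
    once <- canonicalizeSmiles(s)
    expect_identical(canonicalizeSmiles(once), once)
  }
  expect_error(canonicalizeSmiles("C1CC"), "invalid")
  expect_identical(canonicalizeSmiles(c("C1CC", "CCO"),
                                      onInvalid = "na")[1L], NA_character_)
})

test_that("enumeration yields distinct non-canonical forms of the molecule", {
  smi <- "CC(=O)OC1=CC=CC=C1C(=O)O"
  can <- canonicalizeSmiles(smi)
  en <- enumerateSmiles(smi, k = 4L, seed = 5L)
  expect_length(en, 4L)
  expect_length(unique(c(can, en)), 5L)             # pairwise distinct
  expect_identical(canonicalizeSmiles(en), rep(can, 4L))
  expect_identical(en, enumerateSmiles(smi, k = 4L, seed = 5L))  # per seed
  expect_false(identical(en, enumerateSmiles(smi, k = 4L, seed = 6L)))
  expect_error(enumerateSmiles("C", k = 1L), "single-atom")
  expect_error(enumerateSmiles("CO", k = 4L), "could only produce")
})

test_that("one-hot encoding is a lossless inverse pair with PAD tail", {
  tb <- tinyBatch()
  arr <- tb$batch$array
  expect_true(all(apply(arr, c(1, 2), sum) == 1))   # one-hot rows
  # round trip
  for (i in seq_along(tb$seqs)) {
    idx <- apply(arr[i, , ], 1L, which.max) - 1L
    expect_identical(decodeIndices(idx, tb$vocab),
                     paste0(tb$seqs[[i]], collapse = ""))
  }
  # a 3-token sequence in maxLen 10: EOS at position 4, PAD beyond
  b <- oneHotEncode(list(c("C", "C", "O")), tb$vocab, maxLen = 10L)
  idx <- apply(b$array[1, , ], 1L, which.max) - 1L
  expect_identical(idx[4L], tokenIndex(tb$vocab, "<eos>"))
  expect_true(all(idx[5:10] == tokenIndex(tb$vocab, "<pad>")))
  expect_equal(b$lengths, 4L)
  # errors
  expect_error(oneHotEncode(list(c("C", "Zz")), tb$vocab), "Zz")
  expect_error(oneHotEncode(list(rep("C", 9L)), tb$vocab, maxLen = 5L),
               "longer")
})

test_that(".smi round trip preserves molecules and counts skips", {
  mset <- tinyCorpus(6L)
  path <- withr::local_tempfile(fileext = ".smi")
  writeSmi(mset, path)
  back <- readSmi(path)
  expect_identical(canonicalSmiles(back), canonicalSmiles(mset))
  expect_identical(attr(back, "skipped"), 0L)
  # invalid and blank lines are skipped with a warning
  writeLines(c("CCO", "", "C1CC", "CCN"), path)
  expect_warning(m2 <- readSmi(path), "skipped 2")
  expect_length(m2, 2L)
  expect_identical(attr(m2, "skipped"), 2L)
  expect_error(readSmi(file.path(tempdir(), "nope_missing.smi")),
               "cannot read")
})
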