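# Synthetic molecule and loss-trace generators.
#
# Random SELFIES token strings are valid molecules by construction, which
# makes them a convenient stand-in for a drug-like benchmark corpus:
# bounded token length, restricted organic alphabet, guaranteed parseable.

#' Generate a synthetic molecule corpus
#'
#' Samples random SELFIES token sequences over a robust organic alphabet,
#' decodes them to molecules, and keeps those that are distinct (by
#' canonical SMILES) and have at least `minHeavyAtoms` heavy atoms, until
#' `n` molecules are collected.  Records carry both the canonical SMILES
#' and the SELFIES translation of the accepted molecule.  Deterministic per
#' seed.
#'
#' A minimum heavy-atom count is imposed because very small fragments
#' support too few alternative atom orderings to be enumerable, and a
#' drug-like corpus contains no 2-atom molecules anyway.
#'
#' @param n number of molecules.
#' @param minTokens,maxTokens SELFIES token-length bounds of the sampled
#'   strings.
#' @param alphabet SELFIES tokens to sample from ([robustAlphabet()] by
#'   default).
#' @param seed integer seed.
#' @param minHeavyAtoms minimum heavy-atom count of accepted molecules.
#' @param enumerate if positive, attach this many non-canonical SMILES
#'   enumerations per accepted molecule (molecules that cannot be
#'   enumerated that many times are rejected and resampled).
#' @param maxAttempts sampling budget; exceeded -> error stating the count
#'   achieved.
#' @return a [MoleculeSet-class] with `n` molecules.
#' @examples
#' \donttest{generateMolecules(5, seed = 7)}
#' @export
generateMolecules <- function(n, minTokens = 6L, maxTokens = 15L,
                              alphabet = robustAlphabet(), seed = 1L,
                              minHeavyAtoms = 5L, enumerate = 0L,
                              maxAttempts = 60L * n) {
  stopifnot(n >= 1L, minTokens >= 1L, minTokens <= maxTokens,
            length(alphabet) >= 1L)
  if (!all(grepl("^\\[[^\\[\\]]+\\]$", alphabet, perl = TRUE)))
    stop("alphabet tokens must be bracket-delimited")
  withr::with_seed(as.integer(seed), {
    smiles <- character(0L)
    selfies <- character(0L)
    enums <- list()
    attempts <- 0L
    while (length(smiles) < n && attempts < maxAttempts) {
      attempts <- attempts + 1L
      len <- sample(seq.int(minTokens, maxTokens), 1L)
      str <- paste0(sample(alphabet, len, replace = TRUE), collapse = "")
      smi <- selfiesToSmiles(str)
      if (!nzchar(smi)) next
      can <- canonicalizeSmiles(smi, onInvalid = "na")
      if (is.na(can) || can %in% smiles) next
      if (heavyAtoms(can) < minHeavyAtoms) next
      if (enumerate > 0L) {
        en <- tryCatch(
          enumerateSmiles(can, k = as.integer(enumerate),
                          seed = sample.int(.Machine$integer.max, 1L)),
          error = function(e) NULL)
        if (is.null(en)) next
        enums <- c(enums, list(en))
      } else enums <- c(enums, list(character(0L)))
      smiles <- c(smiles, can)
      # re-encode so the stored SELFIES matches the canonical structure
      selfies <- c(selfies, smilesToSelfies(can))
    }
    if (length(smiles) < n)
      stop(sprintf("could only generate %d of %d distinct molecules",
                   length(smiles), n))
    new("MoleculeSet", smiles = smiles, selfies = selfies,
        enumerations = enums)
  })
}

#' Token-frequency and string-length statistics of a corpus
#'
#' Summarizes a molecule corpus the way a benchmark subset is sanity
#' checked against its full set: the distribution of string lengths (in
#' tokens) and the per-molecule-normalized token frequencies.  Both are
#' deterministic functions of the corpus, so per-seed corpora yield
#' reproducible histograms.
#'
#' @param mset a [MoleculeSet-class].
#' @param representation `"smiles"` or `"selfies"`.
#' @param plot draw the two base-graphics panels.
#' @return list with `lengths` (integer vector, tokens per molecule) and
#'   `tokenFrequencies` (named numeric, occurrences per molecule),
#'   invisibly when `plot = TRUE`.
#' @export
corpusStatistics <- function(mset, representation = c("smiles", "selfies"),
                             plot = FALSE) {
  representation <- match.arg(representation)
  strings <- if (representation == "selfies") {
    s <- selfiesStrings(mset)
    if (anyNA(s)) s <- vapply(canonicalSmiles(mset), smilesToSelfies, "")
    s
  } else canonicalSmiles(mset)
  seqs <- lapply(strings, tokenizeFor, representation = representation)
  lens <- lengths(seqs)
  freq <- sort(table(unlist(seqs)) / length(seqs), decreasing = TRUE)
  out <- list(lengths = lens,
              tokenFrequencies = stats::setNames(as.numeric(freq),
                                                 names(freq)))
  if (plot) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
    graphics::hist(lens, main = "String length", xlab = "tokens",
                   col = "grey80")
    graphics::barplot(out$tokenFrequencies, las = 2,
                      main = "Token frequency",
                      ylab = "occurrences / molecule")
    return(invisible(out))
  }
  out
}

#' Generate a synthetic validation-loss trace
#'
#' Test harness for the early-stopping rule.  `"improving"` traces decrease
#' by more than `minDelta` every epoch; `"plateau_after_k"` traces improve
#' until epoch `k` and then fluctuate within less than `minDelta` of the
#' epoch-`k` loss.
#'
#' @param pattern `"improving"` or `"plateau_after_k"`.
#' @param length number of epochs.
#' @param k plateau onset epoch (for `"plateau_after_k"`).
#' @param seed integer seed.
#' @param minDelta the improvement threshold the trace is built around.
#' @return numeric vector of validation losses.
#' @export
generateLossTrace <- function(pattern = c("improving", "plateau_after_k"),
                              length, k = 50L, seed = 1L, minDelta = 0.01) {
  pattern <- match.arg(pattern)
  stopifnot(length >= 1L)
  withr::with_seed(as.integer(seed), {
    if (pattern == "improving") {
      drops <- minDelta * 1.5 + runif(length, 0, minDelta)
      start <- 5 + runif(1L)
      start - cumsum(drops) + drops[1L]
    } else {
      stopifnot(k >= 1L)
      nImp <- min(k, length)
      drops <- minDelta * 1.5 + runif(nImp, 0, minDelta)
      start <- 5 + runif(1L)
      improving <- start - cumsum(drops) + drops[1L]
      if (length <= k) return(improving[seq_len(length)])
      base <- improving[nImp]
      jitter <- runif(length - k, -minDelta * 0.45, minDelta * 0.45)
      c(improving, base + jitter)
    }
  })
}
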