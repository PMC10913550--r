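# Reconstruction metrics: Mean Similarity, token-level Levenshtein
# similarity, Full Reconstruction rate.
#
# All three operate on token sequences, not characters, so a two-letter
# element like "Cl" counts as one unit.  The normalizing length n is always
# the input (ground-truth) token count.

#' Mean Similarity between an input and its reconstruction
#'
#' The fraction of positions whose tokens match:
#' `(1/n) * sum_i f(s_i_input, s_i_recon)` with `n` the input token count
#' and `f` the indicator of equality.  Positions beyond the
#' reconstruction's length score 0; reconstruction tokens beyond `n` are
#' ignored.
#'
#' @param input,recon character vectors of tokens (same representation).
#' @return value in [0, 1].
#' @examples
#' meanSimilarity(c("C", "C", "O"), c("C", "C", "N"))  # 2/3
#' @export
meanSimilarity <- function(input, recon) {
  n <- length(input)
  if (n == 0L) stop("input sequence must be non-empty")
  k <- min(n, length(recon))
  if (k == 0L) return(0)
  sum(input[seq_len(k)] == recon[seq_len(k)]) / n
}

# distinct token strings -> single unicode characters so the C edit-distance
# routine can run on token level
.tokensToChars <- function(a, b) {
  toks <- unique(c(a, b))
  codes <- setNames(intToUtf8(96L + seq_along(toks), multiple = TRUE), toks)
  c(paste0(codes[a], collapse = ""), paste0(codes[b], collapse = ""))
}

#' Token-level Levenshtein distance
#'
#' Minimum number of token substitutions, insertions and deletions
#' transforming one sequence into the other, computed by dynamic
#' programming.
#'
#' @param a,b character vectors of tokens (possibly empty).
#' @return non-negative integer.
#' @export
levenshteinDistance <- function(a, b) {
  if (length(a) == 0L) return(length(b))
  if (length(b) == 0L) return(length(a))
  s <- .tokensToChars(a, b)
  as.integer(adist(s[1L], s[2L]))
}

#' Levenshtein similarity
#'
#' `1 - LD / n` with `n` the input token count, clamped below at 0 so a
#' reconstruction much longer than the input scores 0 rather than a
#' negative value.
#'
#' @param input,recon character vectors of tokens.
#' @return value in [0, 1].
#' @export
levenshteinSimilarity <- function(input, recon) {
  n <- length(input)
  if (n == 0L) stop("input sequence must be non-empty")
  max(0, 1 - levenshteinDistance(input, recon) / n)
}

#' Full Reconstruction rate
#'
#' Percentage of pairs whose reconstruction is token-for-token identical to
#' the input (not a single mismatch).
#'
#' @param pairs list of 2-element lists/pairs of token vectors
#'   (input, reconstruction).
#' @return percent in [0, 100].
#' @export
fullReconstructionRate <- function(pairs) {
  if (length(pairs) == 0L) stop("pairs must be non-empty")
  hits <- vapply(pairs, function(p) identical(unname(p[[1L]]),
                                              unname(p[[2L]])), TRUE)
  100 * mean(hits)
}

#' Evaluate an autoencoder on a molecule set
#'
#' Free-running (no teacher forcing) greedy decoding of every molecule,
#' followed by the three reconstruction metrics on token sequences.
#' Molecules containing tokens outside the model's vocabulary are skipped
#' with a warning and counted in `nSkipped`.
#'
#' @param model a [MolAutoencoder-class].
#' @param molecules a [MoleculeSet-class] or character vector of strings in
#'   the model's representation.
#' @return a [ReconstructionReport-class].
#' @export
evaluateModel <- function(model, molecules) {
  strings <- if (is(molecules, "MoleculeSet")) {
    if (model@representation == "selfies") {
      s <- selfiesStrings(molecules)
      if (anyNA(s)) s <- vapply(canonicalSmiles(molecules), smilesToSelfies,
                                "")
      s
    } else canonicalSmiles(molecules)
  } else as.character(molecules)
  if (length(strings) == 0L) stop("no molecules to evaluate")
  seqs <- lapply(strings, tokenizeFor, representation = model@representation)
  known <- vapply(seqs, function(s) all(s %in% model@vocab@tokens), TRUE)
  if (!all(known))
    warning(sprintf("skipping %d molecule(s) with out-of-vocabulary tokens",
                    sum(!known)))
  strings <- strings[known]; seqs <- seqs[known]
  if (length(strings) == 0L) stop("no decodable molecules after vocabulary filtering")
  recon <- reconstructMolecules(model, strings)
  reconSeqs <- attr(recon, "tokens")
  if (is.null(reconSeqs))
    reconSeqs <- lapply(recon, function(s)
      if (nzchar(s)) tokenizeFor(model@representation, s) else character(0L))
  recon <- as.character(recon)
  ms <- mapply(meanSimilarity, seqs, reconSeqs)
  lv <- mapply(levenshteinSimilarity, seqs, reconSeqs)
  ex <- mapply(function(a, b) identical(a, b), seqs, reconSeqs)
  df <- data.frame(input = strings, reconstruction = recon,
                   meanSimilarity = ms, levenshteinSimilarity = lv,
                   exactMatch = ex, row.names = NULL)
  new("ReconstructionReport", perMolecule = df,
      meanSimilarity = mean(ms), levenshteinSimilarity = mean(lv),
      fullReconstruction = 100 * mean(ex), nSkipped = sum(!known))
}

#' Aggregate reconstruction reports across seeds
#'
#' @param reports list of [ReconstructionReport-class] objects.
#' @return data.frame with mean/min/max per metric.
#' @export
aggregateReports <- function(reports) {
  stopifnot(length(reports) >= 1L)
  agg <- function(f) {
    v <- vapply(reports, f, 0)
    c(mean(v), min(v), max(v))
  }
  out <- rbind(meanSimilarity = agg(function(r) r@meanSimilarity),
               levenshteinSimilarity =
                 agg(function(r) r@levenshteinSimilarity),
               fullReconstruction = agg(function(r) r@fullReconstruction))
  colnames(out) <- c("mean", "min", "max")
  as.data.frame(out)
}
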