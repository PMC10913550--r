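# Tokenization, vocabulary construction and one-hot encoding.

.SMILES_TOKEN_RE <- paste0(
  "\\[[^\\]]*\\]",          # bracket atoms as single tokens
  "|Cl|Br",                 # two-letter elements
  "|%[0-9]{2}",             # two-digit ring closures
  "|[BCNOPSFI]",            # organic-subset atoms
  "|[bcnops]",              # aromatic atoms
  "|[-=#$:/\\\\.+()0-9*]"   # bonds, branches, ring digits, misc
)

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into chemistry tokens using the community-standard
#' regex scheme: bracket atoms `[...]` are single tokens, the two-letter
#' elements `Cl`/`Br` are kept whole, `%nn` ring closures are one token, and
#' everything else (atoms, aromatic atoms, bonds, branch parentheses, ring
#' digits) is a single character.  Concatenating the tokens reproduces the
#' input exactly.
#'
#' @param s a non-empty SMILES string.
#' @return character vector of tokens.
#' @examples
#' tokenizeSmiles("CC(=O)Cl")   # "C" "C" "(" "=" "O" ")" "Cl"
#' @export
tokenizeSmiles <- function(s) {
  if (!is.character(s) || length(s) != 1L || !nzchar(s))
    stop("s must be a single non-empty SMILES string")
  m <- gregexpr(.SMILES_TOKEN_RE, s, perl = TRUE)[[1L]]
  toks <- regmatches(s, list(m))[[1L]]
  if (!identical(paste0(toks, collapse = ""), s)) {
    # locate the first character not consumed by any token
    covered <- rep(FALSE, nchar(s))
    for (i in seq_along(m))
      covered[m[i]:(m[i] + attr(m, "match.length")[i] - 1L)] <- TRUE
    pos <- which(!covered)[1L]
    stop(sprintf("cannot tokenize SMILES at position %d: '%s'",
                 pos, substr(s, pos, pos)))
  }
  toks
}

#' Tokenize a SELFIES string
#'
#' SELFIES strings are concatenations of bracket-delimited tokens; this
#' splits them into the maximal bracket-delimited substrings, in order.
#'
#' @param s a SELFIES string such as `"[C][C][O]"`.
#' @return character vector of tokens.
#' @export
tokenizeSelfies <- function(s) {
  if (!is.character(s) || length(s) != 1L || !nzchar(s))
    stop("s must be a single non-empty SELFIES string")
  toks <- regmatches(s, gregexpr("\\[[^\\[\\]]*\\]", s, perl = TRUE))[[1L]]
  if (!identical(paste0(toks, collapse = ""), s))
    stop("malformed SELFIES string (unbalanced or stray brackets): ", s)
  toks
}

#' Build a vocabulary from tokenized sequences
#'
#' Collects every distinct token of a corpus and prepends the reserved
#' specials, so PAD = 0, SOS = 1, EOS = 2 and chemistry tokens follow in
#' lexicographic (C-locale) order.  The ordering is deterministic, making
#' one-hot encodings reproducible across runs.
#'
#' @param corpus a list of token character vectors (all from one
#'   representation).
#' @return A [Vocabulary-class] object.
#' @examples
#' buildVocabulary(list(c("C", "C", "O")))   # 3 specials + C + O
#' @export
buildVocabulary <- function(corpus) {
  if (!is.list(corpus) || length(corpus) == 0L)
    stop("corpus must be a non-empty list of token vectors")
  toks <- unique(unlist(corpus, use.names = FALSE))
  if (is.null(toks) || length(toks) == 0L)
    stop("corpus contains no tokens")
  bracketed <- grepl("^\\[", toks)
  if (any(bracketed) && !all(bracketed) && sum(bracketed) > length(toks) / 2)
    stop("corpus mixes SELFIES and SMILES tokens")
  specials <- c(pad = "<pad>", sos = "<sos>", eos = "<eos>")
  if (any(toks %in% specials)) stop("corpus contains reserved special tokens")
  chem <- withr::with_locale(c(LC_COLLATE = "C"), sort(toks))
  new("Vocabulary", tokens = c(unname(specials), chem), specials = specials)
}

#' Serialize / reload a vocabulary as JSON
#'
#' The ordered token list and the special-token names are written verbatim,
#' so a reloaded vocabulary reproduces the exact same indices.
#'
#' @param vocab a [Vocabulary-class].
#' @param path file path.
#' @return `readVocabulary` returns a [Vocabulary-class].
#' @export
writeVocabulary <- function(vocab, path) {
  jsonlite::write_json(list(tokens = vocab@tokens,
                            specials = as.list(vocab@specials)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeVocabulary
#' @export
readVocabulary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("Vocabulary", tokens = x$tokens,
      specials = unlist(x$specials)[c("pad", "sos", "eos")])
}

#' One-hot encode tokenized sequences
#'
#' Builds the `[n_molecules x max_len x vocab_size]` one-hot block the
#' encoder consumes.  Each sequence is terminated with EOS and padded with
#' PAD up to `maxLen`; `lengths` counts tokens including the EOS.
#'
#' @param seqs list of token character vectors.
#' @param vocab a [Vocabulary-class] covering all tokens.
#' @param maxLen maximum sequence length including EOS; defaults to the
#'   longest sequence + 1.
#' @return an object of class `OneHotBatch`: list with `array`
#'   (3-d numeric), `lengths` (integer), and the vocabulary.
#' @export
oneHotEncode <- function(seqs, vocab, maxLen = NULL) {
  stopifnot(is.list(seqs), length(seqs) >= 1L)
  lens <- lengths(seqs) + 1L                     # + EOS
  if (is.null(maxLen)) maxLen <- max(lens)
  if (any(lens > maxLen))
    stop("sequence(s) longer than maxLen - 1: ",
         paste(which(lens > maxLen), collapse = ", "))
  V <- vocabSize(vocab)
  idx <- indexEncode(seqs, vocab, maxLen)        # n x maxLen, 0-based
  n <- length(seqs)
  arr <- array(0, dim = c(n, maxLen, V))
  off <- rep(seq_len(n), maxLen) +
         n * (rep(seq_len(maxLen) - 1L, each = n)) +
         n * maxLen * as.vector(idx)
  arr[off] <- 1
  structure(list(array = arr, lengths = lens, vocab = vocab),
            class = "OneHotBatch")
}

# 0-based index matrix (n x maxLen) with EOS appended and PAD fill
indexEncode <- function(seqs, vocab, maxLen) {
  eos <- tokenIndex(vocab, vocab@specials[["eos"]])
  out <- matrix(0L, nrow = length(seqs), ncol = maxLen)  # PAD = 0
  for (i in seq_along(seqs)) {
    ti <- tokenIndex(vocab, seqs[[i]])
    out[i, seq_len(length(ti) + 1L)] <- c(ti, eos)
  }
  out
}

#' Decode token indices back to a string
#'
#' Inverse of the one-hot encoding: maps 0-based indices to tokens,
#' truncates at the first EOS and strips PAD/SOS, then concatenates.
#'
#' @param indices integer vector of 0-based token indices.
#' @param vocab a [Vocabulary-class].
#' @return a single string.
#' @export
decodeIndices <- function(indices, vocab) {
  stopifnot(all(indices >= 0L), all(indices < vocabSize(vocab)))
  toks <- vocab@tokens[indices + 1L]
  eos <- which(toks == vocab@specials[["eos"]])
  if (length(eos)) toks <- toks[seq_len(eos[1L] - 1L)]
  toks <- toks[!toks %in% vocab@specials]
  paste0(toks, collapse = "")
}
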