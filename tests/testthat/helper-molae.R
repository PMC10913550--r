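# Shared fixtures, built in code and cached for the session.

.fixtureCache <- new.env(parent = emptyenv())

# small reusable corpus of synthetic molecules
tinyCorpus <- function(n = 12L, seed = 11L, ...) {
  key <- paste0("corpus_", n, "_", seed, "_",
                paste(deparse(list(...)), collapse = ""))
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateMolecules(n, minTokens = 6L,
                                              maxTokens = 12L, seed = seed,
                                              ...)
  .fixtureCache[[key]]
}

# a tiny one-hot batch over a handful of SMILES
tinyBatch <- function(smiles = c("CCO", "CC(=O)O", "C1CCNCC1")) {
  seqs <- lapply(smiles, tokenizeSmiles)
  vocab <- buildVocabulary(seqs)
  list(batch = oneHotEncode(seqs, vocab), vocab = vocab, seqs = seqs)
}

# memoized recursive token edit distance -- independent oracle for the
# dynamic-programming implementation
recursiveLevenshtein <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    cost <- if (a[i] == b[j]) 0L else 1L
    r <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L,
             rec(i - 1L, j - 1L) + cost)
    memo[[key]] <- r
    r
  }
  rec(length(a), length(b))
}

# all token strings up to a given length over an alphabet
allTokenStrings <- function(alphabet, maxLen) {
  out <- list(character(0L))
  frontier <- list(character(0L))
  for (l in seq_len(maxLen)) {
    frontier <- unlist(lapply(frontier, function(s)
      lapply(alphabet, function(a) c(s, a))), recursive = FALSE)
    out <- c(out, frontier)
  }
  out
}

# finite-difference gradient check for a configuration; returns worst
# relative error over sampled coordinates with non-negligible gradients
gradCheckWorst <- function(cfg, seed = 3L, nCoords = 3L, d = 1e-4) {
  V <- 6L; B <- 3L; Tenc <- 4L; Tdec <- 5L
  set.seed(seed)
  P <- initParams <- molae:::initParams(cfg, V, seed = seed)
  lens <- c(2L, 4L, 3L)
  X <- array(0, dim = c(B, Tenc, V))
  for (b in seq_len(B)) for (t in seq_len(Tenc))
    X[b, t, sample(3:V, 1L)] <- 1
  Yidx <- matrix(sample(0:(V - 1L), B * Tdec, replace = TRUE), B, Tdec)
  maskY <- outer(seq_len(B), seq_len(Tdec),
                 function(b, t) t <= c(3L, 5L, 4L)[b])
  eps <- if (cfg@variational) matrix(rnorm(B * cfg@latentSize), B) else NULL
  res <- molae:::trainStep(P, cfg, X, lens, Yidx, maskY, eps = eps)
  worst <- 0
  for (nm in names(P)) {
    x <- P[[nm]]
    for (ii in sample(length(x), min(nCoords, length(x)))) {
      P2 <- P; P2[[nm]][ii] <- x[ii] + d
      l1 <- molae:::trainStep(P2, cfg, X, lens, Yidx, maskY, eps = eps,
                              wantGrads = FALSE)$loss
      P2[[nm]][ii] <- x[ii] - d
      l0 <- molae:::trainStep(P2, cfg, X, lens, Yidx, maskY, eps = eps,
                              wantGrads = FALSE)$loss
      num <- (l1 - l0) / (2 * d)
      ana <- res$grads[[nm]][ii]
      if (abs(num) + abs(ana) < 1e-7) next   # below finite-diff resolution
      worst <- max(worst, abs(num - ana) / (abs(num) + abs(ana)))
    }
  }
  worst
}
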