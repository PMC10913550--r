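# Organic-subset SELFIES codec.
#
# Implements the SELFIES idea -- a bracket-token molecular string format in
# which every token sequence decodes to a valid molecule -- for neutral,
# single-fragment organic molecules (C, N, O, F, S, P, Cl, Br; bond orders
# 1-3; branches and rings).  Decoding is robust: bond orders are capped by
# the remaining valence of both partners and structurally impossible tokens
# are skipped, so arbitrary token strings always yield a chemically valid
# (possibly empty) molecule.  Encoding is a depth-first traversal of the
# kekulized molecular graph; branch lengths and ring distances are carried
# by overloaded index tokens (base-16 encoding via a fixed 16-token table).

.SELFIES_CAPS <- c(C = 4L, N = 3L, O = 2L, F = 1L, S = 6L, P = 5L,
                   Cl = 1L, Br = 1L)

.SELFIES_INDEX <- c("[C]" = 0L, "[Ring1]" = 1L, "[Ring2]" = 2L,
                    "[Branch1]" = 3L, "[Branch2]" = 4L, "[O]" = 5L,
                    "[N]" = 6L, "[=N]" = 7L, "[=C]" = 8L, "[#C]" = 9L,
                    "[S]" = 10L, "[P]" = 11L, "[F]" = 12L, "[=O]" = 13L,
                    "[Cl]" = 14L, "[Br]" = 15L)

.selfiesIndexValue <- function(tok) {
  v <- .SELFIES_INDEX[tok]
  ifelse(is.na(v), 0L, v)
}

.indexTokens <- function(q, n) {
  # q encoded base-16, most significant first, n index tokens
  digits <- integer(n)
  for (i in rev(seq_len(n))) {
    digits[i] <- q %% 16L
    q <- q %/% 16L
  }
  names(.SELFIES_INDEX)[digits + 1L]
}

.bondPrefix <- function(order) c("", "=", "#")[order]
.bondOrderOf <- function(prefix) match(prefix, c("", "=", "#"))

#' The default robust SELFIES alphabet
#'
#' A small organic token set (single/double-bonded C, N, O, fluorine,
#' branch and ring control tokens) over which random token strings decode
#' to drug-like neutral fragments.
#'
#' @return character vector of SELFIES tokens.
#' @export
robustAlphabet <- function() {
  c("[C]", "[=C]", "[N]", "[=N]", "[O]", "[=O]", "[F]",
    "[Branch1]", "[Ring1]")
}

# ---- decoder ----------------------------------------------------------------

# tokens -> graph; robust: never errors on token content
decodeSelfiesTokens <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$elem <- character(0L)
  env$free <- integer(0L)
  env$bonds <- matrix(integer(), ncol = 3L,
                      dimnames = list(NULL, c("a", "b", "order")))
  parseSegment(tokens, NA_integer_, env)
  list(elem = env$elem, bonds = env$bonds, annotated = FALSE)
}

# parse a token vector attached to atom `attach`; mutates env
parseSegment <- function(toks, attach, env) {
  cur <- attach
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    tok <- toks[i]
    m <- regmatches(tok, regexec("^\\[([=#]?)([A-Z][a-z]?)\\]$", tok))[[1L]]
    if (length(m) == 3L && m[3L] %in% names(.SELFIES_CAPS)) {
      # atom token
      elem <- m[3L]
      o <- .bondOrderOf(m[2L])
      cap <- .SELFIES_CAPS[[elem]]
      if (is.na(cur)) {
        env$elem <- c(env$elem, elem)
        env$free <- c(env$free, cap)
        cur <- length(env$elem)
      } else {
        if (env$free[cur] < 1L) return(invisible())  # chain saturated: stop
        o <- min(o, env$free[cur], cap)
        env$elem <- c(env$elem, elem)
        env$free <- c(env$free, cap - o)
        newA <- length(env$elem)
        env$bonds <- rbind(env$bonds, c(cur, newA, o))
        env$free[cur] <- env$free[cur] - o
        cur <- newA
      }
      i <- i + 1L
    } else if (grepl("^\\[Branch[12]\\]$", tok)) {
      nIdx <- as.integer(sub("^\\[Branch([12])\\]$", "\\1", tok))
      q <- .readIndex(toks, i + 1L, nIdx)
      contentStart <- i + nIdx + 1L
      contentEnd <- min(n, contentStart + q)         # q + 1 tokens
      if (!is.na(cur) && env$free[cur] >= 2L && contentStart <= n) {
        parseSegment(toks[contentStart:contentEnd], cur, env)
        i <- contentEnd + 1L
      } else {
        i <- i + nIdx + 1L                           # skip symbol + indices
      }
    } else if (grepl("^\\[[=#]?Ring[12]\\]$", tok)) {
      mm <- regmatches(tok, regexec("^\\[([=#]?)Ring([12])\\]$", tok))[[1L]]
      o <- .bondOrderOf(mm[2L])
      nIdx <- as.integer(mm[3L])
      q <- .readIndex(toks, i + 1L, nIdx)
      if (!is.na(cur)) {
        target <- max(1L, cur - (q + 1L))
        o <- min(o, env$free[cur], env$free[target])
        exists <- nrow(env$bonds) > 0L &&
          any((env$bonds[, "a"] == target & env$bonds[, "b"] == cur) |
              (env$bonds[, "a"] == cur & env$bonds[, "b"] == target))
        if (target != cur && !exists && o >= 1L) {
          env$bonds <- rbind(env$bonds, c(target, cur, o))
          env$free[cur] <- env$free[cur] - o
          env$free[target] <- env$free[target] - o
        }
      }
      i <- i + nIdx + 1L
    } else {
      i <- i + 1L                                    # unknown token: no-op
    }
  }
  invisible()
}

.readIndex <- function(toks, from, nIdx) {
  q <- 0L
  for (j in seq_len(nIdx)) {
    tok <- if (from + j - 1L <= length(toks)) toks[from + j - 1L] else NA
    v <- if (is.na(tok)) 0L else .selfiesIndexValue(tok)
    q <- q * 16L + as.integer(v)
  }
  q
}

# ---- encoder ----------------------------------------------------------------

# graph -> token vector (DFS from atom 1, neighbors in index order)
encodeGraphTokens <- function(graph) {
  na <- length(graph$elem)
  if (na == 0L) return(character(0L))
  if (graph$annotated)
    stop("charged/isotopic molecules are outside the SELFIES subset")
  caps <- .SELFIES_CAPS[graph$elem]
  if (anyNA(caps))
    stop("element(s) outside the SELFIES subset: ",
         paste(unique(graph$elem[is.na(caps)]), collapse = ", "))
  deg <- integer(na)
  adj <- vector("list", na)
  bonds <- graph$bonds
  for (r in seq_len(nrow(bonds))) {
    a <- bonds[r, "a"]; b <- bonds[r, "b"]; o <- bonds[r, "order"]
    adj[[a]] <- rbind(adj[[a]], c(b, o))
    adj[[b]] <- rbind(adj[[b]], c(a, o))
    deg[a] <- deg[a] + o; deg[b] <- deg[b] + o
  }
  if (any(deg > caps))
    stop("molecule exceeds the codec's valence caps")
  if (any(bonds[, "order"] > 3L) || any(bonds[, "order"] < 1L))
    stop("bond order outside 1..3 (aromatic molblock?)")
  adj <- lapply(adj, function(x)
    if (is.null(x)) x else x[order(x[, 1L]), , drop = FALSE])

  visitPos <- integer(na)          # DFS pre-order position, 0 = unvisited
  counter <- 0L
  ringsAt <- vector("list", na)    # closures emitted at later endpoint

  serialize <- function(a, incomingOrder, parent) {
    counter <<- counter + 1L
    visitPos[a] <<- counter
    prefix <- .bondPrefix(incomingOrder)
    toks <- sprintf("[%s%s]", prefix, graph$elem[a])
    children <- list()
    nb <- adj[[a]]
    for (r in seq_len(NROW(nb))) {
      b <- nb[r, 1L]; o <- nb[r, 2L]
      if (!is.na(parent) && b == parent) next
      if (visitPos[b] > 0L) {
        # back edge; the earlier endpoint saw b unvisited, so this is the
        # only time the edge is recorded -- always at the later endpoint
        ringsAt[[a]] <<- c(ringsAt[[a]], list(c(b, o)))
      } else {
        children <- c(children, list(c(b, o)))
      }
    }
    # rings are emitted right after the atom token (decoder state matches)
    for (z in ringsAt[[a]]) {
      q <- visitPos[a] - visitPos[z[1L]] - 1L
      nIdx <- if (q <= 15L) 1L else 2L
      if (q > 255L) stop("ring span too large for this codec")
      ringTok <- sprintf("[%sRing%d]", .bondPrefix(z[2L]), nIdx)
      toks <- c(toks, ringTok, .indexTokens(q, nIdx))
    }
    # children not yet visited (a ring sibling may have been visited since)
    subs <- list()
    for (ch in children)
      if (visitPos[ch[1L]] == 0L)
        subs <- c(subs, list(serialize(ch[1L], ch[2L], a)))
    if (length(subs)) {
      for (s in subs[-length(subs)]) {
        q <- length(s) - 1L
        nIdx <- if (q <= 15L) 1L else 2L
        if (q > 255L) stop("branch too long for this codec")
        toks <- c(toks, sprintf("[Branch%d]", nIdx), .indexTokens(q, nIdx), s)
      }
      toks <- c(toks, subs[[length(subs)]])
    }
    toks
  }
  serialize(1L, 1L, NA_integer_)
}

# ---- public API -------------------------------------------------------------

#' Convert SMILES to SELFIES
#'
#' Parses the molecule with the cheminformatics toolkit, kekulizes it, and
#' serializes the bond graph as SELFIES tokens.  The round trip
#' SMILES -> SELFIES -> SMILES yields a string canonicalizing to the same
#' molecule.
#'
#' @param smiles a valid SMILES string (neutral, single fragment, organic
#'   subset).
#' @return a SELFIES string.
#' @examples
#' \donttest{smilesToSelfies("CCO")   # "[C][C][O]"}
#' @export
smilesToSelfies <- function(smiles) {
  stopifnot(length(smiles) == 1L, nzchar(smiles))
  graph <- smilesToGraph(smiles)
  paste0(encodeGraphTokens(graph), collapse = "")
}

#' Convert SELFIES to SMILES
#'
#' Robust decoding: any token string over the supported alphabet yields a
#' valid molecule.  Control-token-only strings decode to the empty
#' molecule, returned as `""`.
#'
#' @param selfies a SELFIES string.
#' @return a SMILES string (possibly `""` for the empty molecule).
#' @export
selfiesToSmiles <- function(selfies) {
  stopifnot(length(selfies) == 1L)
  if (!nzchar(selfies)) return("")
  graph <- decodeSelfiesTokens(tokenizeSelfies(selfies))
  if (length(graph$elem) == 0L) return("")
  graphsToSmiles(list(graph))
}

#' Heavy-atom count of a SMILES string
#'
#' @param smiles a valid SMILES string.
#' @return integer number of non-hydrogen atoms.
#' @export
heavyAtoms <- function(smiles) {
  heavyAtomCount(smilesToGraph(smiles))
}
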