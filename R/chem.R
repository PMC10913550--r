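# Canonicalization, enumeration and .smi I/O (OpenBabel-backed).

#' Canonicalize SMILES strings
#'
#' Returns the backing toolkit's (OpenBabel, via ChemmineOB) canonical
#' SMILES for each input.  Canonicalization is idempotent; different SMILES
#' of the same molecule map to the same canonical string.  The canonical
#' dialect is toolkit-specific, so mixed-toolkit comparisons should always
#' go through this function.
#'
#' @param smiles character vector of SMILES strings.
#' @param onInvalid `"error"` (default) to stop on an unparseable SMILES,
#'   `"na"` to return `NA` for it.
#' @return character vector of canonical SMILES.
#' @examples
#' \donttest{canonicalizeSmiles(c("OCC", "CCO"))  # both "CCO"}
#' @export
canonicalizeSmiles <- function(smiles, onInvalid = c("error", "na")) {
  onInvalid <- match.arg(onInvalid)
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  out <- .obCanonicalPass(smiles)
  # the toolkit's aromaticity perception can depend on the input atom
  # order for borderline fused heteroaromatics, so one pass is not always
  # a fixed point; a second pass on the toolkit's own output is
  ok <- !is.na(out)
  if (any(ok)) out[ok] <- .obCanonicalPass(out[ok])
  if (onInvalid == "error" && anyNA(out))
    stop("invalid SMILES: ",
         paste(unique(smiles[is.na(out)]), collapse = ", "))
  out
}

# one batched canonicalization pass; NA for unparseable entries
.obCanonicalPass <- function(smiles) {
  bad <- is.na(smiles) | !nzchar(smiles)
  out <- rep(NA_character_, length(smiles))
  todo <- which(!bad)
  if (!length(todo)) return(out)
  res <- stripSmiOutput(obSmilesTo(smiles[todo], "CAN"))
  res <- res[nzchar(res)]
  if (length(res) == length(todo)) {
    out[todo] <- res
    return(out)
  }
  # at least one molecule failed to parse: resolve one by one
  out[todo] <- vapply(smiles[todo], function(s) {
    r <- stripSmiOutput(obSmilesTo(s, "CAN"))
    r <- r[nzchar(r)]
    if (length(r) == 1L) r else NA_character_
  }, "", USE.NAMES = FALSE)
  out
}

#' Enumerate non-canonical SMILES of a molecule
#'
#' Generates `k` distinct non-canonical SMILES of the input molecule by
#' randomly renumbering the atom order of its (kekulized) connection table
#' and writing the string back without canonicalization, so the traversal
#' starts differently each time.  Duplicates (including the canonical form)
#' are rejected and resampled, with a bounded retry budget.
#'
#' @param smiles a valid SMILES string of a molecule with at least 2 atoms.
#' @param k number of distinct variants requested.
#' @param seed integer seed; the output is deterministic per seed.
#' @param maxRetries retry budget per requested variant.
#' @return character vector of `k` non-canonical SMILES, each of which
#'   canonicalizes to `canonicalizeSmiles(smiles)`.
#' @export
enumerateSmiles <- function(smiles, k, seed = 1L, maxRetries = 50L) {
  stopifnot(length(smiles) == 1L, k >= 1L)
  canonical <- canonicalizeSmiles(smiles)
  graph <- smilesToGraph(canonical)
  na <- length(graph$elem)
  if (na < 2L)
    stop("cannot enumerate a single-atom molecule: ", smiles)
  withr::with_seed(as.integer(seed), {
    found <- character(0L)
    tries <- 0L
    budget <- maxRetries * k
    while (length(found) < k && tries < budget) {
      m <- min(k, 8L)  # draw permutations in small batches
      perms <- replicate(m, sample.int(na), simplify = FALSE)
      tries <- tries + m
      cand <- graphsToSmiles(lapply(perms, permuteGraph, graph = graph))
      cand <- setdiff(unique(cand), c(canonical, found))
      if (length(cand)) {
        # guard the closure contract: discard variants whose canonical
        # form disagrees (aromaticity-perception instability of the
        # toolkit on some exotic ring systems)
        backCan <- canonicalizeSmiles(cand, onInvalid = "na")
        cand <- cand[!is.na(backCan) & backCan == canonical]
      }
      found <- c(found, cand)
    }
    if (length(found) < k)
      stop(sprintf(paste0("could only produce %d distinct non-canonical ",
                          "SMILES for '%s' (requested %d)"),
                   length(found), smiles, k))
    found[seq_len(k)]
  })
}

#' Attach enumerations to a molecule set
#'
#' Convenience wrapper calling [enumerateSmiles()] for every molecule with
#' a per-molecule seed derived from `seed`.
#'
#' @param mset a [MoleculeSet-class].
#' @param k enumerations per molecule.
#' @param seed integer base seed.
#' @return the molecule set with filled `enumerations`.
#' @export
enumerateMoleculeSet <- function(mset, k = 4L, seed = 1L) {
  smis <- canonicalSmiles(mset)
  enums <- lapply(seq_along(smis), function(i)
    enumerateSmiles(smis[i], k = k, seed = as.integer(seed) + i))
  new("MoleculeSet", smiles = mset@smiles, selfies = mset@selfies,
      enumerations = enums)
}

#' Read molecules from a .smi file
#'
#' One SMILES per line, with an optional whitespace-separated ID column
#' (ignored).  Blank lines and lines that fail canonicalization are skipped
#' with a warning; the skip count is available as `attr(x, "skipped")`.
#'
#' @param path path to a readable .smi file.
#' @return a [MoleculeSet-class] with canonical SMILES.
#' @export
readSmi <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  raw <- sub("[ \t].*$", "", trimws(lines))
  nonblank <- raw[nzchar(raw)]
  skipped <- length(raw) - length(nonblank)
  can <- character(0L)
  if (length(nonblank)) {
    can <- canonicalizeSmiles(nonblank, onInvalid = "na")
    skipped <- skipped + sum(is.na(can))
    can <- can[!is.na(can)]
  }
  if (skipped > 0L)
    warning(sprintf("skipped %d blank or unparseable line(s) in %s",
                    skipped, path))
  out <- MoleculeSet(can)
  attr(out, "skipped") <- skipped
  out
}

#' Write molecules to a .smi file
#'
#' @param mset a [MoleculeSet-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSmi <- function(mset, path) {
  writeLines(canonicalSmiles(mset), path)
  invisible(path)
}
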