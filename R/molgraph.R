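# Internal molecular-graph plumbing on V2000 molblocks.
#
# OpenBabel (via ChemmineOB) is the parsing/writing authority for SMILES;
# molblocks are the exchange format because they carry an explicit,
# kekulized bond-order graph and a controllable atom order.

# one convertFormat call for many newline-separated SMILES
obSmilesTo <- function(smiles, to) {
  ChemmineOB::convertFormat("SMI", to, paste0(paste(smiles, collapse = "\n"),
                                              "\n"))
}

stripSmiOutput <- function(out) {
  lines <- strsplit(out, "\n", fixed = TRUE)[[1L]]
  sub("[ \t].*$", "", lines)
}

# graph: list(elem = character, bonds = integer matrix with columns a, b, order)
parseMolblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  counts <- lines[4L]
  na <- as.integer(substr(counts, 1L, 3L))
  nb <- as.integer(substr(counts, 4L, 6L))
  elem <- character(na)
  if (na > 0L)
    elem <- trimws(substr(lines[4L + seq_len(na)], 32L, 34L))
  bonds <- matrix(integer(), ncol = 3L,
                  dimnames = list(NULL, c("a", "b", "order")))
  if (nb > 0L) {
    bl <- lines[4L + na + seq_len(nb)]
    bonds <- cbind(a = as.integer(substr(bl, 1L, 3L)),
                   b = as.integer(substr(bl, 4L, 6L)),
                   order = as.integer(substr(bl, 7L, 9L)))
  }
  annotated <- any(grepl("^M  (CHG|ISO|RAD)", lines))
  list(elem = elem, bonds = bonds, annotated = annotated)
}

writeMolblock <- function(graph) {
  na <- length(graph$elem)
  nb <- nrow(graph$bonds)
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, graph$elem)
  bl <- character(0L)
  if (nb > 0L)
    bl <- sprintf("%3d%3d%3d  0  0  0  0",
                  graph$bonds[, "a"], graph$bonds[, "b"],
                  graph$bonds[, "order"])
  paste(c("", "  molae", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
          atoms, bl, "M  END", "$$$$", ""),
        collapse = "\n")
}

# split a multi-record SDF string into molblock texts
splitSdf <- function(text) {
  recs <- strsplit(text, "\\$\\$\\$\\$\n?")[[1L]]
  recs <- recs[nzchar(trimws(recs))]
  recs
}

smilesToGraph <- function(smiles) {
  sdf <- obSmilesTo(smiles, "SDF")
  if (!nzchar(trimws(sdf)))
    stop("SMILES could not be parsed: ", smiles)
  parseMolblock(sdf)
}

# batch graphs -> (non-canonical) SMILES strings, file atom order preserved
graphsToSmiles <- function(graphs) {
  sdf <- paste0(vapply(graphs, writeMolblock, ""), collapse = "")
  out <- ChemmineOB::convertFormat("SDF", "SMI", sdf)
  smis <- stripSmiOutput(out)
  smis <- smis[nzchar(smis)]
  if (length(smis) != length(graphs))
    stop("molblock to SMILES conversion dropped records")
  smis
}

# permute atom numbering of a graph (new order = old indices in `perm`)
permuteGraph <- function(graph, perm) {
  inv <- order(perm)                      # inv[old] = new index
  bonds <- graph$bonds
  if (nrow(bonds)) {
    bonds[, "a"] <- inv[bonds[, "a"]]
    bonds[, "b"] <- inv[bonds[, "b"]]
  }
  list(elem = graph$elem[perm], bonds = bonds, annotated = graph$annotated)
}

heavyAtomCount <- function(graph) sum(graph$elem != "H")
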