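# Latent-space diagnostics: utilization typing, PCA co-localization of
# enumerated molecules, Euclidean distance separation.

#' Min-max scale a latent matrix per dimension
#'
#' Affinely rescales every column to [0, 1], making utilization patterns
#' comparable across models; constant columns map to all-zeros.
#'
#' @param latents numeric matrix, molecules by latent dimensions (n >= 2).
#' @return matrix of the same shape with entries in [0, 1].
#' @export
minmaxScale <- function(latents) {
  stopifnot(is.matrix(latents), nrow(latents) >= 2L)
  rng <- apply(latents, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  out <- sweep(latents, 2L, rng[1L, ], "-")
  nz <- span > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, span[nz], "/")
  out[, !nz] <- 0
  out
}

#' Classify latent-space utilization
#'
#' Rescales the latent matrix to [0, 1] with a single (matrix-wide) min-max
#' transform -- the heatmap's one color scale -- computes per-dimension
#' variances of the scaled values and the fraction of dimensions with
#' variance below `tauLow`, and assigns one of three utilization types:
#' `posterior_collapse` when at least `collapseFrac` of dimensions are
#' low-variance (encodings nearly identical across molecules),
#' `selective` when the low-variance fraction is at least `selectiveFrac`
#' (a blend of heavily used and near-dead dimensions, indicating excess
#' latent capacity), and `high_utilization` otherwise.
#'
#' The matrix-wide scale matters: scaling each dimension separately (as
#' [minmaxScale()] does for display purposes) would amplify the residual
#' jitter of a collapsed dimension to the full [0, 1] range and erase the
#' very signal -- low variance relative to the latent space's overall
#' spread -- that distinguishes the three types.
#'
#' @param latents numeric matrix, molecules by latent dimensions.
#' @param tauLow variance threshold below which a scaled dimension counts
#'   as unused.
#' @param collapseFrac,selectiveFrac low-variance fraction thresholds for
#'   the `posterior_collapse` and `selective` labels.
#' @return a [UtilizationReport-class].
#' @export
classifyUtilization <- function(latents, tauLow = 0.01, collapseFrac = 0.9,
                                selectiveFrac = 0.05) {
  stopifnot(is.matrix(latents), nrow(latents) >= 2L)
  rng <- range(latents)
  scaled <- if (diff(rng) > 0) (latents - rng[1L]) / diff(rng) else
    latents * 0
  v <- apply(scaled, 2L, var)
  fracLow <- mean(v < tauLow)
  label <- if (fracLow >= collapseFrac) "posterior_collapse"
           else if (fracLow >= selectiveFrac) "selective"
           else "high_utilization"
  new("UtilizationReport", scaled = scaled, dimVariances = v,
      fractionLow = fracLow, label = label,
      thresholds = c(tauLow = tauLow, collapseFrac = collapseFrac,
                     selectiveFrac = selectiveFrac))
}

.backgroundStrings <- function(mset, representation) {
  if (representation == "selfies") {
    s <- selfiesStrings(mset)
    if (anyNA(s)) s <- vapply(canonicalSmiles(mset), smilesToSelfies, "")
    s
  } else canonicalSmiles(mset)
}

#' Co-localization of enumerated molecules in the latent space
#'
#' Picks `nTest` random molecules, enumerates each `kEnum` times (yielding
#' `kEnum + 1` strings per molecule), embeds them together with a random
#' background sample, fits a PCA on all embeddings jointly and reports the
#' first two components, their explained-variance percentages, and the
#' mean within-group Euclidean distances.  A latent space that reflects
#' chemical similarity maps a molecule's enumerations close together.
#'
#' @param model a trained [MolAutoencoder-class].
#' @param mset background [MoleculeSet-class] pool.
#' @param nBackground background sample size (capped at the pool size,
#'   with a warning).
#' @param nTest number of test molecules.
#' @param kEnum enumerations per test molecule.
#' @param seed integer seed for sampling and enumeration.
#' @return list with `background` / `test` coordinate data.frames,
#'   `explainedVariance` (percent per component, all components),
#'   `groupMeanDistance` (per test molecule), and
#'   `backgroundPairwiseSample` of Euclidean distances.
#' @export
enumerationColocalization <- function(model, mset, nBackground = 10000L,
                                      nTest = 3L, kEnum = 4L, seed = 1L) {
  n <- length(mset)
  if (nBackground > n) {
    warning(sprintf("background pool has %d molecules (< %d); using all",
                    n, nBackground))
    nBackground <- n
  }
  withr::with_seed(as.integer(seed), {
    bgIdx <- sample.int(n, nBackground)
    testIdx <- sample.int(n, nTest)
    # enumerate a molecule into vocabulary-covered strings, or NULL
    tryGroup <- function(can) {
      en <- tryCatch(
        enumerateSmiles(can, k = kEnum, seed = sample.int(1e9L, 1L)),
        error = function(e) NULL)
      if (is.null(en)) return(NULL)
      strings <- c(can, en)
      if (model@representation == "selfies")
        strings <- tryCatch(vapply(strings, smilesToSelfies, ""),
                            error = function(e) NULL)
      if (is.null(strings)) return(NULL)
      covered <- vapply(strings, function(s)
        all(tokenizeFor(model@representation, s) %in% model@vocab@tokens),
        TRUE)
      if (!all(covered)) return(NULL)    # out-of-vocabulary enumeration
      list(canonical = can, strings = unname(strings))
    }
    groups <- list()
    for (i in testIdx) {
      g <- tryGroup(canonicalSmiles(mset)[i])
      tries <- 0L
      while (is.null(g) && tries < 100L) {   # failed pick: resample another
        tries <- tries + 1L
        g <- tryGroup(canonicalSmiles(mset)[sample.int(n, 1L)])
      }
      if (is.null(g))
        stop("could not find enumerable test molecules covered by the ",
             "model vocabulary")
      groups[[length(groups) + 1L]] <- g
    }
    bgStrings <- .backgroundStrings(mset[bgIdx], model@representation)
    zBg <- encodeMolecules(model, bgStrings)
    zGroups <- lapply(groups, function(g) encodeMolecules(model, g$strings))
    all <- rbind(zBg, do.call(rbind, zGroups))
    pca <- prcomp(all, center = TRUE, scale. = FALSE)
    ev <- 100 * pca$sdev^2 / sum(pca$sdev^2)
    coords <- pca$x[, 1:2, drop = FALSE]
    nB <- nrow(zBg)
    gSizes <- vapply(zGroups, nrow, 0L)
    gEnd <- nB + cumsum(gSizes)
    gStart <- gEnd - gSizes + 1L
    groupCoords <- lapply(seq_along(zGroups), function(j)
      data.frame(molecule = j, coords[gStart[j]:gEnd[j], , drop = FALSE]))
    gDist <- vapply(zGroups, function(zg) mean(dist(zg)), 0)
    bgD <- as.vector(dist(zBg[sample.int(nB, min(nB, 200L)), , drop = FALSE]))
    list(background = data.frame(coords[seq_len(nB), , drop = FALSE]),
         test = do.call(rbind, groupCoords),
         testMolecules = vapply(groups, `[[`, "", "canonical"),
         explainedVariance = ev,
         groupMeanDistance = gDist,
         backgroundPairwiseSample = bgD)
  })
}

#' Latent distance separation of similar versus random molecules
#'
#' Embeds `nRandom` random molecules, computes all pairwise Euclidean
#' distances (the background histogram), and for each test group (e.g. a
#' molecule and its enumerations) the mean within-group distance.  When a
#' model's latent space reflects chemical similarity, the group means fall
#' toward the low end of the background distribution.
#'
#' @param model a trained [MolAutoencoder-class].
#' @param mset background [MoleculeSet-class] pool.
#' @param nRandom number of random background molecules.
#' @param testGroups list of character vectors of strings in the model's
#'   representation (each a group of same-molecule variants), or `NULL`.
#' @param seed integer seed.
#' @param maxPairs cap on returned pairwise distances (seeded subsample
#'   above it).
#' @return list with `pairwiseDistances`, `groupMeanDistance`, and the
#'   background median.
#' @export
distanceSeparation <- function(model, mset, nRandom = 1000L,
                               testGroups = NULL, seed = 1L,
                               maxPairs = 250000L) {
  n <- length(mset)
  if (nRandom > n) {
    warning(sprintf("pool has %d molecules (< %d); using all", n, nRandom))
    nRandom <- n
  }
  withr::with_seed(as.integer(seed), {
    idx <- sample.int(n, nRandom)
    z <- encodeMolecules(model, .backgroundStrings(mset[idx],
                                                   model@representation))
    d <- as.vector(dist(z))
    if (length(d) > maxPairs) d <- sample(d, maxPairs)
    gm <- numeric(0L)
    if (!is.null(testGroups))
      gm <- vapply(testGroups, function(g)
        mean(dist(encodeMolecules(model, g))), 0)
    list(pairwiseDistances = d, groupMeanDistance = gm,
         backgroundMedian = median(d))
  })
}
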