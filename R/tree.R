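## Tree representation of a spectrum and the recursive tree similarity.
##
## A spectrum is summarized by recursively bisecting the ppm window at the
## intensity-weighted center of mass of each region: signal-rich regions are
## refined while blank or merely noisy zones collapse to light leaves. Two
## spectra are compared level by level, combining the similarity of the
## nodes at depth k with the similarity of the subtrees at depth k + 1.
##
## Tree nodes are plain nested lists: list(lo, hi, mass, com, children)
## where children is either list() (leaf) or list(high, low) - the two
## subregions (com, hi) and (lo, com).

.isLeaf <- function(node) length(node$children) == 0L

.buildTreeRec <- function(centers, w, i1, i2, loPpm, hiPpm, depth, p,
                          minWidth) {
  if (i1 > i2) {
    ## empty region: zero mass, com at the midpoint
    return(list(lo = loPpm, hi = hiPpm, mass = 0,
                com = (loPpm + hiPpm) / 2, children = list()))
  }
  idx <- i1:i2
  mass <- sum(w[idx])
  com <- if (mass > 0) sum(w[idx] * centers[idx]) / mass
         else (loPpm + hiPpm) / 2
  node <- list(lo = loPpm, hi = hiPpm, mass = mass, com = com,
               children = list())
  stopSplit <- depth >= p@maxDepth || mass < p@minMass ||
    (hiPpm - loPpm) < minWidth || length(idx) < 2L ||
    com <= loPpm || com >= hiPpm
  if (stopSplit) return(node)
  ## centers is descending: indices with center > com come first
  nHigh <- sum(centers[idx] > com)
  high <- .buildTreeRec(centers, w, i1, i1 + nHigh - 1L, com, hiPpm,
                        depth + 1L, p, minWidth)
  low <- .buildTreeRec(centers, w, i1 + nHigh, i2, loPpm, com,
                       depth + 1L, p, minWidth)
  node$children <- list(high, low)
  node
}

#' Build the tree representation of a spectrum
#'
#' The root covers the whole window; each node splits at its
#' intensity-weighted center of mass into the high-ppm region (com, hi)
#' and the low-ppm region (lo, com), grid points being assigned to a child
#' by comparing their bin center with com (centers > com go to the high
#' side). A node becomes a leaf at `maxDepth`, when its mass falls below
#' `minMass`, or when its region is narrower than `minWidth`. Masses are
#' fractions of the spectrum's total intensity.
#'
#' No noise floor is applied here; see [spectrumTree()] for the full
#' preprocessing used by [spectrumSimilarity()].
#'
#' @param s an [NMRSpectrum-class] with positive total intensity (unit
#'   total expected; masses are computed as fractions of the total either
#'   way).
#' @param p a [TreeParams-class].
#' @return The root node: a nested list with elements `lo`, `hi`, `mass`,
#'   `com`, `children` (empty, or the high- and low-ppm child).
#' @export
#' @examples
#' s <- NMRSpectrum(c(0, 1, 0, 0, 0, 0, 1, 0), ppmMax = 10, ppmMin = 0)
#' tr <- buildTree(normalizeTotal(s), treeParams())
#' tr$com
buildTree <- function(s, p = treeParams()) {
  stopifnot(is(s, "NMRSpectrum"), is(p, "TreeParams"))
  y <- intensities(s)
  tot <- sum(y)
  if (tot <= 0)
    stop("degenerate input: zero-mass spectrum", call. = FALSE)
  w <- y / tot
  centers <- ppmGrid(s)
  lim <- ppmLimits(s)
  step <- (lim[["ppmMax"]] - lim[["ppmMin"]]) / (length(y) - 1)
  minWidth <- if (is.na(p@minWidth)) 2 * step else p@minWidth
  .buildTreeRec(centers, w, 1L, length(y), lim[["ppmMin"]], lim[["ppmMax"]],
                0L, p, minWidth)
}

#' Preprocess a spectrum and build its tree
#'
#' Normalizes to unit total intensity, zeroes every point below
#' `noiseFloor` times the maximum intensity (so blank or merely noisy zones
#' carry no mass), renormalizes, and builds the tree.
#'
#' @inheritParams buildTree
#' @return The root tree node.
#' @export
spectrumTree <- function(s, p = treeParams()) {
  s <- normalizeTotal(s)
  y <- intensities(s)
  if (p@noiseFloor > 0) {
    y[y < p@noiseFloor * max(y)] <- 0
    if (sum(y) <= 0)
      stop("degenerate input: spectrum is all noise floor", call. = FALSE)
    s <- normalizeTotal(initialize(s, intensities = y))
  }
  buildTree(s, p)
}

#' Similarity of two tree nodes
#'
#' `exp(-|com_a - com_b| / comScale) * min(mass) / max(mass)`: 1 exactly
#' when centers of mass and masses coincide, decaying with center-of-mass
#' displacement (scale `comScale` ppm) and mass imbalance. Two empty nodes
#' match perfectly (1); an empty node against a non-empty one scores 0.
#'
#' @param a,b tree nodes (see [buildTree()]).
#' @param p a [TreeParams-class]; only `comScale` is used.
#' @return similarity in [0, 1]; symmetric in its arguments.
#' @export
nodeSimilarity <- function(a, b, p = treeParams()) {
  .nodeSim(a, b, p@comScale)
}

.nodeSim <- function(a, b, alpha) {
  if (a$mass == 0 && b$mass == 0) return(1)
  if (a$mass == 0 || b$mass == 0) return(0)
  exp(-abs(a$com - b$com) / alpha) *
    (min(a$mass, b$mass) / max(a$mass, b$mass))
}

.treeSim <- function(a, b, w, alpha) {
  ns <- .nodeSim(a, b, alpha)
  aLeaf <- length(a$children) == 0L
  bLeaf <- length(b$children) == 0L
  if (aLeaf && bLeaf) return(ns)
  if (!aLeaf && !bLeaf) {
    deeper <- 0.5 * (.treeSim(a$children[[1]], b$children[[1]], w, alpha) +
                     .treeSim(a$children[[2]], b$children[[2]], w, alpha))
    return(w * ns + (1 - w) * deeper)
  }
  ## one side stopped splitting: keep comparing the leaf, as a node, against
  ## the other side's subtrees (avoids a cliff when a weak region stops
  ## splitting in one spectrum only)
  if (aLeaf) {
    deeper <- 0.5 * (.treeSim(a, b$children[[1]], w, alpha) +
                     .treeSim(a, b$children[[2]], w, alpha))
  } else {
    deeper <- 0.5 * (.treeSim(a$children[[1]], b, w, alpha) +
                     .treeSim(a$children[[2]], b, w, alpha))
  }
  w * ns + (1 - w) * deeper
}

#' Recursive similarity of two spectrum trees
#'
#' The similarity at depth k combines the node similarity at that level
#' with the similarity of the subtrees at depth k + 1:
#' `S = w * nodeSim + (1 - w) * mean(S(high children), S(low children))`;
#' two leaves compare by node similarity alone, and a leaf facing an
#' internal node is carried down and compared as a node against the deeper
#' structure. The result lies in [0, 1] and is symmetric.
#'
#' @param a,b root nodes built with identical [TreeParams-class] and
#'   identical windows.
#' @param p the [TreeParams-class] used to build them.
#' @return similarity in [0, 1].
#' @export
treeSimilarity <- function(a, b, p = treeParams()) {
  if (abs(a$lo - b$lo) > 1e-9 || abs(a$hi - b$hi) > 1e-9)
    stop("trees were built on different ppm windows", call. = FALSE)
  .treeSim(a, b, p@levelWeight, p@comScale)
}

#' Tree similarity of two spectra
#'
#' Full pipeline: normalize, apply the noise floor, build both trees
#' ([spectrumTree()]) and evaluate [treeSimilarity()].
#'
#' @param s1,s2 [NMRSpectrum-class] objects on the same grid.
#' @param p a [TreeParams-class].
#' @return similarity in [0, 1].
#' @export
#' @examples
#' p <- PredictionSet("M1", shift = c(5, 2), nProtons = c(1, 2))
#' s <- simulateSpectrum(p)
#' spectrumSimilarity(s, s)
spectrumSimilarity <- function(s1, s2, p = treeParams()) {
  .checkSameGrid(s1, s2)
  treeSimilarity(spectrumTree(s1, p), spectrumTree(s2, p), p)
}

.checkSameGrid <- function(s1, s2) {
  l1 <- ppmLimits(s1)
  l2 <- ppmLimits(s2)
  if (nPoints(s1) != nPoints(s2) || any(abs(l1 - l2) > 1e-9))
    stop("spectra must share the same ppm window and grid", call. = FALSE)
  invisible(TRUE)
}

#' Classical binning similarity (cosine on binned profiles)
#'
#' The traditional baseline: both spectra are re-binned to `nBins`
#' equal-width bins, each profile normalized to unit total, and the cosine
#' similarity of the two profiles returned.
#'
#' @param s1,s2 [NMRSpectrum-class] objects on the same window.
#' @param nBins number of bins (default 256).
#' @return cosine similarity in [0, 1].
#' @export
binningSimilarity <- function(s1, s2, nBins = 256L) {
  .checkSameGrid(s1, s2)
  v1 <- intensities(normalizeTotal(binSpectrum(s1, nBins)))
  v2 <- intensities(normalizeTotal(binSpectrum(s2, nBins)))
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    stop("degenerate input: zero-norm binned profile", call. = FALSE)
  min(1, sum(v1 * v2) / (n1 * n2))
}

#' Export a tree to a nested list / JSON
#'
#' @param tree a tree node from [buildTree()].
#' @param path optional file path; when given, the nested form is written
#'   as JSON.
#' @return The nested list (invisibly when `path` is given).
#' @export
exportTree <- function(tree, path = NULL) {
  strip <- function(nd) {
    out <- list(lo = nd$lo, hi = nd$hi, mass = nd$mass, com = nd$com)
    if (!.isLeaf(nd))
      out$children <- lapply(nd$children, strip)
    out
  }
  nested <- strip(tree)
  if (!is.null(path)) {
    jsonlite::write_json(nested, path, auto_unbox = TRUE, digits = NA)
    return(invisible(nested))
  }
  nested
}
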