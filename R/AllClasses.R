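#' @import methods
NULL

## Default observation window of the 250 MHz benchmark spectra:
## 20.693 ppm centered at 6.175 ppm, binned to 1024 points.
.DEFAULT_PPM_CENTER <- 6.175
.DEFAULT_PPM_WIDTH <- 20.693
.DEFAULT_N_POINTS <- 1024L

#' Default ppm window edges
#'
#' The default acquisition window used throughout the package: 20.693 ppm
#' wide, centered at 6.175 ppm, giving edges at 16.5215 ppm (high-frequency,
#' left) and -4.1715 ppm (right).
#'
#' @return Named numeric vector with elements `ppmMax` and `ppmMin`.
#' @export
#' @examples
#' defaultPpmWindow()
defaultPpmWindow <- function() {
  c(ppmMax = .DEFAULT_PPM_CENTER + .DEFAULT_PPM_WIDTH / 2,
    ppmMin = .DEFAULT_PPM_CENTER - .DEFAULT_PPM_WIDTH / 2)
}

#' NMRSpectrum: a 1D spectrum on a uniform ppm grid
#'
#' Holds a single one-dimensional real spectrum. The intensity vector is
#' stored in descending-ppm order (index 1 at `ppmMax`), matching the usual
#' NMR display convention; every function in the package shares this
#' orientation. Grid centers are at
#' `ppmMax - (i - 1) * (ppmMax - ppmMin) / (n - 1)`.
#'
#' @slot moleculeId character label identifying the molecule.
#' @slot ppmMax left (high-frequency) window edge in ppm.
#' @slot ppmMin right window edge in ppm.
#' @slot intensities non-negative finite intensities, descending ppm order.
#'
#' @aliases NMRSpectrum-class
#' @exportClass NMRSpectrum
setClass("NMRSpectrum",
  representation(
    moleculeId = "character",
    ppmMax = "numeric",
    ppmMin = "numeric",
    intensities = "numeric"
  )
)

setValidity("NMRSpectrum", function(object) {
  msg <- character()
  if (length(object@moleculeId) != 1L)
    msg <- c(msg, "moleculeId must be a single string")
  if (length(object@ppmMax) != 1L || length(object@ppmMin) != 1L ||
      !is.finite(object@ppmMax) || !is.finite(object@ppmMin))
    msg <- c(msg, "ppmMax and ppmMin must be single finite numbers")
  else if (object@ppmMax <= object@ppmMin)
    msg <- c(msg, "ppmMax must be greater than ppmMin")
  if (length(object@intensities) < 2L)
    msg <- c(msg, "a spectrum needs at least 2 points")
  if (anyNA(object@intensities) || any(!is.finite(object@intensities)))
    msg <- c(msg, "intensities must all be finite")
  else if (any(object@intensities < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct an NMRSpectrum
#'
#' @param intensities numeric vector of intensities in descending-ppm order.
#' @param ppmMax,ppmMin window edges in ppm (defaults: the 20.693 ppm window
#'   centered at 6.175 ppm).
#' @param moleculeId molecule label.
#' @param clipNegative if TRUE (default), negative intensities (baseline
#'   artifacts) are clipped to zero with a message reporting the count;
#'   if FALSE negative values raise a validity error.
#' @return An [NMRSpectrum-class] object.
#' @export
#' @examples
#' s <- NMRSpectrum(c(0, 1, 2, 1, 0), ppmMax = 8, ppmMin = 4, moleculeId = "m1")
#' nPoints(s)
NMRSpectrum <- function(intensities,
                        ppmMax = defaultPpmWindow()[["ppmMax"]],
                        ppmMin = defaultPpmWindow()[["ppmMin"]],
                        moleculeId = "spectrum",
                        clipNegative = TRUE) {
  intensities <- as.numeric(intensities)
  if (clipNegative && !anyNA(intensities)) {
    nneg <- sum(intensities < 0)
    if (nneg > 0) {
      message(sprintf("clipped %d negative intensities to 0 (%s)",
                      nneg, moleculeId))
      intensities[intensities < 0] <- 0
    }
  }
  new("NMRSpectrum", moleculeId = as.character(moleculeId),
      ppmMax = as.numeric(ppmMax), ppmMin = as.numeric(ppmMin),
      intensities = intensities)
}

#' PredictionSet: predicted proton groups of one molecule
#'
#' One predicted shift list for one molecule: each proton group has a
#' chemical shift (ppm), a count of equivalent protons, and zero or more
#' scalar couplings, each a pair (J in Hz, number of equivalent spin-1/2
#' partners).
#'
#' @slot moleculeId character label.
#' @slot groups data.frame with columns `shift` (ppm, numeric), `nProtons`
#'   (positive integer) and a list-column `couplings` whose elements are
#'   data.frames with columns `J` (Hz) and `nPartners` (possibly 0 rows).
#'
#' @aliases PredictionSet-class
#' @exportClass PredictionSet
setClass("PredictionSet",
  representation(moleculeId = "character", groups = "data.frame")
)

setValidity("PredictionSet", function(object) {
  msg <- character()
  g <- object@groups
  if (length(object@moleculeId) != 1L)
    msg <- c(msg, "moleculeId must be a single string")
  if (nrow(g) < 1L)
    msg <- c(msg, "at least one proton group is required")
  if (!all(c("shift", "nProtons", "couplings") %in% names(g)))
    return("groups must have columns shift, nProtons, couplings")
  if (anyNA(g$shift) || any(!is.finite(g$shift)))
    msg <- c(msg, "shifts must be finite")
  if (any(g$nProtons < 1L) || any(g$nProtons != round(g$nProtons)))
    msg <- c(msg, "nProtons must be positive integers")
  for (cp in g$couplings) {
    if (nrow(cp) == 0L) next
    if (any(cp$J < 0) || any(cp$nPartners < 1L))
      msg <- c(msg, "couplings need J >= 0 and nPartners >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PredictionSet
#'
#' @param moleculeId molecule label.
#' @param shift numeric vector of group shifts (ppm).
#' @param nProtons integer vector of equivalent-proton counts (recycled).
#' @param couplings list of coupling tables, one per group; each either NULL
#'   (no coupling) or a data.frame with columns `J` and `nPartners`.
#' @return A [PredictionSet-class].
#' @export
#' @examples
#' PredictionSet("M1", shift = c(7.26, 2.1), nProtons = c(1, 3),
#'               couplings = list(NULL, data.frame(J = 7, nPartners = 2)))
PredictionSet <- function(moleculeId, shift, nProtons = 1L, couplings = NULL) {
  n <- length(shift)
  nProtons <- as.integer(rep_len(nProtons, n))
  if (is.null(couplings)) couplings <- vector("list", n)
  couplings <- lapply(couplings, function(cp) {
    if (is.null(cp) || (is.data.frame(cp) && nrow(cp) == 0L))
      return(data.frame(J = numeric(), nPartners = integer()))
    data.frame(J = as.numeric(cp$J), nPartners = as.integer(cp$nPartners))
  })
  g <- data.frame(shift = as.numeric(shift), nProtons = nProtons)
  g$couplings <- couplings
  new("PredictionSet", moleculeId = as.character(moleculeId), groups = g)
}

#' SimilarityMatrix: experimental x simulated spectrum similarities
#'
#' Square matrix of similarities in [0, 1]; rows are experimental spectra,
#' columns simulated spectra, and both share one molecule ordering so the
#' correct match of row i is column i.
#'
#' @slot moleculeIds ordered molecule labels (row = column order).
#' @slot values numeric matrix of similarities in [0, 1].
#'
#' @aliases SimilarityMatrix-class
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  representation(moleculeIds = "character", values = "matrix")
)

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  n <- length(object@moleculeIds)
  msg <- character()
  if (nrow(v) != n || ncol(v) != n)
    msg <- c(msg, "values must be square with one row/column per moleculeId")
  if (anyNA(v) || any(v < -1e-12) || any(v > 1 + 1e-12))
    msg <- c(msg, "similarities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' BenchmarkReport: evaluation statistics for one predictor
#'
#' @slot outcomes data.frame with one row per query: `moleculeId`, `rank`
#'   (pessimistic-tie rank of the correct match), `sCorrect`, `sBest`,
#'   `absolute`, `relative` (accuracy-plane components).
#' @slot mrr mean reciprocal rank.
#' @slot cumulative fraction of correct matches within the n highest-ranked
#'   hits, n = 1..nMax.
#' @slot meanAbsolute,meanRelative means of the accuracy-plane components.
#' @slot shiftErrorBins fractions of assigned |observed - predicted| errors
#'   per interval (empty when no assignments were supplied).
#' @slot shiftErrorCumulative cumulative fractions within each deviation.
#' @slot method similarity method used ("tree" or "binning").
#'
#' @aliases BenchmarkReport-class
#' @exportClass BenchmarkReport
setClass("BenchmarkReport",
  representation(
    outcomes = "data.frame",
    mrr = "numeric",
    cumulative = "numeric",
    meanAbsolute = "numeric",
    meanRelative = "numeric",
    shiftErrorBins = "numeric",
    shiftErrorCumulative = "numeric",
    method = "character"
  )
)

setValidity("BenchmarkReport", function(object) {
  msg <- character()
  if (length(object@mrr) == 1L && (object@mrr <= 0 || object@mrr > 1))
    msg <- c(msg, "mrr must lie in (0, 1]")
  if (is.unsorted(object@cumulative))
    msg <- c(msg, "cumulative curve must be non-decreasing")
  if (length(object@shiftErrorBins) &&
      abs(sum(object@shiftErrorBins) - 1) > 1e-9)
    msg <- c(msg, "shift-error fractions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' TreeParams: parameters of the spectrum tree and its similarity
#'
#' @slot maxDepth maximum recursion depth of the bisection tree.
#' @slot minMass intensity fraction below which a node becomes a leaf.
#' @slot minWidth minimum region width in ppm (NA = 2 grid steps of the
#'   spectrum being decomposed).
#' @slot levelWeight weight w in (0,1) given to the current level's node
#'   similarity versus the deeper subtree similarity.
#' @slot comScale ppm scale of the exponential center-of-mass kernel.
#' @slot noiseFloor fraction of the maximum intensity below which points are
#'   zeroed before tree building.
#'
#' @aliases TreeParams-class
#' @exportClass TreeParams
setClass("TreeParams",
  representation(
    maxDepth = "integer", minMass = "numeric", minWidth = "numeric",
    levelWeight = "numeric", comScale = "numeric", noiseFloor = "numeric"
  )
)

setValidity("TreeParams", function(object) {
  msg <- character()
  if (object@maxDepth < 1L) msg <- c(msg, "maxDepth must be >= 1")
  if (object@levelWeight <= 0 || object@levelWeight >= 1)
    msg <- c(msg, "levelWeight must lie strictly in (0, 1)")
  if (object@comScale <= 0) msg <- c(msg, "comScale must be positive")
  if (object@minMass < 0) msg <- c(msg, "minMass must be non-negative")
  if (object@noiseFloor < 0 || object@noiseFloor >= 1)
    msg <- c(msg, "noiseFloor must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct TreeParams
#'
#' @param maxDepth maximum tree depth (default 8).
#' @param minMass leaf threshold on the node's intensity fraction
#'   (default 0.01).
#' @param minWidth minimum region width in ppm; default NA means two grid
#'   steps of the spectrum at hand.
#' @param levelWeight recursion weight w in (0,1) (default 0.5: equal weight
#'   to the current level and the deeper structure).
#' @param comScale ppm scale alpha of the exp(-|dcom|/alpha) node kernel
#'   (default 0.1).
#' @param noiseFloor fraction of max intensity zeroed before tree building
#'   (default 0.005).
#' @return A [TreeParams-class].
#' @export
#' @examples
#' treeParams(maxDepth = 6)
treeParams <- function(maxDepth = 8L, minMass = 0.01, minWidth = NA_real_,
                       levelWeight = 0.5, comScale = 0.1, noiseFloor = 0.005) {
  new("TreeParams", maxDepth = as.integer(maxDepth), minMass = minMass,
      minWidth = as.numeric(minWidth), levelWeight = levelWeight,
      comScale = comScale, noiseFloor = noiseFloor)
}

#' SimulationParams: spectrometer and lineshape settings for simulation
#'
#' @slot field spectrometer frequency in MHz; couplings are field-independent
#'   in Hz so multiplet spacings in ppm scale as J/field.
#' @slot linewidth full width at half maximum in Hz.
#' @slot lineshape "lorentzian" or "gaussian".
#' @slot ppmMax,ppmMin window edges in ppm.
#' @slot nPoints grid size.
#'
#' @aliases SimulationParams-class
#' @exportClass SimulationParams
setClass("SimulationParams",
  representation(
    field = "numeric", linewidth = "numeric", lineshape = "character",
    ppmMax = "numeric", ppmMin = "numeric", nPoints = "integer"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character()
  if (object@field <= 0) msg <- c(msg, "field must be positive")
  if (object@linewidth <= 0) msg <- c(msg, "linewidth must be positive")
  if (!object@lineshape %in% c("lorentzian", "gaussian"))
    msg <- c(msg, "lineshape must be 'lorentzian' or 'gaussian'")
  if (object@nPoints < 2L) msg <- c(msg, "nPoints must be >= 2")
  if (object@ppmMax <= object@ppmMin)
    msg <- c(msg, "ppmMax must exceed ppmMin")
  if (length(msg)) msg else TRUE
})

#' Construct SimulationParams
#'
#' @param field spectrometer frequency in MHz (default 250).
#' @param linewidth FWHM in Hz (default 1.0).
#' @param lineshape "lorentzian" (default) or "gaussian".
#' @param ppmMax,ppmMin target window edges (defaults: the standard window).
#' @param nPoints grid size (default 1024).
#' @return A [SimulationParams-class].
#' @export
#' @examples
#' simulationParams(field = 500, linewidth = 0.8)
simulationParams <- function(field = 250, linewidth = 1.0,
                             lineshape = c("lorentzian", "gaussian"),
                             ppmMax = defaultPpmWindow()[["ppmMax"]],
                             ppmMin = defaultPpmWindow()[["ppmMin"]],
                             nPoints = 1024L) {
  new("SimulationParams", field = field, linewidth = linewidth,
      lineshape = match.arg(lineshape), ppmMax = ppmMax, ppmMin = ppmMin,
      nPoints = as.integer(nPoints))
}
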