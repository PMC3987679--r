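#' Accessors for package classes
#'
#' @param object an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("moleculeId", function(object) standardGeneric("moleculeId"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))

#' @rdname accessors
#' @export
setGeneric("ppmLimits", function(object) standardGeneric("ppmLimits"))

#' @rdname accessors
#' @export
setGeneric("ppmGrid", function(object) standardGeneric("ppmGrid"))

#' @rdname accessors
#' @export
setGeneric("protonGroups", function(object) standardGeneric("protonGroups"))

#' @rdname accessors
#' @export
setGeneric("similarityValues",
           function(object) standardGeneric("similarityValues"))

#' @rdname accessors
#' @export
setGeneric("queryOutcomes", function(object) standardGeneric("queryOutcomes"))

#' @rdname accessors
#' @export
setGeneric("mrr", function(object) standardGeneric("mrr"))

#' @rdname accessors
#' @export
setGeneric("cumulativeCurve",
           function(object) standardGeneric("cumulativeCurve"))

setMethod("moleculeId", "NMRSpectrum", function(object) object@moleculeId)
setMethod("moleculeId", "PredictionSet", function(object) object@moleculeId)
setMethod("moleculeId", "SimilarityMatrix",
          function(object) object@moleculeIds)

setMethod("intensities", "NMRSpectrum", function(object) object@intensities)
setMethod("nPoints", "NMRSpectrum",
          function(object) length(object@intensities))
setMethod("ppmLimits", "NMRSpectrum",
          function(object) c(ppmMax = object@ppmMax, ppmMin = object@ppmMin))

## Descending-ppm grid centers: index 1 sits at ppmMax.
setMethod("ppmGrid", "NMRSpectrum", function(object) {
  n <- length(object@intensities)
  seq(object@ppmMax, object@ppmMin, length.out = n)
})

setMethod("protonGroups", "PredictionSet", function(object) object@groups)

setMethod("similarityValues", "SimilarityMatrix", function(object) {
  v <- object@values
  dimnames(v) <- list(object@moleculeIds, object@moleculeIds)
  v
})

setMethod("show", "NMRSpectrum", function(object) {
  cat(sprintf("NMRSpectrum '%s': %d points, %.4f .. %.4f ppm, total %.4g\n",
              object@moleculeId, length(object@intensities),
              object@ppmMax, object@ppmMin, sum(object@intensities)))
})

setMethod("show", "PredictionSet", function(object) {
  g <- object@groups
  nJ <- sum(vapply(g$couplings, nrow, 1L))
  cat(sprintf("PredictionSet '%s': %d groups, %d protons, %d couplings\n",
              object@moleculeId, nrow(g), sum(g$nProtons), nJ))
})

setMethod("show", "SimilarityMatrix", function(object) {
  n <- length(object@moleculeIds)
  cat(sprintf("SimilarityMatrix: %d x %d, diag mean %.4f, off-diag mean %.4f\n",
              n, n, mean(diag(object@values)),
              if (n > 1) mean(object@values[row(object@values) !=
                                            col(object@values)]) else NA))
})

setMethod("show", "BenchmarkReport", function(object) {
  cat(sprintf("BenchmarkReport (%s similarity): %d queries\n",
              object@method, nrow(object@outcomes)))
  cat(sprintf("  MRR                 %.4f\n", object@mrr))
  cat(sprintf("  mean abs. accuracy  %.4f\n", object@meanAbsolute))
  cat(sprintf("  mean rel. accuracy  %.4f\n", object@meanRelative))
  k <- min(4L, length(object@cumulative))
  cat(sprintf("  correct in top %d    %.1f%%\n",
              k, 100 * object@cumulative[k]))
  if (length(object@shiftErrorBins))
    cat("  shift-error fractions:",
        paste(sprintf("%.3f", object@shiftErrorBins), collapse = " "), "\n")
})
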