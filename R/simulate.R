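## First-order (weak-coupling) simulation of 1D proton spectra from
## predicted shift/coupling lists.

#' First-order multiplet stick pattern of a proton group
#'
#' Iteratively splits a unit line by each scalar coupling: n equivalent
#' spin-1/2 partners turn every line into n + 1 lines with binomial weights
#' at spacings J/field ppm (J is field-independent in Hz, so its ppm width
#' scales inversely with the spectrometer frequency). Weights sum to 1 and
#' offsets are symmetric about 0. An uncoupled group gives a single line.
#'
#' @param group group data: either one row of a [PredictionSet-class]
#'   groups table or a list with element `couplings` (data.frame with
#'   columns `J`, `nPartners`).
#' @param field spectrometer frequency in MHz.
#' @return data.frame with columns `offset` (ppm, relative to the group
#'   shift) and `weight` (fractions summing to 1).
#' @export
#' @examples
#' g <- list(couplings = data.frame(J = 7, nPartners = 2))
#' multipletPattern(g, field = 250)  # triplet, 1:2:1
multipletPattern <- function(group, field) {
  cp <- group$couplings
  if (is.list(cp) && !is.data.frame(cp)) cp <- cp[[1]]
  offset <- 0
  weight <- 1
  if (!is.null(cp) && nrow(cp)) {
    for (i in seq_len(nrow(cp))) {
      np <- cp$nPartners[i]
      spacing <- cp$J[i] / field
      k <- 0:np
      sub <- (k - np / 2) * spacing
      subw <- choose(np, k) / 2^np
      offset <- as.vector(outer(offset, sub, `+`))
      weight <- as.vector(outer(weight, subw, `*`))
    }
  }
  data.frame(offset = offset, weight = weight)
}

## Analytic mass of one unit line inside each grid bin: the lineshape's CDF
## evaluated at the bin edges (bin k spans its center +/- step/2). Binned
## spectra integrate intensity per bin, so a line keeps its mass wherever
## it falls between grid points; pointwise evaluation would make a
## narrower-than-bin line's discrete mass depend on its sub-bin position.
.lineshapeBinMass <- function(x, step, center, fwhmPpm, lineshape) {
  hiEdge <- x + step / 2
  loEdge <- x - step / 2
  if (lineshape == "lorentzian") {
    hw <- fwhmPpm / 2
    (atan((hiEdge - center) / hw) - atan((loEdge - center) / hw)) / pi
  } else {
    sd <- fwhmPpm / (2 * sqrt(2 * log(2)))
    stats::pnorm(hiEdge, center, sd) - stats::pnorm(loEdge, center, sd)
  }
}

#' Simulate a 1D spectrum from a prediction
#'
#' Sums, over all proton groups, `nProtons` times the group's first-order
#' multiplet sticks convolved with the analytic lineshape, each line's
#' intensity integrated analytically over every grid bin (CDF differences
#' at the bin edges), then normalizes to unit total intensity. Bin
#' integration keeps each line's mass independent of where it falls
#' between grid points, as in binned acquisition. Sticks outside the
#' window contribute their in-window tails only.
#'
#' @param pred a [PredictionSet-class].
#' @param params a [SimulationParams-class] (field, linewidth, lineshape,
#'   grid).
#' @return An [NMRSpectrum-class] with unit total intensity, carrying the
#'   prediction's moleculeId.
#' @export
#' @examples
#' p <- PredictionSet("M1", shift = c(5, 2), nProtons = c(1, 2))
#' s <- simulateSpectrum(p, simulationParams())
#' sum(intensities(s))
simulateSpectrum <- function(pred, params = simulationParams()) {
  stopifnot(is(pred, "PredictionSet"), is(params, "SimulationParams"))
  x <- seq(params@ppmMax, params@ppmMin, length.out = params@nPoints)
  fwhmPpm <- params@linewidth / params@field
  g <- protonGroups(pred)
  sticksPos <- numeric()
  sticksAmp <- numeric()
  for (i in seq_len(nrow(g))) {
    pat <- multipletPattern(g[i, ], params@field)
    sticksPos <- c(sticksPos, g$shift[i] + pat$offset)
    sticksAmp <- c(sticksAmp, g$nProtons[i] * pat$weight)
  }
  margin <- 50 * fwhmPpm
  inReach <- sticksPos <= params@ppmMax + margin &
    sticksPos >= params@ppmMin - margin
  if (!any(inReach))
    stop("degenerate input: every line lies farther than 50 linewidths ",
         "outside the window; simulated spectrum would be zero",
         call. = FALSE)
  step <- (params@ppmMax - params@ppmMin) / (params@nPoints - 1L)
  y <- numeric(params@nPoints)
  for (i in which(inReach))
    y <- y + sticksAmp[i] *
      .lineshapeBinMass(x, step, sticksPos[i], fwhmPpm, params@lineshape)
  s <- NMRSpectrum(y, ppmMax = params@ppmMax, ppmMin = params@ppmMin,
                   moleculeId = moleculeId(pred))
  normalizeTotal(s)
}

#' Simulate spectra for a list of predictions
#'
#' @param preds list of [PredictionSet-class].
#' @param params a [SimulationParams-class].
#' @return list of [NMRSpectrum-class], same order and ids as `preds`.
#' @export
simulateSpectra <- function(preds, params = simulationParams()) {
  lapply(preds, simulateSpectrum, params = params)
}
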