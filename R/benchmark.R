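## Similarity matrices, retrieval ranking and every evaluation statistic:
## MRR, cumulative correct-match curve, accuracy-plane decomposition and
## the traditional assigned shift-error histogram.

#' Build the experimental x simulated similarity matrix
#'
#' Entry (i, j) is the similarity between experimental spectrum i and
#' simulated spectrum j. Both lists must carry the same molecule ids in the
#' same order, so the correct match of row i is column j = i. Trees are
#' built once per spectrum and reused across the n^2 comparisons.
#'
#' @param experimental,simulated equal-length lists of
#'   [NMRSpectrum-class] on a shared grid with aligned molecule ids.
#' @param p a [TreeParams-class] (tree method) .
#' @param method "tree" (default) or "binning" (cosine baseline).
#' @param nBins bin count for the binning baseline.
#' @return A [SimilarityMatrix-class].
#' @export
similarityMatrix <- function(experimental, simulated, p = treeParams(),
                             method = c("tree", "binning"), nBins = 256L) {
  method <- match.arg(method)
  if (length(experimental) != length(simulated))
    stop("experimental and simulated lists differ in length", call. = FALSE)
  idsE <- vapply(experimental, moleculeId, "")
  idsS <- vapply(simulated, moleculeId, "")
  if (!identical(idsE, idsS)) {
    bad <- idsE[idsE != idsS]
    stop("molecule ids are not aligned; mismatches: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  n <- length(experimental)
  for (k in seq_len(n)) .checkSameGrid(experimental[[k]], simulated[[k]])
  vals <- matrix(0, n, n)
  if (method == "tree") {
    tE <- lapply(experimental, spectrumTree, p = p)
    tS <- lapply(simulated, spectrumTree, p = p)
    w <- p@levelWeight
    alpha <- p@comScale
    for (i in seq_len(n))
      for (j in seq_len(n))
        vals[i, j] <- .treeSim(tE[[i]], tS[[j]], w, alpha)
  } else {
    bE <- lapply(experimental, function(s)
      intensities(normalizeTotal(binSpectrum(s, nBins))))
    bS <- lapply(simulated, function(s)
      intensities(normalizeTotal(binSpectrum(s, nBins))))
    mE <- do.call(rbind, bE)
    mS <- do.call(rbind, bS)
    normE <- sqrt(rowSums(mE^2))
    normS <- sqrt(rowSums(mS^2))
    if (any(normE == 0) || any(normS == 0))
      stop("degenerate input: zero-norm binned profile", call. = FALSE)
    vals <- (mE %*% t(mS)) / outer(normE, normS)
    vals[vals > 1] <- 1
  }
  new("SimilarityMatrix", moleculeIds = idsE, values = vals)
}

#' @describeIn accessors per-query outcomes of a [SimilarityMatrix-class]:
#'   for each experimental row, the columns are sorted by decreasing
#'   similarity; the rank of the correct match is its position in that list,
#'   ties resolved pessimistically (the correct match takes the worst
#'   position among entries with equal similarity, i.e. rank = number of
#'   entries >= the diagonal entry). Returns a data.frame with columns
#'   `moleculeId`, `rank`, `sCorrect`, `sBest`, `absolute`, `relative`.
#' @export
setMethod("queryOutcomes", "SimilarityMatrix", function(object) {
  v <- object@values
  n <- nrow(v)
  rank <- integer(n)
  sCorrect <- numeric(n)
  sBest <- numeric(n)
  for (i in seq_len(n)) {
    sCorrect[i] <- v[i, i]
    sBest[i] <- max(v[i, ])
    rank[i] <- sum(v[i, ] >= v[i, i])
  }
  acc <- accuracyComponents(sBest, sCorrect)
  data.frame(moleculeId = object@moleculeIds, rank = rank,
             sCorrect = sCorrect, sBest = sBest,
             absolute = acc$absolute, relative = acc$relative)
})

.ranksOf <- function(x) {
  if (is.data.frame(x)) x <- x$rank
  if (!length(x)) stop("no query outcomes supplied", call. = FALSE)
  if (any(x < 1)) stop("ranks must be >= 1", call. = FALSE)
  x
}

#' Mean reciprocal rank of a set of ranks
#'
#' `MRR = (1/n) * sum_i 1/rank_i`, in (0, 1]; 1 exactly when every correct
#' match ranks first.
#'
#' @param x integer ranks, or a data.frame with a `rank` column (as from
#'   [queryOutcomes()]).
#' @return the mean reciprocal rank.
#' @export
#' @examples
#' meanReciprocalRank(c(1, 2, 4))  # 7/12
meanReciprocalRank <- function(x) {
  mean(1 / .ranksOf(x))
}

#' @describeIn accessors MRR of a [SimilarityMatrix-class] (ranks computed
#'   with the pessimistic tie rule) or stored in a
#'   [BenchmarkReport-class].
#' @export
setMethod("mrr", "SimilarityMatrix", function(object) {
  meanReciprocalRank(queryOutcomes(object))
})

setMethod("mrr", "BenchmarkReport", function(object) object@mrr)

setMethod("queryOutcomes", "BenchmarkReport", function(object)
  object@outcomes)

setMethod("cumulativeCurve", "BenchmarkReport", function(object)
  object@cumulative)

#' Cumulative correct-match curve
#'
#' Element n is the fraction of queries whose correct match lies within the
#' n highest-ranking hits; non-decreasing in n.
#'
#' @param outcomes data.frame from [queryOutcomes()] or integer ranks.
#' @param nMax curve length (default 20).
#' @return numeric vector of fractions, length `nMax`.
#' @export
cumulativeMatchCurve <- function(outcomes, nMax = 20L) {
  ranks <- .ranksOf(outcomes)
  if (nMax < 1L) stop("nMax must be >= 1", call. = FALSE)
  vapply(seq_len(nMax), function(n) mean(ranks <= n), 0)
}

#' Accuracy-plane decomposition of a query
#'
#' A query is the point (sBest, sCorrect) in the correct-match-similarity
#' vs best-match-similarity plane. Its position decomposes along two
#' orthogonal directions: the projection onto the identity line,
#' `(sBest + sCorrect)/sqrt(2)`, is the absolute prediction accuracy
#' (grows toward the extreme (1,1) where the simulation is identical to the
#' experiment); the orthogonal component, `(sBest - sCorrect)/sqrt(2)`, is
#' the relative prediction accuracy (0 exactly when the correct match is
#' the best match; lower is better).
#'
#' @param sBest,sCorrect similarities in [0, 1] with `sBest >= sCorrect`
#'   (vectorized).
#' @return list with numeric elements `absolute` and `relative`.
#' @export
#' @examples
#' accuracyComponents(0.9, 0.4)  # relative = 0.5/sqrt(2)
accuracyComponents <- function(sBest, sCorrect) {
  if (any(sCorrect > sBest + 1e-12))
    stop("invariant violation: sCorrect exceeds sBest", call. = FALSE)
  list(absolute = (sBest + sCorrect) / sqrt(2),
       relative = pmax(0, (sBest - sCorrect)) / sqrt(2))
}

#' Summary of the accuracy plane over all queries
#'
#' @param outcomes data.frame from [queryOutcomes()].
#' @return list with `meanAbsolute`, `meanRelative` and `points` (a
#'   data.frame of per-query components for plotting).
#' @export
accuracyPlaneSummary <- function(outcomes) {
  if (!nrow(outcomes)) stop("no query outcomes supplied", call. = FALSE)
  list(meanAbsolute = mean(outcomes$absolute),
       meanRelative = mean(outcomes$relative),
       points = outcomes[, c("moleculeId", "sBest", "sCorrect",
                             "absolute", "relative")])
}

#' Assigned shift-error histogram (traditional evaluation)
#'
#' Pools |observed - predicted| over every assigned pair and partitions the
#' errors on `binWidth`-ppm intervals up to `cutoff` ppm, plus an overflow
#' bin. With the defaults the bins are [0,0.1), [0.1,0.2), [0.2,0.3),
#' [0.3,0.35) and >= 0.35 ppm. Also returns the cumulative form (fraction
#' of predictions within each deviation).
#'
#' @param assignments data.frame with columns `observed` and `predicted`
#'   (ppm), e.g. from [readAssignments()].
#' @param binWidth interval width in ppm (default 0.1).
#' @param cutoff upper edge of the last finite interval in ppm
#'   (default 0.35).
#' @return list with `fractions` (sums to 1), `cumulative` (within each
#'   finite upper edge), `edges` and `counts`.
#' @export
shiftErrorHistogram <- function(assignments, binWidth = 0.1, cutoff = 0.35) {
  if (!nrow(assignments))
    stop("no assigned pairs supplied", call. = FALSE)
  err <- abs(assignments$observed - assignments$predicted)
  inner <- seq(0, cutoff, by = binWidth)
  if (inner[length(inner)] < cutoff) inner <- c(inner, cutoff)
  edges <- c(inner, Inf)
  counts <- tabulate(findInterval(err, edges), nbins = length(edges) - 1L)
  fractions <- counts / length(err)
  cumulative <- cumsum(fractions)[seq_len(length(edges) - 2L)]
  names(cumulative) <- sprintf("<%.2g", edges[2:(length(edges) - 1L)])
  list(fractions = fractions, cumulative = cumulative,
       edges = edges, counts = counts)
}

#' Run the full benchmark for one predictor
#'
#' Simulates spectra from the predictions (unless pre-simulated spectra are
#' given), builds the similarity matrix, ranks every query and assembles a
#' [BenchmarkReport-class] with MRR, the cumulative correct-match curve,
#' the accuracy-plane means and, when an assignment table is supplied, the
#' traditional shift-error histogram.
#'
#' @param experimental list of experimental [NMRSpectrum-class].
#' @param predictions list of [PredictionSet-class] aligned with
#'   `experimental` (ignored when `simulated` is given).
#' @param simulated optional pre-simulated spectra.
#' @param simParams a [SimulationParams-class].
#' @param p a [TreeParams-class].
#' @param method "tree" or "binning".
#' @param nBins bin count for the binning method.
#' @param direction "exp_to_sim" (default: experimental spectra query the
#'   simulated database) or "sim_to_exp".
#' @param nMax cumulative-curve length.
#' @param assignments optional assignment data.frame (observed/predicted).
#' @return A [BenchmarkReport-class].
#' @export
runBenchmark <- function(experimental, predictions = NULL, simulated = NULL,
                         simParams = simulationParams(), p = treeParams(),
                         method = c("tree", "binning"), nBins = 256L,
                         direction = c("exp_to_sim", "sim_to_exp"),
                         nMax = 20L, assignments = NULL) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  if (is.null(simulated)) {
    if (is.null(predictions))
      stop("supply either predictions or simulated spectra", call. = FALSE)
    simulated <- simulateSpectra(predictions, simParams)
  }
  m <- similarityMatrix(experimental, simulated, p = p, method = method,
                        nBins = nBins)
  if (direction == "sim_to_exp")
    m <- new("SimilarityMatrix", moleculeIds = m@moleculeIds,
             values = t(m@values))
  out <- queryOutcomes(m)
  nMax <- min(as.integer(nMax), nrow(out))
  plane <- accuracyPlaneSummary(out)
  hist <- if (!is.null(assignments) && nrow(assignments))
    shiftErrorHistogram(assignments) else NULL
  new("BenchmarkReport",
      outcomes = out,
      mrr = meanReciprocalRank(out),
      cumulative = cumulativeMatchCurve(out, nMax),
      meanAbsolute = plane$meanAbsolute,
      meanRelative = plane$meanRelative,
      shiftErrorBins = if (is.null(hist)) numeric() else hist$fractions,
      shiftErrorCumulative = if (is.null(hist)) numeric()
                             else as.numeric(hist$cumulative),
      method = method)
}

#' Write / read a similarity matrix as CSV
#'
#' CSV with molecule ids as header row and first column.
#'
#' @param m a [SimilarityMatrix-class].
#' @param path file path.
#' @return `path` invisibly (write) or the [SimilarityMatrix-class] (read).
#' @export
writeSimilarityMatrix <- function(m, path) {
  v <- similarityValues(m)
  df <- data.frame(molecule_id = rownames(v), v, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSimilarityMatrix
#' @export
readSimilarityMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  ids <- df[[1]]
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  new("SimilarityMatrix", moleculeIds = ids, values = unname(v))
}

#' Write a benchmark report as JSON
#'
#' @param report a [BenchmarkReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  obj <- list(
    method = report@method,
    n_queries = nrow(report@outcomes),
    mrr = report@mrr,
    mean_absolute_accuracy = report@meanAbsolute,
    mean_relative_accuracy = report@meanRelative,
    cumulative = report@cumulative,
    outcomes = report@outcomes
  )
  if (length(report@shiftErrorBins)) {
    obj$shift_error_fractions <- report@shiftErrorBins
    obj$shift_error_cumulative <- report@shiftErrorCumulative
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
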