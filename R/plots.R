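## Figure-style plots: cumulative correct-match curves with MRR legend,
## the accuracy plane, and the similarity-matrix heatmap.

#' Plot cumulative correct-match curves for one or more predictors
#'
#' Each curve shows the fraction of correct matches within the n
#' highest-ranking hits; the legend carries each predictor's MRR.
#'
#' @param reports named list of [BenchmarkReport-class] (names label the
#'   predictors).
#' @return a ggplot object.
#' @export
plotCumulativeCurves <- function(reports) {
  if (is(reports, "BenchmarkReport")) reports <- list(predictor = reports)
  if (is.null(names(reports)))
    names(reports) <- paste0("predictor", seq_along(reports))
  df <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(predictor = sprintf("%s (MRR %.3f)", nm, r@mrr),
               n = seq_along(r@cumulative), fraction = r@cumulative)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$fraction,
                                   colour = .data$predictor)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "n highest-ranking hits",
                  y = "fraction of correct matches", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot queries on the correct-match vs best-match similarity plane
#'
#' All queries lie on or above the identity line; points on the line are
#' queries whose correct match is the best match.
#'
#' @param report a [BenchmarkReport-class].
#' @return a ggplot object.
#' @export
plotAccuracyPlane <- function(report) {
  df <- report@outcomes
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sBest, y = .data$sCorrect)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "best-match similarity",
                  y = "correct-match similarity",
                  subtitle = sprintf("mean relative accuracy %.4f",
                                     report@meanRelative)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a similarity matrix
#'
#' Rows are experimental spectra, columns simulated spectra; an accurate
#' predictor concentrates high similarity on the diagonal.
#'
#' @param m a [SimilarityMatrix-class].
#' @return a ggplot object.
#' @export
plotSimilarityMatrix <- function(m) {
  v <- m@values
  n <- nrow(v)
  df <- data.frame(experimental = rep(seq_len(n), times = n),
                   simulated = rep(seq_len(n), each = n),
                   similarity = as.vector(v))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$simulated,
                                   y = .data$experimental,
                                   fill = .data$similarity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "simulated spectrum", y = "experimental spectrum") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
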