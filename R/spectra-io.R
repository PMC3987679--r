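## Reading, writing, binning and normalizing 1D spectra and the tabular
## prediction / assignment formats.

.jcampRecords <- function(lines) {
  ## collapse JCAMP label lines "##LABEL= value" into a named list; data
  ## blocks keep their following numeric lines.
  idx <- grep("^##", lines)
  recs <- list()
  for (k in seq_along(idx)) {
    i <- idx[k]
    j <- if (k < length(idx)) idx[k + 1] - 1L else length(lines)
    m <- regmatches(lines[i], regexec("^##([^=]*)=\\s*(.*)$", lines[i]))[[1]]
    if (length(m) < 3L) next
    label <- toupper(gsub("[ _-]", "", m[2]))
    recs[[label]] <- list(value = trimws(m[3]),
                          body = if (j > i) lines[(i + 1L):j] else character())
  }
  recs
}

.jcampNumeric <- function(recs, label) {
  r <- recs[[label]]
  if (is.null(r)) return(NULL)
  x <- suppressWarnings(as.numeric(r$value))
  if (is.na(x)) stop(sprintf("JCAMP record ##%s= is not numeric: '%s'",
                             label, r$value), call. = FALSE)
  x
}

#' Read a 1D spectrum from a JCAMP-DX file
#'
#' Supports the plain-text AFFN forms `##XYDATA= (X++(Y..Y))` and
#' `##XYPOINTS= (XY..XY)`. The ppm grid is taken from FIRSTX/LASTX (with
#' XFACTOR/YFACTOR scaling); intensities are re-oriented to the package's
#' descending-ppm convention if the file stores them ascending. Compressed
#' ASDF encodings (SQZ/DIF/DUP) and nD or complex data are rejected.
#'
#' @param path path to a JCAMP-DX file containing a single real 1D block.
#' @param clipNegative clip negative intensities to zero (default TRUE).
#' @return An [NMRSpectrum-class].
#' @export
readJCAMP <- function(path, clipNegative = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\$\\$.*$", "", lines)      # strip comments
  recs <- .jcampRecords(lines)
  if (!is.null(recs$DATATYPE) &&
      grepl("ND|2D", recs$DATATYPE$value, ignore.case = TRUE))
    stop("unsupported JCAMP data type: ", recs$DATATYPE$value, call. = FALSE)
  if (!is.null(recs$NTUPLES))
    stop("unsupported JCAMP form: ##NTUPLES (nD/complex data)", call. = FALSE)

  firstx <- .jcampNumeric(recs, "FIRSTX")
  lastx <- .jcampNumeric(recs, "LASTX")
  xfac <- .jcampNumeric(recs, "XFACTOR")
  yfac <- .jcampNumeric(recs, "YFACTOR")
  if (is.null(xfac)) xfac <- 1
  if (is.null(yfac)) yfac <- 1

  if (!is.null(recs$XYDATA)) {
    if (is.null(firstx) || is.null(lastx))
      stop("JCAMP format error: ##XYDATA block without ##FIRSTX=/##LASTX=",
           call. = FALSE)
    body <- recs$XYDATA$body
    stripped <- gsub("NaN|[+-]?Inf|[eE][+-]?[0-9]+", "", body)
    if (any(grepl("[A-DF-Za-df-z@%]", stripped)))
      stop("unsupported JCAMP encoding: compressed (ASDF) XYDATA",
           call. = FALSE)
    vals <- lapply(strsplit(trimws(body), "[,;[:space:]]+"), function(tok) {
      tok <- tok[nzchar(tok)]
      suppressWarnings(as.numeric(tok))
    })
    ## (X++(Y..Y)): first token of each line is an X check value
    y <- unlist(lapply(vals, function(v) v[-1]), use.names = FALSE)
    if (anyNA(y))
      stop("JCAMP format error: non-numeric value in ##XYDATA block",
           call. = FALSE)
    y <- y * yfac
    x <- seq(firstx * xfac, lastx * xfac, length.out = length(y))
  } else if (!is.null(recs$XYPOINTS)) {
    tok <- unlist(strsplit(trimws(recs$XYPOINTS$body), "[,;[:space:]]+"))
    tok <- suppressWarnings(as.numeric(tok[nzchar(tok)]))
    if (anyNA(tok) || length(tok) %% 2L != 0L)
      stop("JCAMP format error: malformed ##XYPOINTS block", call. = FALSE)
    x <- tok[seq(1, length(tok), by = 2)] * xfac
    y <- tok[seq(2, length(tok), by = 2)] * yfac
  } else {
    stop("JCAMP format error: no ##XYDATA= or ##XYPOINTS= block found",
         call. = FALSE)
  }
  npt <- .jcampNumeric(recs, "NPOINTS")
  if (!is.null(npt) && npt != length(y))
    stop(sprintf("JCAMP format error: ##NPOINTS=%d but %d values read",
                 as.integer(npt), length(y)), call. = FALSE)
  if (anyNA(y) || any(!is.finite(y)))
    stop("JCAMP format error: non-finite intensity in data block",
         call. = FALSE)
  if (x[1] < x[length(x)]) {          # ascending storage -> flip
    x <- rev(x)
    y <- rev(y)
  }
  id <- if (!is.null(recs$TITLE) && nzchar(recs$TITLE$value))
    recs$TITLE$value else basename(path)
  NMRSpectrum(y, ppmMax = x[1], ppmMin = x[length(x)], moleculeId = id,
              clipNegative = clipNegative)
}

#' Write a spectrum as JCAMP-DX
#'
#' Writes the `##XYDATA= (X++(Y..Y))` AFFN form, descending ppm.
#'
#' @param s an [NMRSpectrum-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeJCAMP <- function(s, path) {
  stopifnot(is(s, "NMRSpectrum"))
  y <- intensities(s)
  x <- ppmGrid(s)
  n <- length(y)
  hdr <- c(
    sprintf("##TITLE= %s", moleculeId(s)),
    "##JCAMP-DX= 5.00",
    "##DATA TYPE= NMR SPECTRUM",
    "##XUNITS= PPM", "##YUNITS= ARBITRARY UNITS",
    "##XFACTOR= 1", "##YFACTOR= 1",
    sprintf("##FIRSTX= %.10g", x[1]),
    sprintf("##LASTX= %.10g", x[n]),
    sprintf("##NPOINTS= %d", n),
    "##XYDATA= (X++(Y..Y))")
  rows <- split(seq_len(n), ceiling(seq_len(n) / 6))
  body <- vapply(rows, function(i) {
    paste(c(sprintf("%.10g", x[i[1]]), sprintf("%.10g", y[i])),
          collapse = " ")
  }, character(1))
  writeLines(c(hdr, body, "##END="), path)
  invisible(path)
}

#' Read a matrix of binned spectra
#'
#' Reads a plain-text numeric matrix (whitespace- or comma-separated), one
#' spectrum per row, all rows sharing the declared ppm window. Molecule ids
#' default to "row0001", "row0002", ...
#'
#' @param path path to the matrix file.
#' @param ppmMax,ppmMin declared window edges (defaults: standard window).
#' @param moleculeIds optional character vector of row labels.
#' @return A list of [NMRSpectrum-class] objects.
#' @export
readSpectrumMatrix <- function(path,
                               ppmMax = defaultPpmWindow()[["ppmMax"]],
                               ppmMin = defaultPpmWindow()[["ppmMin"]],
                               moleculeIds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("matrix format error: empty file", call. = FALSE)
  rows <- lapply(strsplit(trimws(lines), "[,[:space:]]+"), function(tok) {
    suppressWarnings(as.numeric(tok[nzchar(tok)]))
  })
  len <- vapply(rows, length, 1L)
  if (length(unique(len)) != 1L)
    stop("matrix format error: ragged rows (first offender row ",
         which(len != len[1])[1], ")", call. = FALSE)
  if (any(vapply(rows, anyNA, TRUE)))
    stop("matrix format error: non-numeric value (first offender row ",
         which(vapply(rows, anyNA, TRUE))[1], ")", call. = FALSE)
  if (is.null(moleculeIds))
    moleculeIds <- sprintf("row%04d", seq_along(rows))
  mapply(function(y, id) {
    NMRSpectrum(y, ppmMax = ppmMax, ppmMin = ppmMin, moleculeId = id)
  }, rows, moleculeIds, SIMPLIFY = FALSE)
}

#' Write spectra as a plain-text matrix
#'
#' @param spectra list of [NMRSpectrum-class] sharing one grid.
#' @param path output path; one whitespace-separated row per spectrum.
#' @return `path`, invisibly.
#' @export
writeSpectrumMatrix <- function(spectra, path) {
  lines <- vapply(spectra, function(s)
    paste(sprintf("%.10g", intensities(s)), collapse = " "), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Re-bin a spectrum
#'
#' Sums input intensities into `nOut` equal-width bins spanning the window.
#' A point belongs to bin k when its ppm center falls in the half-open bin
#' \code{[edge_k, edge_k+1)} counted from the high-ppm edge; the final bin is
#' closed. Total intensity is conserved exactly.
#'
#' @param s an [NMRSpectrum-class].
#' @param nOut number of output bins, `2 <= nOut <= nPoints(s)`.
#' @return A binned [NMRSpectrum-class] whose grid points are the bin
#'   centers.
#' @export
binSpectrum <- function(s, nOut) {
  stopifnot(is(s, "NMRSpectrum"))
  nOut <- as.integer(nOut)
  if (nOut < 2L) stop("nOut must be at least 2", call. = FALSE)
  n <- nPoints(s)
  if (nOut > n) stop("nOut must not exceed nPoints(s)", call. = FALSE)
  lim <- ppmLimits(s)
  width <- (lim[["ppmMax"]] - lim[["ppmMin"]]) / nOut
  ## bin index counted from the high-ppm edge, half-open, last bin closed
  k <- floor((lim[["ppmMax"]] - ppmGrid(s)) / width) + 1L
  k[k > nOut] <- nOut
  y <- vapply(seq_len(nOut), function(b) sum(intensities(s)[k == b]), 0)
  centers <- lim[["ppmMax"]] - (seq_len(nOut) - 0.5) * width
  NMRSpectrum(y, ppmMax = centers[1], ppmMin = centers[nOut],
              moleculeId = moleculeId(s))
}

#' Normalize a spectrum to unit total intensity
#'
#' Divides by the total intensity; the last point absorbs floating-point
#' rounding so the sum is exactly 1. Idempotent.
#'
#' @param s an [NMRSpectrum-class] with positive total intensity.
#' @return The normalized [NMRSpectrum-class].
#' @export
normalizeTotal <- function(s) {
  stopifnot(is(s, "NMRSpectrum"))
  y <- intensities(s)
  tot <- sum(y)
  if (tot <= 0)
    stop("degenerate input: spectrum has zero total intensity", call. = FALSE)
  y <- y / tot
  n <- length(y)
  y[n] <- 1 - sum(y[-n])
  if (y[n] < 0) y[n] <- 0          # guard against tiny negative rounding
  initialize(s, intensities = y)
}

.parseCouplingField <- function(txt, line) {
  txt <- trimws(txt)
  if (!nzchar(txt))
    return(data.frame(J = numeric(), nPartners = integer()))
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  out <- lapply(parts, function(p) {
    kv <- strsplit(trimws(p), ":", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop(sprintf("prediction format error at line %d: bad coupling '%s'",
                   line, p), call. = FALSE)
    J <- suppressWarnings(as.numeric(kv[1]))
    np <- suppressWarnings(as.integer(kv[2]))
    if (is.na(J) || is.na(np) || J < 0 || np < 1)
      stop(sprintf("prediction format error at line %d: bad coupling '%s'",
                   line, p), call. = FALSE)
    data.frame(J = J, nPartners = np)
  })
  do.call(rbind, out)
}

#' Read per-molecule shift predictions
#'
#' Reads the CSV prediction dialect: columns `molecule_id, shift_ppm,
#' n_protons, couplings`, where `couplings` is empty or a ;-separated list
#' of `J:nPartners` pairs (J in Hz). Lines sharing a molecule_id are merged
#' into one [PredictionSet-class] in file order, even when non-adjacent.
#'
#' @param path path to the prediction table (header optional).
#' @return A list of [PredictionSet-class], in order of first appearance.
#' @export
readPredictions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  rows <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    f <- trimws(f)
    if (i == which(keep)[1] && identical(tolower(f[1]), "molecule_id"))
      next                                   # header line
    if (length(f) < 3L)
      stop(sprintf("prediction format error at line %d: expected >= 3 fields",
                   i), call. = FALSE)
    shift <- suppressWarnings(as.numeric(f[2]))
    np <- suppressWarnings(as.integer(f[3]))
    if (is.na(shift) || !is.finite(shift))
      stop(sprintf("prediction format error at line %d: bad shift '%s'",
                   i, f[2]), call. = FALSE)
    if (is.na(np) || np < 1L)
      stop(sprintf("prediction format error at line %d: bad n_protons '%s'",
                   i, f[3]), call. = FALSE)
    cp <- .parseCouplingField(if (length(f) >= 4L) f[4] else "", i)
    rows[[length(rows) + 1L]] <- list(id = f[1], shift = shift, np = np,
                                      cp = cp)
  }
  if (!length(rows))
    stop("prediction format error: no data lines", call. = FALSE)
  ids <- vapply(rows, `[[`, "", "id")
  lapply(unique(ids), function(id) {
    sel <- rows[ids == id]
    PredictionSet(id,
                  shift = vapply(sel, `[[`, 0, "shift"),
                  nProtons = vapply(sel, `[[`, 0L, "np"),
                  couplings = lapply(sel, `[[`, "cp"))
  })
}

#' Write predictions in the package's CSV dialect
#'
#' @param preds list of [PredictionSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(preds, path) {
  lines <- "molecule_id,shift_ppm,n_protons,couplings"
  for (p in preds) {
    g <- protonGroups(p)
    for (i in seq_len(nrow(g))) {
      cp <- g$couplings[[i]]
      cptxt <- if (nrow(cp))
        paste(sprintf("%.6g:%d", cp$J, cp$nPartners), collapse = ";") else ""
      lines <- c(lines, sprintf("%s,%.6g,%d,%s", moleculeId(p),
                                g$shift[i], g$nProtons[i], cptxt))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an assignment table
#'
#' Reads assigned (observed, predicted) shift pairs used by the traditional
#' shift-error evaluation: CSV columns `molecule_id, observed_ppm,
#' predicted_ppm`.
#'
#' @param path path to the assignment CSV (header optional).
#' @return data.frame with columns `moleculeId`, `observed`, `predicted`.
#' @export
readAssignments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = FALSE, strip.white = TRUE,
                        col.names = c("moleculeId", "observed", "predicted"),
                        colClasses = c("character", "character", "character"))
  if (nrow(df) && identical(tolower(df$moleculeId[1]), "molecule_id"))
    df <- df[-1, , drop = FALSE]
  obs <- suppressWarnings(as.numeric(df$observed))
  pred <- suppressWarnings(as.numeric(df$predicted))
  if (anyNA(obs) || anyNA(pred))
    stop("assignment format error: non-numeric shift", call. = FALSE)
  data.frame(moleculeId = df$moleculeId, observed = obs, predicted = pred,
             row.names = NULL)
}

#' Write an assignment table
#'
#' @param assignments data.frame with columns moleculeId, observed,
#'   predicted.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAssignments <- function(assignments, path) {
  lines <- c("molecule_id,observed_ppm,predicted_ppm",
             sprintf("%s,%.6g,%.6g", assignments$moleculeId,
                     assignments$observed, assignments$predicted))
  writeLines(lines, path)
  invisible(path)
}
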