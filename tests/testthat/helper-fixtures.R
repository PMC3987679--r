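# shared fixture builders; everything is generated in code

# spectrum with unit-mass delta peaks at given ppm positions (snapped to
# the nearest grid point), on an n-point window
deltaSpectrum <- function(peaks, weights = NULL, ppmMax = 10, ppmMin = 0,
                          n = 101, id = "synthetic") {
  if (is.null(weights)) weights <- rep(1, length(peaks))
  grid <- seq(ppmMax, ppmMin, length.out = n)
  y <- numeric(n)
  for (i in seq_along(peaks)) {
    j <- which.min(abs(grid - peaks[i]))
    y[j] <- y[j] + weights[i]
  }
  NMRSpectrum(y, ppmMax = ppmMax, ppmMin = ppmMin, moleculeId = id)
}

randomSpectrum <- function(n = 256, ppmMax = 12, ppmMin = 0, id = "rand") {
  NMRSpectrum(stats::runif(n), ppmMax = ppmMax, ppmMin = ppmMin,
              moleculeId = id)
}

# minimal JCAMP-DX fixture text (X++(Y..Y) form)
jcampText <- function(y, firstx = 10, lastx = 3, title = "fixture") {
  n <- length(y)
  x <- seq(firstx, lastx, length.out = n)
  c(sprintf("##TITLE= %s", title),
    "##JCAMP-DX= 5.00",
    "##DATA TYPE= NMR SPECTRUM",
    "##XUNITS= PPM", "##YUNITS= ARBITRARY UNITS",
    sprintf("##FIRSTX= %g", firstx),
    sprintf("##LASTX= %g", lastx),
    sprintf("##NPOINTS= %d", n),
    "##XYDATA= (X++(Y..Y))",
    paste(c(sprintf("%g", x[1]), sprintf("%g", y)), collapse = " "),
    "##END=")
}

# walk a tree, applying fn(node) at every node
walkTree <- function(node, fn) {
  fn(node)
  for (ch in node$children) walkTree(ch, fn)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
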