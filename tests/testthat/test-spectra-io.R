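test_that("JCAMP metadata passes through and orientation is normalized", {
  path <- withr::local_tempfile(fileext = ".jdx")

  writeLines(jcampText(1:8, firstx = 10, lastx = 3), path)
  s <- readJCAMP(path)
  expect_equal(unname(ppmLimits(s)), c(10, 3))
  expect_equal(nPoints(s), 8L)
  expect_equal(intensities(s), as.numeric(1:8))

  # ascending storage must re-orient to descending ppm
  writeLines(jcampText(8:1, firstx = 3, lastx = 10), path)
  s2 <- readJCAMP(path)
  expect_equal(unname(ppmLimits(s2)), c(10, 3))
  expect_equal(intensities(s2), as.numeric(1:8))
})

test_that("JCAMP rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".jdx")

  txt <- jcampText(c(1, 2, NaN, 4, 5, 6, 7, 8))
  writeLines(txt, path)
  expect_error(readJCAMP(path), "non-finite|non-numeric")

  writeLines(grep("FIRSTX", jcampText(1:8), invert = TRUE, value = TRUE),
             path)
  expect_error(readJCAMP(path), "FIRSTX")

  writeLines(c("##TITLE= x", "##END="), path)
  expect_error(readJCAMP(path), "XYDATA|XYPOINTS")
})

test_that("JCAMP write/read round-trips intensities", {
  path <- withr::local_tempfile(fileext = ".jdx")
  set.seed(11)
  s <- randomSpectrum(n = 512, id = "rt")
  writeJCAMP(s, path)
  s2 <- readJCAMP(path)
  expect_equal(intensities(s2), intensities(s), tolerance = 1e-6)
  expect_equal(unname(ppmLimits(s2)), unname(ppmLimits(s)),
               tolerance = 1e-9)
})

test_that("negative intensities are clipped on load with a message", {
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(jcampText(c(1, -2, 3, -4, 5, 6, 7, 8)), path)
  expect_message(s <- readJCAMP(path), "clipped 2")
  expect_true(all(intensities(s) >= 0))
})

test_that("spectrum matrix reader handles shapes and errors", {
  path <- withr::local_tempfile(fileext = ".txt")

  m <- matrix(runif(3 * 64), nrow = 3)
  writeLines(apply(m, 1, paste, collapse = " "), path)
  sp <- readSpectrumMatrix(path, ppmMax = 10, ppmMin = 2)
  expect_length(sp, 3L)
  expect_equal(vapply(sp, moleculeId, ""), sprintf("row%04d", 1:3))
  expect_equal(intensities(sp[[2]]), m[2, ])

  # 1 x 4 with window 10 -> 2 ppm: grid spacing 8/3
  writeLines("1 2 3 4", path)
  s <- readSpectrumMatrix(path, ppmMax = 10, ppmMin = 2)[[1]]
  expect_equal(diff(ppmGrid(s))[1], -8 / 3)

  writeLines(c("1 2 3", "1 2"), path)
  expect_error(readSpectrumMatrix(path, 10, 2), "ragged rows")

  writeLines(character(), path)
  expect_error(readSpectrumMatrix(path, 10, 2), "empty")
})

test_that("binning conserves total intensity and sums per bin", {
  s <- NMRSpectrum(rep(1, 8), ppmMax = 8, ppmMin = 0)
  b <- binSpectrum(s, 4)
  expect_equal(intensities(b), rep(2, 4))

  # conservation property over random spectra and bin counts
  set.seed(42)
  for (rep in 1:20) {
    s <- randomSpectrum(n = 1024)
    nOut <- sample(c(2L, 7L, 64L, 256L, 1000L, 1024L), 1L)
    b <- binSpectrum(s, nOut)
    expect_equal(sum(intensities(b)), sum(intensities(s)),
                 tolerance = 1e-9)
    expect_equal(nPoints(b), nOut)
  }

  expect_error(binSpectrum(s, 1), "at least 2")
  expect_error(binSpectrum(s, 2000), "not exceed")
})

test_that("normalizeTotal yields exact unit mass and is idempotent", {
  s <- NMRSpectrum(c(2, 2, 4), ppmMax = 3, ppmMin = 1)
  n1 <- normalizeTotal(s)
  expect_identical(intensities(n1), c(0.25, 0.25, 0.5))
  expect_identical(sum(intensities(n1)), 1)
  n2 <- normalizeTotal(n1)
  expect_identical(intensities(n2), intensities(n1))
  expect_error(normalizeTotal(NMRSpectrum(c(0, 0, 0), 3, 1)),
               "degenerate")
})

test_that("prediction reader parses groups, couplings and merges blocks", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("molecule_id,shift_ppm,n_protons,couplings",
               "M1,7.26,1,",
               "M2,1.0,2,3.5:1",
               "M1,2.1,3,7.0:2"), path)
  preds <- readPredictions(path)
  expect_length(preds, 2L)
  expect_equal(vapply(preds, moleculeId, ""), c("M1", "M2"))
  g1 <- protonGroups(preds[[1]])
  expect_equal(nrow(g1), 2L)                 # non-adjacent blocks merged
  expect_equal(sum(g1$nProtons), 4L)
  expect_equal(nrow(g1$couplings[[1]]), 0L)  # empty coupling field
  expect_equal(g1$couplings[[2]]$J, 7.0)
  expect_equal(g1$couplings[[2]]$nPartners, 2L)

  writeLines("M1,5.0,-2,", path)
  expect_error(readPredictions(path), "line 1")
  writeLines("M1,5.0,1,badJ", path)
  expect_error(readPredictions(path), "coupling")
})

test_that("prediction and assignment tables round-trip through files", {
  pdir <- withr::local_tempdir()
  preds <- list(
    PredictionSet("A", shift = c(1.2, 6.8), nProtons = c(3, 1),
                  couplings = list(data.frame(J = 7, nPartners = 2), NULL)),
    PredictionSet("B", shift = 4.4, nProtons = 2))
  pf <- file.path(pdir, "preds.csv")
  writePredictions(preds, pf)
  back <- readPredictions(pf)
  expect_equal(vapply(back, moleculeId, ""), c("A", "B"))
  expect_equal(protonGroups(back[[1]])$shift, c(1.2, 6.8))
  expect_equal(protonGroups(back[[1]])$couplings[[1]]$J, 7)

  asg <- data.frame(moleculeId = c("A", "A", "B"),
                    observed = c(1.2, 6.8, 4.4),
                    predicted = c(1.25, 6.78, 4.1))
  af <- file.path(pdir, "asg.csv")
  writeAssignments(asg, af)
  expect_equal(readAssignments(af), asg)
})
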