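simMatrix <- function(values, ids = sprintf("m%02d", seq_len(nrow(values)))) {
  new("SimilarityMatrix", moleculeIds = ids, values = values)
}

test_that("ranks use the pessimistic tie rule", {
  m <- simMatrix(rbind(c(0.2, 0.9, 0.5),
                       c(0.1, 0.6, 0.3),
                       c(0.4, 0.4, 0.8)))
  out <- queryOutcomes(m)
  expect_equal(out$rank[1], 3L)     # 0.2 is the worst of its row
  expect_equal(out$rank[2], 1L)
  expect_equal(out$sBest, c(0.9, 0.6, 0.8))
  expect_equal(out$sCorrect, c(0.2, 0.6, 0.8))

  tied <- simMatrix(rbind(c(0.5, 0.5), c(0.2, 0.7)))
  expect_equal(queryOutcomes(tied)$rank, c(2L, 1L))
})

test_that("ranks equal the count-of->=-diagonal oracle on random matrices", {
  set.seed(31)
  for (rep in 1:5) {
    v <- matrix(runif(20 * 20), 20, 20)
    out <- queryOutcomes(simMatrix(v))
    oracle <- vapply(1:20, function(i) sum(v[i, ] >= v[i, i]), 0L)
    expect_identical(out$rank, oracle)
  }
})

test_that("MRR evaluates the reciprocal-rank mean", {
  expect_equal(meanReciprocalRank(c(1, 1, 1, 1)), 1.0)
  expect_equal(meanReciprocalRank(c(1, 2, 4)), 7 / 12)
  expect_equal(meanReciprocalRank(rep(10, 6)), 0.1)
  expect_error(meanReciprocalRank(integer()), "no query outcomes")
})

test_that("cumulative match curve counts ranks within n", {
  expect_equal(cumulativeMatchCurve(c(1L, 2L, 3L), nMax = 3L),
               c(1, 2, 3) / 3)
  expect_equal(cumulativeMatchCurve(rep(1L, 5), nMax = 4L), rep(1, 4))
  set.seed(5)
  ranks <- sample(1:15, 40, replace = TRUE)
  curve <- cumulativeMatchCurve(ranks, nMax = 15L)
  oracle <- vapply(1:15, function(n) sum(ranks <= n) / 40, 0)
  expect_equal(curve, oracle)
  expect_true(all(diff(curve) >= 0))
})

test_that("accuracy components decompose the similarity plane", {
  expect_equal(accuracyComponents(1, 1),
               list(absolute = sqrt(2), relative = 0))
  expect_equal(accuracyComponents(0.9, 0.9)$relative, 0)
  expect_equal(accuracyComponents(0.9, 0.4)$relative, 0.5 / sqrt(2))
  expect_equal(accuracyComponents(0.9, 0.4)$absolute, 1.3 / sqrt(2))
  expect_error(accuracyComponents(0.4, 0.9), "invariant")
})

test_that("accuracy plane summary averages per-query components", {
  set.seed(17)
  v <- matrix(runif(100 * 100), 100, 100)
  out <- queryOutcomes(simMatrix(v, sprintf("m%03d", 1:100)))
  sm <- accuracyPlaneSummary(out)
  expect_equal(sm$meanRelative,
               mean((out$sBest - out$sCorrect) / sqrt(2)))
  expect_equal(sm$meanAbsolute,
               mean((out$sBest + out$sCorrect) / sqrt(2)))
  # identity predictor: diagonal dominates, relative accuracy exactly 0
  ident <- diag(100) * 0.5 + 0.25
  outI <- queryOutcomes(simMatrix(ident, sprintf("m%03d", 1:100)))
  expect_equal(accuracyPlaneSummary(outI)$meanRelative, 0)
})

test_that("shift-error histogram partitions errors on 0.1 ppm intervals", {
  asg <- function(err) data.frame(moleculeId = "m", observed = err,
                                  predicted = 0)
  h <- shiftErrorHistogram(asg(c(0.05, 0.12, 0.40)))
  expect_equal(h$fractions, c(1, 1, 0, 0, 1) / 3)
  expect_equal(sum(h$fractions), 1)
  h0 <- shiftErrorHistogram(asg(rep(0, 4)))
  expect_equal(h0$fractions, c(1, 0, 0, 0, 0))

  set.seed(3)
  err <- runif(1000, 0, 0.6)
  h2 <- shiftErrorHistogram(asg(err))
  oracle <- c(mean(err < 0.1), mean(err >= 0.1 & err < 0.2),
              mean(err >= 0.2 & err < 0.3), mean(err >= 0.3 & err < 0.35),
              mean(err >= 0.35))
  expect_equal(h2$fractions, oracle)
  expect_equal(unname(h2$cumulative),
               cumsum(oracle)[1:4])
  expect_error(shiftErrorHistogram(data.frame(observed = numeric(),
                                              predicted = numeric())),
               "no assigned pairs")
})

test_that("identity predictions give a diagonal-dominant matrix", {
  cfg <- synthConfig(nMolecules = 10, sigmaPred = 0, sigmaExpNoise = 0,
                     seed = 9)
  truth <- generateTruth(cfg)
  spectra <- simulateSpectra(truth)
  m <- similarityMatrix(spectra, spectra)
  v <- similarityValues(m)
  expect_equal(unname(diag(v)), rep(1, 10))
  for (i in 1:10)
    expect_equal(which.max(v[i, ]), i, ignore_attr = TRUE)
  out <- queryOutcomes(m)
  expect_equal(out$rank, rep(1L, 10))
  # 1x1 matrix edge case
  m1 <- similarityMatrix(spectra[1], spectra[1])
  expect_equal(unname(similarityValues(m1)[1, 1]), 1)
})

test_that("misaligned molecule ids are rejected with the offenders named", {
  cfg <- synthConfig(nMolecules = 3, seed = 2)
  sp <- simulateSpectra(generateTruth(cfg))
  swapped <- sp[c(2, 1, 3)]
  expect_error(similarityMatrix(sp, swapped), "mol0001")
  expect_error(similarityMatrix(sp, sp[1:2]), "length")
})

test_that("runBenchmark assembles a coherent report either direction", {
  d <- makeBenchmarkDataset(synthConfig(nMolecules = 12, sigmaPred = 0.05,
                                        seed = 21))
  r <- runBenchmark(d$experimental, d$predictions,
                    assignments = d$assignments, nMax = 12L)
  expect_s4_class(r, "BenchmarkReport")
  expect_equal(r@mrr, meanReciprocalRank(r@outcomes))
  expect_equal(r@cumulative[length(r@cumulative)], 1)
  expect_equal(sum(r@shiftErrorBins), 1)
  expect_equal(r@meanRelative, mean(r@outcomes$relative))

  rRev <- runBenchmark(d$experimental, d$predictions,
                       direction = "sim_to_exp")
  expect_s4_class(rRev, "BenchmarkReport")

  # no assignments: histogram omitted, no error
  r2 <- runBenchmark(d$experimental, d$predictions)
  expect_length(r2@shiftErrorBins, 0L)
})

test_that("similarity matrices and reports round-trip through files", {
  d <- makeBenchmarkDataset(synthConfig(nMolecules = 5, seed = 4))
  m <- similarityMatrix(d$experimental, simulateSpectra(d$predictions))
  dir <- withr::local_tempdir()
  mf <- file.path(dir, "m.csv")
  writeSimilarityMatrix(m, mf)
  m2 <- readSimilarityMatrix(mf)
  expect_equal(moleculeId(m2), moleculeId(m))
  expect_equal(similarityValues(m2), similarityValues(m),
               tolerance = 1e-12)

  r <- runBenchmark(d$experimental, d$predictions,
                    assignments = d$assignments)
  rf <- file.path(dir, "report.json")
  writeReport(r, rf)
  back <- jsonlite::read_json(rf)
  expect_equal(back$mrr, r@mrr)
  expect_equal(back$n_queries, 5L)
  expect_length(back$shift_error_fractions, 5L)
})
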