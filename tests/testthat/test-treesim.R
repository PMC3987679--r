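test_that("tree splits at the center of mass with conserved masses", {
  # two equal peaks at 3 and 7 ppm: root com 5, children 0.5/0.5
  s <- normalizeTotal(deltaSpectrum(c(3, 7)))
  tr <- buildTree(s, treeParams())
  expect_equal(tr$com, 5.0)
  expect_equal(tr$mass, 1.0)
  expect_length(tr$children, 2L)
  expect_equal(tr$children[[1]]$mass, 0.5)   # high-ppm child
  expect_equal(tr$children[[2]]$mass, 0.5)
  expect_equal(tr$children[[1]]$com, 7.0)
  expect_equal(tr$children[[2]]$com, 3.0)
})

test_that("a delta peak keeps a constant com down its path", {
  s <- normalizeTotal(deltaSpectrum(6.0))
  tr <- buildTree(s, treeParams())
  node <- tr
  while (length(node$children)) {
    expect_equal(node$com, 6.0)
    # the child holding the mass is on the low side of its own com split
    node <- if (node$children[[1]]$mass > 0) node$children[[1]]
            else node$children[[2]]
  }
  expect_equal(node$com, 6.0)
})

test_that("tree structure is internally consistent on random spectra", {
  set.seed(7)
  for (rep in 1:5) {
    s <- normalizeTotal(randomSpectrum(n = 1024))
    tr <- buildTree(s, treeParams())
    walkTree(tr, function(nd) {
      expect_true(nd$lo <= nd$com && nd$com <= nd$hi)
      expect_gte(nd$mass, 0)
      if (length(nd$children)) {
        expect_equal(nd$children[[1]]$mass + nd$children[[2]]$mass,
                     nd$mass, tolerance = 1e-9)
        # children tile the parent region exactly at the com
        expect_identical(nd$children[[1]]$hi, nd$hi)
        expect_identical(nd$children[[1]]$lo, nd$com)
        expect_identical(nd$children[[2]]$hi, nd$com)
        expect_identical(nd$children[[2]]$lo, nd$lo)
      }
    })
    # leaf masses sum to the root mass
    leafSum <- 0
    walkTree(tr, function(nd) {
      if (!length(nd$children)) leafSum <<- leafSum + nd$mass
    })
    expect_equal(leafSum, tr$mass, tolerance = 1e-9)
  }
  expect_error(buildTree(NMRSpectrum(c(0, 0, 0), 3, 1), treeParams()),
               "degenerate")
})

test_that("node similarity has its closed-form values", {
  mk <- function(mass, com) list(lo = 0, hi = 10, mass = mass, com = com,
                                 children = list())
  p <- treeParams()            # comScale 0.1
  expect_equal(nodeSimilarity(mk(0.3, 5), mk(0.3, 5), p), 1.0)
  expect_equal(nodeSimilarity(mk(0.3, 5), mk(0.3, 5.1), p), exp(-1))
  expect_equal(nodeSimilarity(mk(0.2, 5), mk(0.1, 5), p), 0.5)
  # empty-vs-empty matches, empty-vs-occupied does not
  expect_equal(nodeSimilarity(mk(0, 5), mk(0, 2), p), 1.0)
  expect_equal(nodeSimilarity(mk(0, 5), mk(0.2, 5), p), 0.0)
  # symmetric
  expect_equal(nodeSimilarity(mk(0.2, 4.7), mk(0.05, 5.3), p),
               nodeSimilarity(mk(0.05, 5.3), mk(0.2, 4.7), p))
})

test_that("tree similarity is a bounded symmetric self-identical measure", {
  set.seed(13)
  p <- treeParams()
  for (rep in 1:25) {
    s1 <- normalizeTotal(randomSpectrum())
    s2 <- normalizeTotal(randomSpectrum())
    t1 <- buildTree(s1, p)
    t2 <- buildTree(s2, p)
    s12 <- treeSimilarity(t1, t2, p)
    expect_gte(s12, 0)
    expect_lte(s12, 1)
    expect_equal(s12, treeSimilarity(t2, t1, p), tolerance = 1e-12)
    expect_equal(treeSimilarity(t1, t1, p), 1.0)
  }
  tOther <- buildTree(normalizeTotal(randomSpectrum(ppmMax = 9)), p)
  expect_error(treeSimilarity(t1, tOther, p), "window")
})

test_that("similarity decays with peak displacement", {
  p <- treeParams()
  base <- simulateSpectrum(PredictionSet("m", 5.0, 1L))
  deltas <- c(0, 0.02, 0.05, 0.1, 0.5, 2.0)
  sims <- vapply(deltas, function(d) {
    shifted <- simulateSpectrum(PredictionSet("m", 5.0 + d, 1L))
    spectrumSimilarity(base, shifted, p)
  }, 0)
  expect_equal(sims[1], 1.0)
  expect_true(all(diff(sims) <= 1e-12))   # non-increasing in displacement
  expect_gt(sims[3], sims[6])             # 0.05 ppm beats 5x larger shifts
})

test_that("a slightly displaced multiplet hurts the tree measure less than
           binning", {
  # 3-multiplet spectrum; one multiplet displaced by 0.04 ppm
  mk <- function(s2) PredictionSet("m", shift = c(1.8, s2, 7.4),
    nProtons = c(3L, 1L, 2L),
    couplings = list(data.frame(J = 7, nPartners = 2), NULL,
                     data.frame(J = 8, nPartners = 1)))
  a <- simulateSpectrum(mk(4.60))
  b <- simulateSpectrum(mk(4.64))
  expect_gt(spectrumSimilarity(a, b), binningSimilarity(a, b, 256L))
})

test_that("binning similarity equals the brute-force cosine", {
  set.seed(23)
  for (rep in 1:10) {
    s1 <- randomSpectrum(n = 1024)
    s2 <- randomSpectrum(n = 1024)
    v1 <- intensities(normalizeTotal(binSpectrum(s1, 256L)))
    v2 <- intensities(normalizeTotal(binSpectrum(s2, 256L)))
    oracle <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    expect_equal(binningSimilarity(s1, s2, 256L), oracle,
                 tolerance = 1e-12)
  }
  expect_equal(binningSimilarity(s1, s1, 256L), 1.0)
  # disjoint single-bin peaks are orthogonal
  a <- deltaSpectrum(8, n = 64)
  b <- deltaSpectrum(2, n = 64)
  expect_equal(binningSimilarity(a, b, 16L), 0.0)
})

test_that("spectrum similarity handles degenerate and trivial cases", {
  s <- simulateSpectrum(PredictionSet("m", c(2, 6), c(1L, 2L)))
  expect_equal(spectrumSimilarity(s, s), 1.0)
  zero <- NMRSpectrum(rep(0, nPoints(s)),
                      ppmMax = ppmLimits(s)[["ppmMax"]],
                      ppmMin = ppmLimits(s)[["ppmMin"]])
  expect_error(spectrumSimilarity(s, zero), "degenerate")
  small <- NMRSpectrum(runif(64), 10, 0)
  expect_error(spectrumSimilarity(s, small), "grid")
})

test_that("trees export to a nested JSON-ready form", {
  s <- normalizeTotal(deltaSpectrum(c(3, 7)))
  tr <- buildTree(s, treeParams())
  path <- withr::local_tempfile(fileext = ".json")
  exportTree(tr, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$com, 5.0)
  expect_length(back$children, 2L)
})
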