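## Seeded synthetic benchmark data: ground-truth shift lists, simulated
## "experimental" spectra with additive noise, and Gaussian shift-perturbed
## "predictions". Emulates the structure of a 1000-molecule small-molecule
## benchmark (few proton groups per molecule, shifts across the usual 1H
## range, occasional first-order couplings) without any chemistry: the
## evaluation machinery only ever consumes shift lists and spectra.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration of the synthetic benchmark generator
#'
#' @param nMolecules number of molecules.
#' @param groupsRange integer range of proton groups per molecule
#'   (default 2..8).
#' @param shiftRange ppm interval shifts are drawn from, uniformly
#'   (default 0.5..9.5).
#' @param nProtonsChoices candidate equivalent-proton counts (default
#'   1, 2, 3).
#' @param nProtonsWeights sampling weights for `nProtonsChoices`.
#' @param couplingProb probability that a group carries one scalar coupling
#'   (default 0.5).
#' @param jRange Hz interval couplings are drawn from (default 2..12).
#' @param sigmaPred ppm standard deviation of the Gaussian shift
#'   perturbation modelling predictor error (default 0.02).
#' @param sigmaExpNoise additive spectral noise as a fraction of the
#'   maximum intensity (default 0.01).
#' @param seed base RNG seed. Truth and noise use two independent streams
#'   derived from it, so sigma sweeps share identical truths.
#' @return A validated list of class `SynthConfig`.
#' @export
synthConfig <- function(nMolecules = 100L, groupsRange = c(2L, 8L),
                        shiftRange = c(0.5, 9.5),
                        nProtonsChoices = c(1L, 2L, 3L),
                        nProtonsWeights = c(1, 1, 1),
                        couplingProb = 0.5, jRange = c(2, 12),
                        sigmaPred = 0.02, sigmaExpNoise = 0.01,
                        seed = 1L) {
  stopifnot(nMolecules >= 1L, sigmaPred >= 0, sigmaExpNoise >= 0,
            groupsRange[1] >= 1L, groupsRange[2] >= groupsRange[1],
            shiftRange[2] > shiftRange[1], jRange[2] >= jRange[1],
            couplingProb >= 0, couplingProb <= 1,
            length(nProtonsChoices) == length(nProtonsWeights))
  structure(list(nMolecules = as.integer(nMolecules),
                 groupsRange = as.integer(groupsRange),
                 shiftRange = shiftRange,
                 nProtonsChoices = as.integer(nProtonsChoices),
                 nProtonsWeights = nProtonsWeights,
                 couplingProb = couplingProb, jRange = jRange,
                 sigmaPred = sigmaPred, sigmaExpNoise = sigmaExpNoise,
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

#' Generate ground-truth shift lists
#'
#' Seeded and reproducible: the same config yields the identical output.
#' Shifts are i.i.d. uniform on `shiftRange`; each group carries, with
#' probability `couplingProb`, a single coupling with J uniform on `jRange`
#' and 1-3 equivalent partners.
#'
#' @param cfg a [synthConfig()].
#' @return list of [PredictionSet-class] with ids "mol0001", ...
#' @export
generateTruth <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  .withSeed(cfg$seed, {
    lapply(seq_len(cfg$nMolecules), function(i) {
      ng <- sample(cfg$groupsRange[1]:cfg$groupsRange[2], 1L)
      shift <- stats::runif(ng, cfg$shiftRange[1], cfg$shiftRange[2])
      np <- sample(cfg$nProtonsChoices, ng, replace = TRUE,
                   prob = cfg$nProtonsWeights)
      couplings <- lapply(seq_len(ng), function(g) {
        if (stats::runif(1) < cfg$couplingProb)
          data.frame(J = stats::runif(1, cfg$jRange[1], cfg$jRange[2]),
                     nPartners = sample(1:3, 1L))
        else NULL
      })
      PredictionSet(sprintf("mol%04d", i), shift = shift, nProtons = np,
                    couplings = couplings)
    })
  })
}

#' Perturb ground-truth shifts to emulate a predictor
#'
#' Adds independent Gaussian noise N(0, sigmaPred^2) to every group shift;
#' group structure (proton counts, couplings) is preserved.
#'
#' @param truth list of [PredictionSet-class].
#' @param sigmaPred ppm standard deviation of the perturbation.
#' @param seed RNG seed for the perturbation stream.
#' @return list of perturbed [PredictionSet-class].
#' @export
perturbPredictions <- function(truth, sigmaPred, seed = 1L) {
  stopifnot(sigmaPred >= 0)
  if (sigmaPred == 0) return(truth)
  .withSeed(seed, {
    lapply(truth, function(ps) {
      g <- protonGroups(ps)
      PredictionSet(moleculeId(ps),
                    shift = g$shift + stats::rnorm(nrow(g), 0, sigmaPred),
                    nProtons = g$nProtons, couplings = g$couplings)
    })
  })
}

#' Simulate noisy "experimental" spectra from ground truth
#'
#' Simulates each molecule's spectrum and adds zero-mean uniform noise
#' whose peak-to-peak range is `noise` times the maximum intensity (the
#' usual way spectral noise is quoted relative to the tallest peak), clips
#' at zero and renormalizes to unit total intensity. With the default tree
#' noise floor (0.005 of max) a noise fraction of 0.01 is exactly removed
#' before tree building, which is what the floor is for.
#'
#' @param truth list of [PredictionSet-class].
#' @param simParams a [SimulationParams-class].
#' @param noise peak-to-peak noise range as a fraction of max intensity.
#' @param seed RNG seed for the noise stream.
#' @return list of [NMRSpectrum-class].
#' @export
makeExperimental <- function(truth, simParams = simulationParams(),
                             noise = 0.01, seed = 1L) {
  stopifnot(noise >= 0)
  clean <- simulateSpectra(truth, simParams)
  if (noise == 0) return(clean)
  .withSeed(seed, {
    lapply(clean, function(s) {
      y <- intensities(s)
      amp <- noise * max(y) / 2
      y <- y + stats::runif(length(y), -amp, amp)
      normalizeTotal(initialize(s, intensities = pmax(y, 0)))
    })
  })
}

#' Generate a complete synthetic benchmark dataset
#'
#' Convenience wrapper producing aligned truth, noisy experimental spectra,
#' perturbed predictions and the assignment table pairing true ("observed")
#' with perturbed ("predicted") group shifts. Truth and noise use
#' independent RNG streams derived from `cfg$seed`, so datasets at
#' different `sigmaPred` share identical truths and experimental spectra.
#'
#' @param cfg a [synthConfig()].
#' @param simParams a [SimulationParams-class].
#' @return list with elements `truth`, `experimental`, `predictions`,
#'   `assignments`.
#' @export
#' @examples
#' d <- makeBenchmarkDataset(synthConfig(nMolecules = 5, seed = 7))
#' length(d$experimental)
makeBenchmarkDataset <- function(cfg, simParams = simulationParams()) {
  stopifnot(inherits(cfg, "SynthConfig"))
  truth <- generateTruth(cfg)
  experimental <- makeExperimental(truth, simParams,
                                   noise = cfg$sigmaExpNoise,
                                   seed = cfg$seed + 500009L)
  predictions <- perturbPredictions(truth, cfg$sigmaPred,
                                    seed = cfg$seed + 1000003L)
  assignments <- do.call(rbind, mapply(function(tr, pr) {
    data.frame(moleculeId = moleculeId(tr),
               observed = protonGroups(tr)$shift,
               predicted = protonGroups(pr)$shift)
  }, truth, predictions, SIMPLIFY = FALSE))
  list(truth = truth, experimental = experimental,
       predictions = predictions, assignments = assignments)
}
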