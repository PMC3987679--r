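## YAML/JSON round-tripping of the two parameter objects, so runs are
## reproducible from a config file and the CLI can override fields.

#' Serialize tree and simulation parameters to a config file
#'
#' Writes a YAML (or JSON, by extension) file with `tree:` and
#' `simulation:` sections.
#'
#' @param path output path ending in .yaml/.yml or .json.
#' @param tree a [TreeParams-class].
#' @param simulation a [SimulationParams-class].
#' @return `path`, invisibly.
#' @export
writeParamsConfig <- function(path, tree = treeParams(),
                              simulation = simulationParams()) {
  obj <- list(
    tree = list(maxDepth = tree@maxDepth, minMass = tree@minMass,
                minWidth = if (is.na(tree@minWidth)) NULL else tree@minWidth,
                levelWeight = tree@levelWeight, comScale = tree@comScale,
                noiseFloor = tree@noiseFloor),
    simulation = list(field = simulation@field,
                      linewidth = simulation@linewidth,
                      lineshape = simulation@lineshape,
                      ppmMax = simulation@ppmMax,
                      ppmMin = simulation@ppmMin,
                      nPoints = simulation@nPoints))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read tree and simulation parameters from a config file
#'
#' @param path a YAML or JSON file written by [writeParamsConfig()] (either
#'   section may be omitted; defaults fill the gaps).
#' @return list with elements `tree` ([TreeParams-class]) and `simulation`
#'   ([SimulationParams-class]).
#' @export
readParamsConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  tp <- obj$tree
  sp <- obj$simulation
  fill <- function(x, default) if (is.null(x)) default else x
  tree <- treeParams(
    maxDepth = fill(tp$maxDepth, 8L),
    minMass = fill(tp$minMass, 0.01),
    minWidth = fill(tp$minWidth, NA_real_),
    levelWeight = fill(tp$levelWeight, 0.5),
    comScale = fill(tp$comScale, 0.1),
    noiseFloor = fill(tp$noiseFloor, 0.005))
  simulation <- simulationParams(
    field = fill(sp$field, 250),
    linewidth = fill(sp$linewidth, 1.0),
    lineshape = fill(sp$lineshape, "lorentzian"),
    ppmMax = fill(sp$ppmMax, defaultPpmWindow()[["ppmMax"]]),
    ppmMin = fill(sp$ppmMin, defaultPpmWindow()[["ppmMin"]]),
    nPoints = fill(sp$nPoints, 1024L))
  list(tree = tree, simulation = simulation)
}
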