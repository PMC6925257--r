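#' @import methods
#' @importFrom stats rbinom rhyper rbeta runif quantile sd uniroot dhyper setNames
#' @importFrom utils read.delim write.table packageVersion
#' @useDynLib satdyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---------------------------------------------------------------------------
## PlasmidModel: the species table of a within-cell model
## ---------------------------------------------------------------------------

#' Within-cell plasmid model
#'
#' A `PlasmidModel` bundles the plasmid species competing inside one cell with
#' the additive fitness model used to score cells. Each species has a name, an
#' autonomy flag (does it encode a complete replication machinery?), a marker
#' flag (does it carry the selected resistance gene?), and a per-copy fitness
#' cost. Cell fitness is `max(floor, baseline - sum(counts * cost))`.
#'
#' The bundled pQGS model ([pqgsModel()]) has an autonomous, marker-bearing
#' ancestral plasmid costing 3.06% per copy, a cost-free nonautonomous
#' satellite, and an autonomous deletion plasmid costing 0.50% per copy, with
#' a nominal copy number of 18 plasmids per cell.
#'
#' @slot species data.frame with columns `name`, `autonomous`, `carriesMarker`,
#'   `perCopyCost`.
#' @slot copyNumber nominal total plasmid copy number per newborn cell.
#' @slot baseline fitness of a plasmid-free cell (1.0).
#' @slot floor lower bound on cell fitness (0).
#' @export
setClass("PlasmidModel",
  representation(species = "data.frame", copyNumber = "integer",
                 baseline = "numeric", floor = "numeric"),
  prototype(copyNumber = 18L, baseline = 1, floor = 0))

setValidity("PlasmidModel", function(object) {
  sp <- object@species
  msg <- character()
  need <- c("name", "autonomous", "carriesMarker", "perCopyCost")
  if (!all(need %in% names(sp)))
    return(paste("species table needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(sp$name)) msg <- c(msg, "species names must be unique")
  if (any(sp$perCopyCost < 0 | sp$perCopyCost > 1))
    msg <- c(msg, "per-copy costs must lie in [0, 1]")
  if (length(object@copyNumber) != 1L || object@copyNumber < 1L)
    msg <- c(msg, "copyNumber must be a single positive integer")
  if (object@floor > object@baseline)
    msg <- c(msg, "fitness floor above baseline")
  if (length(msg)) msg else TRUE
})

#' Construct a plasmid model
#'
#' @param species data.frame with columns `name`, `autonomous`,
#'   `carriesMarker`, `perCopyCost`.
#' @param copyNumber nominal plasmid copy number per newborn cell.
#' @param baseline fitness of a plasmid-free cell.
#' @param floor minimum fitness.
#' @return A [PlasmidModel-class] object.
#' @examples
#' plasmidModel(data.frame(name = c("anc", "sat"),
#'                         autonomous = c(TRUE, FALSE),
#'                         carriesMarker = c(TRUE, FALSE),
#'                         perCopyCost = c(0.0306, 0)))
#' @export
plasmidModel <- function(species, copyNumber = 18L, baseline = 1, floor = 0) {
  species$name <- as.character(species$name)
  new("PlasmidModel", species = species, copyNumber = as.integer(copyNumber),
      baseline = baseline, floor = floor)
}

#' Species accessors for a plasmid model
#'
#' @param model a [PlasmidModel-class].
#' @return `speciesNames()` the character vector of species names;
#'   `perCopyCost()`, `isAutonomous()`, `carriesMarker()` vectors named by
#'   species; `copyNumber()` the nominal copy number.
#' @export
speciesNames <- function(model) model@species$name

#' @rdname speciesNames
#' @export
perCopyCost <- function(model) setNames(model@species$perCopyCost, model@species$name)

#' @rdname speciesNames
#' @export
isAutonomous <- function(model) setNames(model@species$autonomous, model@species$name)

#' @rdname speciesNames
#' @export
carriesMarker <- function(model) setNames(model@species$carriesMarker, model@species$name)

#' @rdname speciesNames
#' @export
copyNumber <- function(model) model@copyNumber

setMethod("show", "PlasmidModel", function(object) {
  cat("PlasmidModel with", nrow(object@species), "species,",
      object@copyNumber, "plasmids per cell\n")
  print(object@species, row.names = FALSE)
})

## ---------------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------------

#' Serial-dilution simulation configuration
#'
#' Holds the population-level parameters of one simulation protocol: the
#' transfer regime, duration, background fitness, selection, and numerical
#' controls for the aggregated-state engine.
#'
#' @slot dilutionFactor fold dilution per transfer (e.g. 2, 1.072, 2000).
#' @slot generationsPerCycle background doublings between transfers.
#' @slot nGenerations duration of a run in generations.
#' @slot nCycles duration in growth cycles (used by the establishment
#'   protocol).
#' @slot backgroundFitness fitness of the implicit background population.
#' @slot selectionOn if `TRUE`, cells without a marker-bearing plasmid die.
#' @slot establishmentMultiple establishment threshold as a multiple of the
#'   dilution factor.
#' @slot nCells initial number of focal cells.
#' @slot nReplicates replicate populations (trajectory protocols).
#' @slot scheme within-cell replication scheme: `"exact"`, `"polya"`, or
#'   `"frozen"`.
#' @slot exactMax per-state division count above which the engine switches
#'   from exact sampling to expected-value propagation.
#' @slot seed integer seed; `NA` leaves the RNG state alone.
#' @export
setClass("SimulationConfig",
  representation(dilutionFactor = "numeric", generationsPerCycle = "numeric",
                 nGenerations = "numeric", nCycles = "numeric",
                 backgroundFitness = "numeric", selectionOn = "logical",
                 establishmentMultiple = "numeric", nCells = "numeric",
                 nReplicates = "numeric", scheme = "character",
                 exactMax = "numeric", seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@dilutionFactor < 1) msg <- c(msg, "dilutionFactor must be >= 1")
  if (!object@scheme %in% c("exact", "polya", "frozen"))
    msg <- c(msg, "scheme must be one of exact/polya/frozen")
  if (object@backgroundFitness <= 0 && !is.na(object@backgroundFitness))
    msg <- c(msg, "backgroundFitness must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param dilutionFactor fold dilution per transfer.
#' @param nGenerations run length in generations.
#' @param nCells initial focal population size.
#' @param backgroundFitness background fitness (NA = tuned or protocol default).
#' @param selectionOn whether marker selection is active.
#' @param nCycles number of growth cycles (establishment protocol).
#' @param generationsPerCycle background doublings per cycle.
#' @param establishmentMultiple threshold multiple of the dilution factor.
#' @param nReplicates number of replicate populations.
#' @param scheme replication scheme (`"exact"`, `"polya"`, `"frozen"`).
#' @param exactMax exact-sampling threshold of the engine.
#' @param seed integer seed or NA.
#' @return A [SimulationConfig-class] object.
#' @export
simulationConfig <- function(dilutionFactor = 2, nGenerations = 500,
                             nCells = 10000, backgroundFitness = NA_real_,
                             selectionOn = TRUE, nCycles = Inf,
                             generationsPerCycle = log2(dilutionFactor),
                             establishmentMultiple = 20, nReplicates = 1,
                             scheme = "exact", exactMax = 5000,
                             seed = NA_real_) {
  new("SimulationConfig", dilutionFactor = dilutionFactor,
      generationsPerCycle = generationsPerCycle, nGenerations = nGenerations,
      nCycles = nCycles, backgroundFitness = backgroundFitness,
      selectionOn = selectionOn, establishmentMultiple = establishmentMultiple,
      nCells = nCells, nReplicates = nReplicates, scheme = scheme,
      exactMax = exactMax, seed = seed)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
      sprintf("%g-fold dilution, %g generations, %g cells, background w = %s",
              object@dilutionFactor, object@nGenerations, object@nCells,
              format(object@backgroundFitness)),
      sprintf("selection %s, scheme %s", if (object@selectionOn) "on" else "off",
              object@scheme), sep = "\n  ")
})

## ---------------------------------------------------------------------------
## PlasmidMap: an annotated circular replicon
## ---------------------------------------------------------------------------

#' Annotated circular plasmid map
#'
#' A circular replicon of a given length with role-tagged feature intervals.
#' Coordinates are 0-based half-open on the circle; a feature may wrap the
#' origin of coordinates, in which case `end = start + width` exceeds the
#' sequence length. Roles are `origin` (replication origin), `rep_gene`
#' (replication protein gene), `marker` (selected resistance gene),
#' `accessory` (burdensome cargo), and `other`.
#'
#' @slot seqLength replicon length in bases.
#' @slot features data.frame with columns `name`, `role`, `start`, `width`.
#' @export
setClass("PlasmidMap",
  representation(seqLength = "integer", features = "data.frame"))

.plasmidRoles <- c("origin", "rep_gene", "marker", "accessory", "other")

setValidity("PlasmidMap", function(object) {
  ft <- object@features
  msg <- character()
  need <- c("name", "role", "start", "width")
  if (!all(need %in% names(ft)))
    return(paste("features need columns:", paste(need, collapse = ", ")))
  if (!all(ft$role %in% .plasmidRoles))
    msg <- c(msg, paste("unknown roles:",
                        paste(setdiff(ft$role, .plasmidRoles), collapse = ", ")))
  if (any(ft$start < 0 | ft$start >= object@seqLength))
    msg <- c(msg, "feature starts must lie in [0, length)")
  if (any(ft$width < 1 | ft$width > object@seqLength))
    msg <- c(msg, "feature widths must lie in [1, length]")
  if (length(msg)) msg else TRUE
})

#' Construct a plasmid map
#'
#' @param seqLength replicon length (bases).
#' @param features data.frame with columns `name`, `role`, `start` and either
#'   `width` or `end` (0-based half-open; `end` may exceed `seqLength` for
#'   features wrapping the coordinate origin).
#' @return A [PlasmidMap-class] object.
#' @examples
#' plasmidMap(60, data.frame(
#'   name = c("oriV", "repA", "aadA", "gfp"),
#'   role = c("origin", "rep_gene", "marker", "accessory"),
#'   start = c(0, 10, 25, 35), end = c(6, 20, 30, 50)))
#' @export
plasmidMap <- function(seqLength, features) {
  if (!"width" %in% names(features)) {
    if (!"end" %in% names(features))
      stop("features need a 'width' or 'end' column")
    features$width <- features$end - features$start
  }
  features$name <- as.character(features$name)
  features$role <- as.character(features$role)
  features$start <- as.numeric(features$start)
  features$width <- as.numeric(features$width)
  features <- features[c("name", "role", "start", "width")]
  new("PlasmidMap", seqLength = as.integer(seqLength), features = features)
}

#' Map accessors
#'
#' @param map a [PlasmidMap-class].
#' @param role optional role filter.
#' @return `plasmidLength()` the replicon length; `plasmidFeatures()` the
#'   feature table with `start`, `end` (half-open, `end` may exceed the length
#'   for wrapping features) and `width`.
#' @export
plasmidLength <- function(map) map@seqLength

#' @rdname plasmidLength
#' @export
plasmidFeatures <- function(map, role = NULL) {
  ft <- map@features
  ft$end <- ft$start + ft$width
  if (!is.null(role)) ft <- ft[ft$role %in% role, , drop = FALSE]
  ft[c("name", "role", "start", "end", "width")]
}

setMethod("show", "PlasmidMap", function(object) {
  cat("PlasmidMap: circular,", object@seqLength, "bp,",
      nrow(object@features), "features\n")
  print(plasmidFeatures(object), row.names = FALSE)
})

## ---------------------------------------------------------------------------
## PopulationEnsemble: focal cells aggregated by identical state
## ---------------------------------------------------------------------------

#' Focal cell population aggregated by cell state
#'
#' Cells with identical plasmid content are stored once with a multiplicity,
#' which keeps serial-dilution simulations tractable. `states` has one column
#' per species of the model; `counts` holds the number of cells in each state
#' (fractional values arise in the expected-value regime of the engine).
#'
#' @slot model the [PlasmidModel-class] the states refer to.
#' @slot states numeric matrix of per-species plasmid counts (rows = states).
#' @slot counts cell multiplicity per state.
#' @export
setClass("PopulationEnsemble",
  representation(model = "PlasmidModel", states = "matrix", counts = "numeric"))

setValidity("PopulationEnsemble", function(object) {
  msg <- character()
  if (ncol(object@states) != nrow(object@model@species))
    msg <- c(msg, "states must have one column per species")
  if (nrow(object@states) != length(object@counts))
    msg <- c(msg, "one multiplicity per state row")
  if (any(object@counts < 0)) msg <- c(msg, "cell multiplicities must be >= 0")
  if (any(object@states < 0)) msg <- c(msg, "plasmid counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a population ensemble
#'
#' @param model a [PlasmidModel-class].
#' @param cells either a named numeric vector (one cell state, replicated
#'   `n` times), or a matrix of states with one column per species.
#' @param n multiplicities (recycled over state rows).
#' @return A [PopulationEnsemble-class].
#' @examples
#' m <- pqgsModel()
#' populationEnsemble(m, c(ancestral = 17, satellite = 1, deletion = 0), n = 100)
#' @export
populationEnsemble <- function(model, cells, n = 1) {
  if (is.null(dim(cells))) {
    cells <- matrix(cells[speciesNames(model)], nrow = 1,
                    dimnames = list(NULL, speciesNames(model)))
  } else {
    cells <- cells[, speciesNames(model), drop = FALSE]
  }
  new("PopulationEnsemble", model = model, states = cells,
      counts = rep_len(as.numeric(n), nrow(cells)))
}

#' Population size of an ensemble
#'
#' @param pop a [PopulationEnsemble-class].
#' @return total number of cells.
#' @export
populationSize <- function(pop) sum(pop@counts)

#' Mean per-cell copy number by species
#'
#' @param pop a [PopulationEnsemble-class].
#' @return named vector of mean plasmid counts per cell.
#' @export
meanCopyNumber <- function(pop) {
  if (populationSize(pop) == 0)
    return(setNames(rep(NA_real_, ncol(pop@states)), colnames(pop@states)))
  drop(crossprod(pop@states, pop@counts)) / populationSize(pop)
}

setMethod("show", "PopulationEnsemble", function(object) {
  cat("PopulationEnsemble:", format(populationSize(object)), "cells in",
      sum(object@counts > 0), "distinct states\n")
  if (populationSize(object) > 0) {
    cat("mean copy number per cell:\n")
    print(round(meanCopyNumber(object), 3))
  }
})
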