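## Population layer: generic ensemble operations. The protocol drivers in
## protocols.R use the fast two-species engine; these operations work for any
## number of species and are the reference semantics the engine must match.

#' Advance a population by one division-opportunity step
#'
#' Each viable cell divides with probability equal to its relative fitness
#' (one simulation step; the implicit background of fitness `w_b` sets the
#' clock, one background-cell generation being `1/w_b` steps). A dividing
#' cell doubles its plasmids ([replicatePlasmids()]) and assorts them to two
#' daughters ([segregatePlasmids()]); daughters failing [isViable()] are
#' removed; cells without an autonomous plasmid persist unchanged (they
#' cannot divide). Non-dividing viable cells persist unchanged.
#'
#' @param pop a [PopulationEnsemble-class].
#' @param cfg a [SimulationConfig-class] (scheme and selection are honoured).
#' @return the advanced [PopulationEnsemble-class].
#' @export
advanceGeneration <- function(pop, cfg = simulationConfig()) {
  model <- pop@model
  states <- pop@states
  counts <- pop@counts
  if (sum(counts) == 0) return(pop)   # extinction
  auto <- isAutonomous(model)
  newStates <- list()
  newCounts <- numeric()
  push <- function(s, k) {
    newStates[[length(newStates) + 1L]] <<- s
    newCounts[length(newCounts) + 1L] <<- k
  }
  for (i in seq_len(nrow(states))) {
    if (counts[i] == 0) next
    cell <- setNames(states[i, ], colnames(states))
    if (!isViable(cell, model, cfg@selectionOn)) next
    w <- cellFitness(cell, model)
    canDivide <- sum(cell[auto]) > 0 && sum(cell) > 0
    d <- if (canDivide) rbinom(1, round(counts[i]), min(1, w)) else 0
    if (counts[i] - d > 0) push(states[i, ], counts[i] - d)
    for (k in seq_len(d)) {
      doubled <- replicatePlasmids(cell, model, cfg@scheme)
      dd <- segregatePlasmids(doubled, model)
      for (dau in dd)
        if (isViable(dau, model, cfg@selectionOn)) push(dau, 1)
    }
  }
  if (!length(newCounts))
    return(new("PopulationEnsemble", model = model,
               states = states[0, , drop = FALSE], counts = numeric()))
  sm <- do.call(rbind, newStates)
  colnames(sm) <- colnames(states)
  ## aggregate identical states
  key <- apply(sm, 1, paste, collapse = ",")
  agg <- rowsum(newCounts, key)
  first <- !duplicated(key)
  sm <- sm[first, , drop = FALSE]
  cnt <- agg[match(apply(sm, 1, paste, collapse = ","), rownames(agg)), 1]
  new("PopulationEnsemble", model = model, states = sm, counts = cnt)
}

#' Dilute a population by binomial thinning
#'
#' Each cell survives a transfer independently with probability `1/factor`.
#'
#' @param pop a [PopulationEnsemble-class].
#' @param factor fold dilution (>= 1).
#' @return the thinned [PopulationEnsemble-class].
#' @export
dilutePopulation <- function(pop, factor) {
  if (factor < 1) stop("dilution factor must be >= 1")
  if (factor == 1 || populationSize(pop) == 0) return(pop)
  cnt <- .thinTwoSpecies(pop@counts, factor)
  new("PopulationEnsemble", model = pop@model, states = pop@states, counts = cnt)
}

#' Realized fitness from a size trajectory
#'
#' The number of doublings a focal population achieved, corrected for the
#' dilutions applied, relative to the number of background doublings elapsed:
#' `log2(N_t * prod(dilutions) / N_0) / nGenerations`.
#'
#' @param focalSizes numeric vector of focal population sizes (first and last
#'   are used).
#' @param dilutions fold dilutions applied during the interval.
#' @param nGenerations background doublings elapsed.
#' @return dimensionless fitness relative to the background.
#' @examples
#' realizedFitness(c(100, 100 * 2^9), dilutions = rep(1, 10), nGenerations = 10)
#' @export
realizedFitness <- function(focalSizes, dilutions = 1, nGenerations) {
  n0 <- focalSizes[1]
  nt <- focalSizes[length(focalSizes)]
  if (n0 <= 0 || nt <= 0) stop("undefined fitness: non-positive population size")
  log2(nt * prod(dilutions) / n0) / nGenerations
}
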