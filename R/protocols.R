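## The three study protocols, built on the aggregated two-species engine:
## equilibrium tuning of the background fitness, phenotypic-delay
## trajectories, and establishment probability under daily transfers.

## identify the (reference, mutant) pair of a two-species run
.splitInitialCell <- function(initialCell, model) {
  initialCell <- .checkCell(initialCell, model)
  present <- names(initialCell)[initialCell > 0]
  ref <- present[which.max(initialCell[present])]
  mut <- setdiff(present, ref)
  if (length(mut) > 1)
    stop("the aggregated engine tracks one mutant species besides '", ref, "'")
  list(ref = ref, mutant = if (length(mut)) mut else NA_character_,
       j0 = unname(initialCell[ref]))
}

## run one serial-dilution trajectory and return the stationary net log
## growth: the size ratio between the end of the run and the end of a
## burn-in window, so the transient from the seeded composition to the
## quasi-stationary state does not bias the measurement. Extinction maps to
## a large negative value.
.netLogGrowth <- function(m0, sc, wb, nSteps, scheme, exactMax, Dm,
                          selectionOn = TRUE, burnIn = 0.4) {
  m <- m0
  n0 <- sum(m)
  burnAt <- ceiling(nSteps * burnIn)
  for (t in seq_len(nSteps)) {
    m <- .stepTwoSpecies(m, sc, scheme, exactMax, selectionOn = selectionOn,
                         Dm = Dm)
    m <- .thinTwoSpecies(m, 1 + wb)   # continuous equivalent of 2-fold
    if (sum(m) == 0) return(-20)      # serial dilutions per background doubling
    ## during burn-in the population is held at its nominal size while the
    ## composition relaxes from the seeded cell to the quasi-stationary mix;
    ## growth is then measured freely from the full-size stationary sample
    if (t <= burnAt) m <- m * (n0 / sum(m))
  }
  log(sum(m) / n0)
}

#' Tune the background fitness to the focal type's equilibrium
#'
#' Bisects the fitness of the implicit background population until a focal
#' population seeded with `nCells` copies of `initialCell` neither grows nor
#' shrinks over `nGenerations` of growth under 2-fold serial dilution. At
#' that point the background fitness equals the focal type's realized
#' equilibrium fitness, including losses from marker-free segregants. With
#' the pQGS preset seeded with 1 satellite + 17 ancestral plasmids the tuned
#' value is about 0.77, well below the naive additive expectation
#' `1 - 5.2 x 0.0306 = 0.841` for the equilibrium ancestral copy number.
#'
#' A single-species seed has no compositional stochasticity, so its
#' equilibrium fitness is [cellFitness()] and is returned directly.
#'
#' @param initialCell named vector of plasmid counts of the seeded cell type.
#' @param model a [PlasmidModel-class].
#' @param cfg a [SimulationConfig-class] (the equilibrium preset by default).
#' @param bracket search interval for the background fitness.
#' @param tol bisection tolerance on the tuned fitness.
#' @param stabilityTol maximum |log(N_final/N_initial)| accepted as stable.
#' @return the tuned background fitness (scalar, with attributes
#'   `stability` = final mean log size ratio and `nIterations`).
#' @examples
#' \donttest{
#' cfg <- protocolPreset("equilibrium", deskScale = TRUE)
#' wstar <- tuneBackgroundFitness(c(ancestral = 17, satellite = 1, deletion = 0),
#'                                pqgsModel(), cfg)
#' }
#' @export
tuneBackgroundFitness <- function(initialCell, model,
                                  cfg = protocolPreset("equilibrium"),
                                  bracket = c(0.4, 1), tol = 0.005,
                                  stabilityTol = 0.1) {
  if (!is.na(cfg@seed)) set.seed(cfg@seed)
  parts <- .splitInitialCell(initialCell, model)
  if (is.na(parts$mutant)) {
    if (!isViable(initialCell, model, cfg@selectionOn))
      stop("no equilibrium: the seeded cell type is not viable under selection")
    return(structure(cellFitness(initialCell, model),
                     stability = 0, nIterations = 0L))
  }
  sc <- .twoSpeciesScenario(model, parts$mutant, parts$ref)
  Dm <- .daughterMatrix(sc$n, cfg@scheme)
  m0 <- numeric(sc$n + 1)
  m0[parts$j0 + 1] <- cfg@nCells
  iterReps <- max(2L, ceiling(cfg@nReplicates / 3))
  evalAt <- function(wb, reps) {
    nSteps <- round(cfg@nGenerations / wb)   # generations = background-cell doublings
    mean(vapply(seq_len(reps), function(i)
      .netLogGrowth(m0, sc, wb, nSteps, cfg@scheme, cfg@exactMax, Dm,
                    cfg@selectionOn), 0))
  }
  lo <- bracket[1]; hi <- bracket[2]
  glo <- evalAt(lo, iterReps); ghi <- evalAt(hi, iterReps)
  if (glo < 0 || ghi > 0)
    stop("no equilibrium: population not stable anywhere in the bracket")
  it <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    g <- evalAt(mid, iterReps)
    if (g > 0) lo <- mid else hi <- mid
    it <- it + 1L
  }
  wb <- (lo + hi) / 2
  stab <- evalAt(wb, cfg@nReplicates)
  nSteps <- round(cfg@nGenerations / wb)
  if (abs(stab) > max(stabilityTol, tol * nSteps))
    warning("tuned point drifts more than the bisection precision implies")
  structure(wb, stability = stab, nIterations = it)
}

#' Equilibrium plasmid composition of a focal cell type
#'
#' Runs the serial-dilution simulation at the tuned background fitness and
#' returns the time-averaged mean per-cell copy number of each species over
#' the post-burn-in population. With the pQGS preset seeded with 1 satellite
#' + 17 ancestral plasmids this converges to about 5.2 ancestral and 12.8
#' satellite plasmids per cell.
#'
#' The population is held at its nominal size during the run (composition
#' dynamics are invariant to uniform thinning), so the averages are well
#' sampled regardless of the transient from the seeded composition.
#'
#' @inheritParams tuneBackgroundFitness
#' @param backgroundFitness background fitness to run at; tuned via
#'   [tuneBackgroundFitness()] when `NULL`.
#' @param burnIn fraction of the run discarded before averaging.
#' @return named vector of mean per-cell copy numbers (all model species),
#'   with the tuned background fitness as attribute `backgroundFitness`.
#' @export
equilibriumComposition <- function(initialCell, model,
                                   cfg = protocolPreset("equilibrium"),
                                   backgroundFitness = NULL, burnIn = 0.5) {
  parts <- .splitInitialCell(initialCell, model)
  if (is.null(backgroundFitness))
    backgroundFitness <- as.numeric(tuneBackgroundFitness(initialCell, model, cfg))
  if (!is.na(cfg@seed)) set.seed(cfg@seed + 1)
  out <- setNames(numeric(nrow(model@species)), speciesNames(model))
  if (is.na(parts$mutant)) {
    out[names(initialCell)] <- initialCell
    return(structure(out, backgroundFitness = backgroundFitness))
  }
  sc <- .twoSpeciesScenario(model, parts$mutant, parts$ref)
  Dm <- .daughterMatrix(sc$n, cfg@scheme)
  m <- numeric(sc$n + 1)
  m[parts$j0 + 1] <- cfg@nCells
  nSteps <- round(cfg@nGenerations / backgroundFitness)
  keepFrom <- ceiling(nSteps * burnIn)
  js <- 0:sc$n
  accA <- 0; accN <- 0
  sizes <- numeric(nSteps)
  for (t in seq_len(nSteps)) {
    m <- .stepTwoSpecies(m, sc, cfg@scheme, cfg@exactMax, Dm = Dm)
    m <- .thinTwoSpecies(m, 1 + backgroundFitness)
    sizes[t] <- sum(m)
    if (sizes[t] == 0)
      stop(structure(class = c("extinctionError", "error", "condition"),
                     list(message = "population extinct before equilibrium",
                          call = sys.call(), trajectory = sizes[1:t])))
    ## hold the population at its nominal size: the composition dynamics are
    ## invariant to uniform thinning, and the transient from the seeded cell
    ## to the equilibrium mix would otherwise shrink the sample
    m <- m * (cfg@nCells / sum(m))
    if (t >= keepFrom) {
      accA <- accA + sum(js * m) / sum(m)
      accN <- accN + 1
    }
  }
  out[parts$ref] <- accA / accN
  out[parts$mutant] <- sc$n - accA / accN
  structure(out, backgroundFitness = backgroundFitness)
}

#' Phenotypic-delay trajectories of a new mutant plasmid
#'
#' Seeds `nReplicates` populations of `nCells` cells, each carrying one copy
#' of the mutant plasmid (satellite or deletion) and `copyNumber - 1`
#' ancestral copies, and propagates them under per-generation dilutions in a
#' background of ancestral-plasmid cells. The realized fitness of the
#' mutant-carrying subpopulation is recorded per generation (from its growth
#' between consecutive transfers, corrected for dilution); cells that lose
#' the mutant plasmid rejoin the background, and satellite-only cells die
#' under selection. The trajectory shows the phenotypic delay: descendants
#' only gradually realize the fitness of the mutant equilibrium (about 0.77
#' for satellites, 0.910 for deletion plasmids).
#'
#' @param mutant `"satellite"` or `"deletion"` (a species of `model`).
#' @param model a [PlasmidModel-class].
#' @param cfg a [SimulationConfig-class] (the delay preset by default).
#' @return data.frame of class `fitnessTrajectory` with columns `generation`,
#'   `meanFitness`, `lower`, `upper` (95% band across replicates).
#' @examples
#' \donttest{
#' cfg <- protocolPreset("delay", deskScale = TRUE)
#' trj <- phenotypicDelayTrajectories("deletion", pqgsModel(), cfg)
#' }
#' @export
phenotypicDelayTrajectories <- function(mutant, model,
                                        cfg = protocolPreset("delay")) {
  if (!mutant %in% speciesNames(model)) stop("unknown mutant species: ", mutant)
  if (!is.na(cfg@seed)) set.seed(cfg@seed)
  wbg <- cfg@backgroundFitness
  if (is.na(wbg)) wbg <- cellFitness(
    setNames((speciesNames(model) == "ancestral") * copyNumber(model),
             speciesNames(model)), model)
  sc <- .twoSpeciesScenario(model, mutant)
  Dm <- .daughterMatrix(sc$n, cfg@scheme)
  nGen <- cfg@nGenerations
  marks <- round((1:nGen) * .stepsPerGeneration(wbg))
  W <- matrix(NA_real_, cfg@nReplicates, nGen)
  for (r in seq_len(cfg@nReplicates)) {
    m <- numeric(sc$n + 1)
    m[sc$n] <- cfg@nCells        # j = n - 1 ancestral, 1 mutant copy
    nPrev <- cfg@nCells; tPrev <- 0
    for (g in seq_len(nGen)) {
      for (t in seq_len(marks[g] - tPrev))
        m <- .stepTwoSpecies(m, sc, cfg@scheme, cfg@exactMax,
                             selectionOn = cfg@selectionOn,
                             dropNonCarrier = TRUE, Dm = Dm)
      ng <- sum(m)
      if (ng == 0) break
      W[r, g] <- (ng / nPrev)^(1 / (marks[g] - tPrev)) - 1
      m <- .thinTwoSpecies(m, cfg@dilutionFactor)
      nPrev <- sum(m); tPrev <- marks[g]
      if (nPrev == 0) break
    }
  }
  if (all(is.na(W[, 1])))
    stop("all replicate populations went extinct")
  mu <- colMeans(W, na.rm = TRUE)
  se <- apply(W, 2, function(x) sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))))
  out <- data.frame(generation = seq_len(nGen), meanFitness = mu,
                    lower = mu - 1.96 * se, upper = mu + 1.96 * se)
  class(out) <- c("fitnessTrajectory", "data.frame")
  attr(out, "mutant") <- mutant
  attr(out, "nReplicates") <- cfg@nReplicates
  out
}

#' Crossover generation of two fitness trajectories
#'
#' The largest generation `g` such that the satellite trajectory's mean lies
#' strictly above the deletion trajectory's mean at every generation up to
#' `g` (0 when the satellite is never above). With the study presets the
#' satellite's head start lasts about a dozen generations before
#' deletion-plasmid carriers overtake.
#'
#' @param sat,del `fitnessTrajectory` data.frames of equal length (see
#'   [phenotypicDelayTrajectories()]).
#' @return integer generation index.
#' @export
crossoverGeneration <- function(sat, del) {
  if (nrow(sat) != nrow(del)) stop("trajectories must have the same length")
  above <- sat$meanFitness > del$meanFitness
  above[is.na(above)] <- FALSE
  if (!above[1]) return(0L)
  max(which(cumsum(!above) == 0))
}

#' Establishment probability of a new mutant plasmid
#'
#' Single-founder trials under the daily serial-transfer regime: a cell with
#' one mutant plasmid plus `copyNumber - 1` ancestral copies arises at a
#' random cell division within a growth cycle (sampled proportional to the
#' number of divisions occurring at each moment of the cycle), grows in
#' competition with an ancestral-plasmid background, and is transferred with
#' `dilutionFactor`-fold bottlenecks at the end of each cycle. A trial
#' succeeds when mutant-carrying descendants reach
#' `establishmentMultiple * dilutionFactor` cells at the end of a growth
#' cycle, and fails when they go extinct.
#'
#' @param mutant `"satellite"` or `"deletion"`.
#' @param model a [PlasmidModel-class].
#' @param cfg a [SimulationConfig-class] (the establishment preset by
#'   default).
#' @param nTrials number of founder trials (defaults to `cfg@nReplicates`).
#' @return list with `probability`, `successes`, `nTrials`, and `ci` (95%
#'   binomial confidence interval).
#' @examples
#' \donttest{
#' cfg <- protocolPreset("establishment", deskScale = TRUE)
#' est <- establishmentProbability("satellite", pqgsModel(), cfg, nTrials = 1000)
#' }
#' @export
establishmentProbability <- function(mutant, model,
                                     cfg = protocolPreset("establishment"),
                                     nTrials = NULL) {
  if (!mutant %in% speciesNames(model)) stop("unknown mutant species: ", mutant)
  if (is.null(nTrials)) nTrials <- cfg@nReplicates
  if (!is.na(cfg@seed)) set.seed(cfg@seed)
  wbg <- cfg@backgroundFitness
  if (is.na(wbg)) wbg <- cellFitness(
    setNames((speciesNames(model) == "ancestral") * copyNumber(model),
             speciesNames(model)), model)
  sc <- .twoSpeciesScenario(model, mutant)
  Dm <- .daughterMatrix(sc$n, cfg@scheme)
  threshold <- cfg@establishmentMultiple * cfg@dilutionFactor
  ## cycle length: the background regrows by the transfer dilution factor
  cyc <- log(cfg@dilutionFactor) / log(1 + wbg)
  lam <- log(1 + wbg)
  nFull <- floor(cyc); frac <- cyc - nFull
  ## founder origin: position in the cycle, division-density weighted
  u <- runif(nTrials)
  t0 <- log(1 + u * (exp(lam * cyc) - 1)) / lam
  succ <- 0L
  maxCycles <- if (is.finite(cfg@nCycles)) cfg@nCycles else 1000
  for (i in seq_len(nTrials)) {
    m <- numeric(sc$n + 1)
    m[sc$n] <- 1
    rem <- cyc - t0[i]
    cycle <- 0L
    repeat {
      nf <- floor(rem)
      for (t in seq_len(nf)) {
        m <- .stepTwoSpecies(m, sc, cfg@scheme, cfg@exactMax,
                             selectionOn = cfg@selectionOn,
                             dropNonCarrier = TRUE, Dm = Dm)
        if (sum(m) == 0) break
      }
      if (sum(m) > 0 && rem - nf > 1e-9)
        m <- .stepTwoSpecies(m, sc, cfg@scheme, cfg@exactMax,
                             selectionOn = cfg@selectionOn,
                             dropNonCarrier = TRUE, Dm = Dm,
                             qScale = rem - nf)
      if (sum(m) == 0) break
      if (sum(m) >= threshold) { succ <- succ + 1L; break }
      m <- .thinTwoSpecies(m, cfg@dilutionFactor)
      if (sum(m) == 0) break
      cycle <- cycle + 1L
      if (cycle >= maxCycles) break
      rem <- cyc
    }
  }
  p <- succ / nTrials
  ci <- stats::binom.test(succ, nTrials)$conf.int
  list(probability = p, successes = succ, nTrials = nTrials,
       ci = c(lower = ci[1], upper = ci[2]))
}
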