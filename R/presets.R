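## Bundled study presets: the pQGS plasmid model and the three simulation
## protocols (equilibrium tuning, phenotypic delay, establishment).

#' The pQGS within-cell model
#'
#' The calibrated model for an *E. coli* cell carrying the pQGS IncQ plasmid
#' and its evolved derivatives: 18 plasmids per cell; the full-length
#' ancestral plasmid costs 3.06% of fitness per copy, an accessory-gene
#' deletion plasmid (DP) 0.50% per copy, and a satellite plasmid (SP) is
#' cost-free. The ancestral plasmid and the DP are autonomous and carry the
#' spectinomycin marker (aadA); the SP is nonautonomous and carries neither.
#'
#' @return A [PlasmidModel-class] with species `ancestral`, `satellite`,
#'   `deletion`.
#' @examples
#' cellFitness(c(ancestral = 18, satellite = 0, deletion = 0), pqgsModel())
#' @export
pqgsModel <- function() {
  plasmidModel(data.frame(
    name          = c("ancestral", "satellite", "deletion"),
    autonomous    = c(TRUE, FALSE, TRUE),
    carriesMarker = c(TRUE, FALSE, TRUE),
    perCopyCost   = c(0.0306, 0, 0.0050)),
    copyNumber = 18L)
}

#' Bundled simulation protocol presets
#'
#' Returns the three study protocols at full scale, or reduced "desk"
#' variants for quick runs and tests:
#' \describe{
#'   \item{equilibrium}{10,000 cells, 500 generations, 2-fold serial
#'     dilutions, selection on; used with [tuneBackgroundFitness()] and
#'     [equilibriumComposition()].}
#'   \item{delay}{200 replicate populations of 20,000 cells, 50 generations,
#'     1.072-fold dilutions, ancestral-only background; used with
#'     [phenotypicDelayTrajectories()].}
#'   \item{establishment}{1,000,000 single-founder trials under daily
#'     2000-fold transfers with establishment threshold 20 x dilution; used
#'     with [establishmentProbability()].}
#' }
#' Desk variants reduce replicate/trial counts (not the biological
#' parameters) and are flagged by `deskScale = TRUE`.
#'
#' @param protocol `"equilibrium"`, `"delay"`, or `"establishment"`.
#' @param deskScale return the scaled-down variant?
#' @return A [SimulationConfig-class]; desk variants carry fewer replicates
#'   or trials, never different biology.
#' @export
protocolPreset <- function(protocol = c("equilibrium", "delay", "establishment"),
                           deskScale = FALSE) {
  protocol <- match.arg(protocol)
  switch(protocol,
    equilibrium = simulationConfig(
      dilutionFactor = 2, nGenerations = 500,
      nCells = if (deskScale) 2000 else 10000,
      nReplicates = if (deskScale) 3 else 10,
      selectionOn = TRUE),
    delay = simulationConfig(
      dilutionFactor = 1.072, nGenerations = 50,
      nCells = 20000,
      nReplicates = if (deskScale) 50 else 200,
      backgroundFitness = 1 - 18 * 0.0306,
      selectionOn = TRUE),
    establishment = simulationConfig(
      dilutionFactor = 2000, nGenerations = Inf,
      nCells = 1, nCycles = Inf,
      nReplicates = if (deskScale) 1e5 else 1e6,
      backgroundFitness = 1 - 18 * 0.0306,
      establishmentMultiple = 20,
      selectionOn = TRUE))
}
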