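## Within-cell layer: fitness, replication to exact doubling, segregation,
## viability. A cell is a named integer vector of plasmid counts per species.

.checkCell <- function(cell, model) {
  cell <- cell[speciesNames(model)]
  if (anyNA(cell)) stop("cell must name every species of the model")
  if (any(cell < 0)) stop("invalid cell state: negative plasmid count")
  cell
}

#' Fitness of a cell under the additive cost model
#'
#' Relative fitness is `baseline - sum(counts * perCopyCost)`, floored at the
#' model's fitness floor. With the pQGS model a cell holding 18 ancestral
#' plasmids has fitness 1 - 18 x 0.0306 = 0.4492, and a cell holding 18
#' deletion plasmids has 1 - 18 x 0.005 = 0.910.
#'
#' @param cell named numeric vector of plasmid counts.
#' @param model a [PlasmidModel-class].
#' @return relative fitness (dimensionless scalar).
#' @examples
#' m <- pqgsModel()
#' cellFitness(c(ancestral = 0, satellite = 0, deletion = 18), m)  # 0.910
#' @export
cellFitness <- function(cell, model) {
  cell <- .checkCell(cell, model)
  max(model@floor, model@baseline - sum(cell * perCopyCost(model)))
}

#' Replicate the plasmids of one cell to exact doubling
#'
#' Doubles the total plasmid count of a cell ahead of division. Replication
#' requires at least one autonomous plasmid in the cell: replication proteins
#' act in trans, so every plasmid present (including nonautonomous
#' satellites) is eligible while any autonomous plasmid remains. Three
#' schemes are supported:
#' \describe{
#'   \item{`exact`}{every plasmid copy is duplicated exactly once (the
#'     default; initiation-limited replication with equal chances).}
#'   \item{`polya`}{n sequential template draws from the growing pool (urn
#'     with replacement): the n new copies follow a Dirichlet-multinomial
#'     distribution around the starting composition.}
#'   \item{`frozen`}{n template draws from the starting pool only
#'     (multinomial).}
#' }
#'
#' @param cell named numeric vector of plasmid counts.
#' @param model a [PlasmidModel-class].
#' @param scheme `"exact"`, `"polya"`, or `"frozen"`.
#' @return the doubled cell, or an error of class `"replicationImpossible"`
#'   when no autonomous plasmid is present (the cell is left unchanged by the
#'   caller in that case).
#' @examples
#' m <- pqgsModel()
#' replicatePlasmids(c(ancestral = 18, satellite = 0, deletion = 0), m)
#' @export
replicatePlasmids <- function(cell, model, scheme = c("exact", "polya", "frozen")) {
  scheme <- match.arg(scheme)
  cell <- .checkCell(cell, model)
  if (sum(cell) == 0L || sum(cell[isAutonomous(model)]) == 0)
    stop(structure(class = c("replicationImpossible", "error", "condition"),
                   list(message = "no autonomous plasmid: replication impossible",
                        call = sys.call())))
  n <- sum(cell)
  newCopies <- switch(scheme,
    exact = cell,
    polya = {
      # Polya urn: composition of the n additions ~ DirMult(n, alpha = cell)
      g <- rgamma(length(cell), shape = cell)
      if (sum(g) == 0) g <- cell / sum(cell)
      drop(rmultinom(1, n, g / sum(g)))
    },
    frozen = drop(rmultinom(1, n, cell / sum(cell))))
  out <- cell + newCopies
  names(out) <- names(cell)
  out
}

#' Segregate a doubled plasmid pool to two daughter cells
#'
#' Random but even assortment: daughter 1 receives exactly half of the
#' doubled pool, drawn uniformly without replacement (multivariate
#' hypergeometric); daughter 2 receives the complement, so per-species counts
#' are conserved.
#'
#' @param cell named numeric vector of plasmid counts with an even total
#'   (call after [replicatePlasmids()]).
#' @param model a [PlasmidModel-class].
#' @return list of two named vectors, `daughter1` and `daughter2`.
#' @export
segregatePlasmids <- function(cell, model) {
  cell <- .checkCell(cell, model)
  tot <- sum(cell)
  if (tot %% 2 != 0) stop("plasmid total must be even at segregation")
  half <- tot / 2
  d1 <- cell * 0
  left <- tot
  slots <- half
  for (s in seq_along(cell)) {
    left <- left - cell[s]
    d1[s] <- rhyper(1, cell[s], left, slots)
    slots <- slots - d1[s]
  }
  list(daughter1 = d1, daughter2 = cell - d1)
}

#' Is a cell viable?
#'
#' Under marker selection a cell needs at least one plasmid carrying the
#' selected resistance gene; without selection every cell is viable.
#'
#' @param cell named numeric vector of plasmid counts.
#' @param model a [PlasmidModel-class].
#' @param selectionOn logical.
#' @return logical.
#' @export
isViable <- function(cell, model, selectionOn = TRUE) {
  cell <- .checkCell(cell, model)
  !selectionOn || sum(cell[carriesMarker(model)]) > 0
}

#' @importFrom stats rgamma rmultinom
NULL
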