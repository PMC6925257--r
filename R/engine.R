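## Aggregated-state simulation engine.
##
## All three study protocols track cells holding a mix of the ancestral
## plasmid and exactly one mutant species (satellite or deletion plasmid),
## with a fixed total of n plasmids per newborn cell. A cell state is then
## just j = number of ancestral copies (0..n), and a population is a vector
## m[j+1] of cell multiplicities. Each simulation step every cell divides
## with probability equal to its fitness w(j); a division doubles the
## plasmid pool (exact doubling by default) and assorts it evenly at random
## to two daughters (hypergeometric). Per-state division counts above
## `exactMax` are propagated through the expected daughter distribution
## instead of sampled; dilution is binomial thinning.

## expected-daughter matrix: D[j+1, x+1] = expected daughters with x ancestral
## copies per division of a parent with j of n, under a replication scheme
.daughterMatrix <- function(n, scheme = "exact") {
  D <- matrix(0, n + 1, n + 1)
  for (j in 0:n) {
    pk <- switch(scheme,
      exact  = as.numeric(0:n == j),
      frozen = dbinom(0:n, n, j / n),
      polya  = .dbetabinom(0:n, n, j, n - j))
    for (k in which(pk > 1e-15) - 1L) {
      a2 <- j + k
      D[j + 1, ] <- D[j + 1, ] + pk[k + 1] * 2 * dhyper(0:n, a2, 2 * n - a2, n)
    }
  }
  D
}

.dbetabinom <- function(k, size, a, b) {
  if (a == 0) return(as.numeric(k == 0))
  if (b == 0) return(as.numeric(k == size))
  exp(lchoose(size, k) + lbeta(a + k, b + size - k) - lbeta(a, b))
}

## scenario: fixed ingredients of a two-species run; the reference species
## defaults to "ancestral" when the model has one
.twoSpeciesScenario <- function(model, mutant, reference = NULL) {
  n <- copyNumber(model)
  cost <- perCopyCost(model)
  auto <- isAutonomous(model)
  mark <- carriesMarker(model)
  if (is.null(reference)) {
    others <- setdiff(speciesNames(model), mutant)
    reference <- if ("ancestral" %in% others) "ancestral" else others[1]
  }
  j <- 0:n   # reference copies; mutant copies = n - j
  w <- pmax(model@floor, model@baseline - j * cost[[reference]] -
              (n - j) * cost[[mutant]])
  ## j = 0 cells can only divide when the mutant is autonomous; cells always
  ## hold at least one reference copy otherwise they have left the class
  list(n = n, w = w, reference = reference,
       mutantAutonomous = auto[[mutant]],
       mutantMarker = mark[[mutant]])
}

## draw ancestral copies added during doubling, per division (vectorised over
## parent states js); n draws total
.replicateDraws <- function(js, n, scheme) {
  switch(scheme,
    exact = js,
    frozen = rbinom(length(js), n, js / n),
    polya = {
      k <- integer(length(js))
      mid <- js > 0 & js < n
      if (any(mid)) {
        p <- rbeta(sum(mid), js[mid], n - js[mid])
        k[mid] <- rbinom(sum(mid), n, p)
      }
      k[js == n] <- n
      k
    })
}

## one division-opportunity step for a two-species population vector m[j+1].
## Returns the updated vector. qScale < 1 scales division probabilities
## (fractional step at the end of a growth cycle).
.stepTwoSpecies <- function(m, sc, scheme = "exact", exactMax = 5000,
                            selectionOn = TRUE, dropNonCarrier = FALSE,
                            Dm = NULL, qScale = 1) {
  n <- sc$n
  q <- sc$w * qScale
  if (!sc$mutantAutonomous) q[1] <- 0   # no machinery: cannot divide
  mNew <- numeric(n + 1)
  active <- which(m > 0)
  ## exact regime: sample divisions and daughters state by state
  small <- active[m[active] <= exactMax]
  if (length(small)) {
    msmall <- round(m[small])
    d <- rbinom(length(small), msmall, q[small])
    mNew[small] <- mNew[small] + (msmall - d)
    div <- d > 0
    if (any(div)) {
      js <- rep((small - 1L)[div], d[div])
      k <- .replicateDraws(js, n, scheme)
      a2 <- js + k
      x1 <- rhyper(length(js), a2, 2 * n - a2, n)
      mNew <- mNew + tabulate(c(x1, a2 - x1) + 1L, n + 1L)
    }
  }
  ## expected-value regime for heavily populated states
  big <- active[m[active] > exactMax]
  if (length(big)) {
    if (is.null(Dm)) Dm <- .daughterMatrix(n, scheme)
    d <- m[big] * q[big]
    mNew[big] <- mNew[big] + (m[big] - d)
    mNew <- mNew + drop(d %*% Dm[big, , drop = FALSE])
  }
  if (selectionOn && !sc$mutantMarker) mNew[1] <- 0   # mutant-only cells die
  if (dropNonCarrier) mNew[n + 1] <- 0                # lost the mutant: exits
  mNew
}

## binomial thinning of a state vector by 1/factor
.thinTwoSpecies <- function(m, factor, exactMax = 5000) {
  if (factor == 1) return(m)
  sm <- m > 0 & m <= .Machine$integer.max   # exact thinning is one draw/state
  m[sm] <- rbinom(sum(sm), round(m[sm]), 1 / factor)
  big <- !sm & m > 0
  m[big] <- m[big] / factor
  m
}

## steps per background-cell generation under the implicit background clock
.stepsPerGeneration <- function(backgroundFitness) 1 / backgroundFitness
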