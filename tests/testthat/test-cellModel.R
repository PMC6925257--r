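# Within-cell layer: additive fitness, replication to exact doubling under
# three schemes, even random segregation, and marker viability.

test_that("additive fitness matches the calibrated cost model", {
  m <- pqgsModel()
  none <- c(ancestral = 0, satellite = 0, deletion = 0)
  expect_identical(cellFitness(none, m), 1)
  expect_equal(cellFitness(c(ancestral = 0, satellite = 0, deletion = 18), m),
               0.910)
  expect_equal(cellFitness(c(ancestral = 18, satellite = 0, deletion = 0), m),
               1 - 18 * 0.0306)
  ## 5.2 full-length-plasmid cost units (the equilibrium mean)
  expect_equal(round(1 - 5.2 * 0.0306, 3), 0.841)
  expect_error(cellFitness(c(ancestral = -1, satellite = 0, deletion = 0), m),
               "negative")
})

test_that("fitness is monotone non-increasing in every costly count", {
  m <- pqgsModel()
  for (sp in c("ancestral", "deletion")) {
    w <- vapply(0:18, function(k) {
      cell <- c(ancestral = 0, satellite = 0, deletion = 0)
      cell[sp] <- k
      cellFitness(cell, m)
    }, 0)
    expect_true(all(diff(w) <= 0))
  }
})

test_that("fitness respects the configured floor", {
  m <- plasmidModel(data.frame(name = "heavy", autonomous = TRUE,
                               carriesMarker = TRUE, perCopyCost = 0.2),
                    copyNumber = 18L, floor = 0)
  expect_identical(cellFitness(c(heavy = 18), m), 0)
})

test_that("replication doubles exactly and needs replication machinery", {
  m <- pqgsModel()
  out <- replicatePlasmids(c(ancestral = 18, satellite = 0, deletion = 0), m)
  expect_identical(unname(out["ancestral"]), 36)
  expect_error(
    replicatePlasmids(c(ancestral = 0, satellite = 5, deletion = 0), m),
    class = "replicationImpossible")
  ## a deletion plasmid supplies machinery in trans for satellites
  set.seed(1)
  out <- replicatePlasmids(c(ancestral = 0, satellite = 3, deletion = 3), m,
                           scheme = "polya")
  expect_identical(sum(out), 12)
})

test_that("urn replication of (1 ancestral, 1 satellite) matches enumeration", {
  ## two sequential draws from the growing pool: exhaustive enumeration gives
  ## P(3,1) = P(2,2) = P(1,3) = 1/3 (Polya urn); the frozen pool gives the
  ## binomial 1/4, 1/2, 1/4
  m <- pqgsModel()
  cell <- c(ancestral = 1, satellite = 1, deletion = 0)
  nrep <- 30000
  set.seed(7)
  anc <- replicate(nrep, replicatePlasmids(cell, m, "polya")[["ancestral"]])
  freq <- tabulate(anc, 3)[c(1, 2, 3)] / nrep
  expect_gt(suppressWarnings(
    chisq.test(table(factor(anc, 1:3)), p = rep(1 / 3, 3))$p.value), 1e-4)
  anc2 <- replicate(nrep, replicatePlasmids(cell, m, "frozen")[["ancestral"]])
  expect_gt(suppressWarnings(
    chisq.test(table(factor(anc2, 1:3)), p = c(.25, .5, .25))$p.value), 1e-4)
})

test_that("urn replication preserves expected species fractions", {
  ## martingale property of equal replication chances, checked by Monte
  ## Carlo against the starting fraction for mixed cells
  m <- pqgsModel()
  set.seed(11)
  for (start in list(c(2, 1), c(3, 3), c(1, 5))) {
    cell <- c(ancestral = start[1], satellite = start[2], deletion = 0)
    anc <- replicate(4000, replicatePlasmids(cell, m, "polya")[["ancestral"]])
    expFrac <- start[1] / sum(start)
    se <- sd(anc / (2 * sum(start))) / sqrt(4000)
    expect_lt(abs(mean(anc) / (2 * sum(start)) - expFrac), 5 * se + 1e-12)
  }
})

test_that("segregation is even, conservative, and hypergeometric", {
  m <- pqgsModel()
  out <- segregatePlasmids(c(ancestral = 36, satellite = 0, deletion = 0), m)
  expect_identical(unname(out$daughter1["ancestral"]), 18)
  expect_error(segregatePlasmids(c(ancestral = 3, satellite = 0, deletion = 0), m),
               "even")
  set.seed(3)
  for (i in 1:20) {
    cell <- c(ancestral = 2 * sample(0:10, 1), satellite = 2 * sample(0:10, 1),
              deletion = 2 * sample(0:10, 1))
    if (sum(cell) == 0) next
    dd <- segregatePlasmids(cell, m)
    expect_identical(dd$daughter1 + dd$daughter2, cell)
    expect_identical(sum(dd$daughter1) * 2, sum(cell))
  }
  ## P(a daughter receives 0 ancestral) for parent (10 anc, 26 sat)
  pZero <- choose(26, 18) / choose(36, 18)
  parent <- c(ancestral = 10, satellite = 26, deletion = 0)
  set.seed(5)
  zeros <- replicate(40000, segregatePlasmids(parent, m)$daughter1[["ancestral"]] == 0)
  se <- sqrt(pZero * (1 - pZero) / 40000)
  expect_lt(abs(mean(zeros) - pZero), 5 * se)
})

test_that("viability requires a marker-bearing plasmid only under selection", {
  m <- pqgsModel()
  expect_false(isViable(c(ancestral = 0, satellite = 18, deletion = 0), m, TRUE))
  expect_true(isViable(c(ancestral = 1, satellite = 17, deletion = 0), m, TRUE))
  expect_true(isViable(c(ancestral = 0, satellite = 0, deletion = 0), m, FALSE))
  expect_true(isViable(c(ancestral = 0, satellite = 0, deletion = 1), m, TRUE))
})
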