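# Microhomology scanner: oracle equivalence, planted-repeat recovery,
# threshold arithmetic, overlap resolution, and circular invariances.
#
# Random nucleotide sequences are dense in qualifying near-repeats, so
# planted-repeat fixtures are checked locally (around the planted loci)
# and negative controls are rejection-sampled against the independent
# oracle over the relevant windows only.

test_that("scanner equals the brute-force oracle on random circular sequences", {
  for (seed in 1:6) {
    sq <- randomPlasmidSequence(150, gc = 0.5, seed = seed)
    got <- enumerateMicrohomologies(sq)
    want <- oracleScan(sq)
    expect_identical(matchKeys(got), matchKeys(want))
  }
  ## biased composition: spurious hits are much denser
  sq <- randomPlasmidSequence(130, gc = 0.2, seed = 99)
  expect_identical(matchKeys(enumerateMicrohomologies(sq)),
                   matchKeys(oracleScan(sq)))
  ## and with stricter params
  sq <- randomPlasmidSequence(150, gc = 0.5, seed = 123)
  p <- repeatParams(minLength = 9, maxIndels = 0, maxMismatches = 2,
                    minIdentity = 0.8)
  expect_identical(
    matchKeys(enumerateMicrohomologies(sq, p)),
    matchKeys(oracleScan(sq, minLen = 9, maxIndel = 0, maxMM = 2,
                         minIdent = 0.8)))
})

test_that("planted repeats meeting the parameters are always recovered", {
  specs <- list(list(len = 7, mm = 0, ind = 0),
                list(len = 12, mm = 0, ind = 0),
                list(len = 12, mm = 2, ind = 0),
                list(len = 10, mm = 2, ind = 1),
                list(len = 15, mm = 3, ind = 1))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    base <- randomPlasmidSequence(350, seed = 200 + i)
    planted <- plantRepeatPair(base, sp$len, 40, 200, mismatches = sp$mm,
                               indels = sp$ind, seed = 300 + i)
    truth <- attr(planted, "planted")
    hits <- enumerateMicrohomologies(planted)
    expect_true(coversPlanted(hits, truth),
                info = sprintf("len=%d mm=%d ind=%d", sp$len, sp$mm, sp$ind))
  }
})

test_that("identity thresholding keeps 8/2 (75%) and drops 8/3 (62.5%)", {
  base <- randomPlasmidSequence(320, seed = 41)
  near <- function(hits, posA, posB)
    hits[abs(hits$aStart - posA) <= 2 & abs(hits$bStart - posB) <= 2, ]
  kept <- plantRepeatPair(base, 8, 30, 170, mismatches = 2, indels = 0,
                          seed = 42)
  hitsK <- near(enumerateMicrohomologies(kept), 30, 170)
  expect_gte(nrow(hitsK), 1)
  dropped <- plantRepeatPair(base, 8, 30, 170, mismatches = 3, indels = 0,
                             seed = 43)
  hitsD <- near(enumerateMicrohomologies(dropped), 30, 170)
  ## any survivor here must owe its identity to flanking matches, never to
  ## the below-threshold 8-column core alone
  expect_true(nrow(hitsD) == 0 || all(hitsD$identity >= 0.75))
  expect_true(all(enumerateMicrohomologies(dropped)$identity >= 0.75))
})

test_that("a 12-column repeat with 1 indel + 2 substitutions sits at the 0.75 boundary", {
  base <- randomPlasmidSequence(350, seed = 51)
  planted <- plantRepeatPair(base, 12, 60, 220, mismatches = 3, indels = 1,
                             seed = 52)
  truth <- attr(planted, "planted")
  expect_equal(truth$identity, 0.75)
  hits <- enumerateMicrohomologies(planted)
  expect_true(coversPlanted(hits, truth))
})

test_that("N never matches", {
  s <- paste0("ACGTACGTAA", strrep("N", 20), "ACGTACGTAA", strrep("N", 20))
  hits <- enumerateMicrohomologies(s)
  expect_gte(nrow(hits), 1)           # the two planted 10-mers
  sN <- gsub("ACGTACGTAA", "NNNNNNNNNN", s)
  expect_identical(nrow(enumerateMicrohomologies(sN)), 0L)
})

test_that("sequences shorter than the minimum length yield no matches", {
  expect_identical(nrow(enumerateMicrohomologies("ACGTA")), 0L)
})

test_that("rotation of the circle preserves the match multiset", {
  sq <- as.character(randomPlasmidSequence(150, seed = 55))
  rot <- paste0(substr(sq, 41, 150), substr(sq, 1, 40))
  sig <- function(df) sort(paste(df$length, df$mismatches, df$indels, sep = ":"))
  expect_identical(sig(enumerateMicrohomologies(sq)),
                   sig(enumerateMicrohomologies(rot)))
})

test_that("overlap resolution prefers longer matches, then fewer mismatches", {
  mk <- function(aS, aE, bS, bE, len, mm, ind = 0)
    data.frame(aStart = aS, aEnd = aE, bStart = bS, bEnd = bE,
               length = len, mismatches = mm, indels = ind,
               identity = (len - mm) / len)
  two <- rbind(mk(0, 9, 100, 109, 9, 0), mk(300, 307, 500, 507, 7, 0))
  attr(two, "seqLength") <- 1000L
  expect_identical(nrow(resolveOverlaps(two)), 2L)
  ## a 9-mer and an overlapping 7-mer: only the 9-mer survives
  ovl <- rbind(mk(0, 9, 100, 109, 9, 0), mk(2, 9, 300, 307, 7, 0))
  attr(ovl, "seqLength") <- 1000L
  expect_identical(resolveOverlaps(ovl)$length, 9)
  ## equal length: the 1-mismatch match beats the 3-mismatch match
  tie <- rbind(mk(2, 10, 300, 308, 8, 3), mk(0, 8, 305, 313, 8, 1))
  attr(tie, "seqLength") <- 1000L
  kept <- resolveOverlaps(tie)
  expect_identical(kept$mismatches, 1)
  ## input order cannot change the outcome
  tieRev <- tie[2:1, ]
  attr(tieRev, "seqLength") <- 1000L
  expect_identical(resolveOverlaps(tieRev)$mismatches, 1)
})

test_that("resolved output is overlap-free on a dense random sequence", {
  sq <- randomPlasmidSequence(300, gc = 0.15, seed = 77)
  res <- resolveOverlaps(enumerateMicrohomologies(sq))
  L <- attr(res, "seqLength")
  expect_gte(nrow(res), 1)
  if (nrow(res) > 1) {
    starts <- c(res$aStart, res$bStart)
    widths <- c(res$aEnd - res$aStart, res$bEnd - res$bStart)
    grp <- rep(seq_len(nrow(res)), 2)   # loci of one match may touch
    bad <- FALSE
    for (i in seq_along(starts)) for (k in seq_along(starts))
      if (grp[i] != grp[k] &&
          satdyn:::.circOverlaps(starts[i], widths[i], starts[k], widths[k], L))
        bad <- TRUE
    expect_false(bad)
  }
})

test_that("cross-region counts see planted cross pairs and are monotone in length", {
  L <- 600
  base <- randomPlasmidSequence(L, seed = 13)
  s1 <- plantRepeatPair(base, 15, 20, 300, seed = 14)
  s2 <- plantRepeatPair(s1, 14, 60, 360, seed = 15)
  s3 <- plantRepeatPair(s2, 13, 100, 420, seed = 16)
  regA <- data.frame(start = 10, end = 130)
  regB <- data.frame(start = 290, end = 450)
  res <- resolveOverlaps(enumerateMicrohomologies(s3))
  expect_gte(countCrossRegionRepeats(res, regA, regB), 3)
  ## a match with both loci inside one region does not count
  inOne <- data.frame(aStart = 15, aEnd = 25, bStart = 40, bEnd = 50,
                      length = 10, mismatches = 0, indels = 0, identity = 1)
  attr(inOne, "seqLength") <- L
  expect_identical(countCrossRegionRepeats(inOne, regA, regB), 0L)
  ## monotone non-increasing counts over sliding length thresholds
  counts <- vapply(7:15, function(minLen) {
    hits <- enumerateMicrohomologies(s3, repeatParams(minLength = minLen))
    as.integer(countCrossRegionRepeats(resolveOverlaps(hits), regA, regB))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("junction annotation finds the engineered flanking repeat", {
  ## fixture: a base sequence whose junction windows hold no qualifying
  ## repeat; rejection-sampled with the fast scanner, then the chosen
  ## fixture is confirmed once with the independent oracle
  seed <- 500
  repeat {
    base <- randomPlasmidSequence(200, seed = seed)
    if (is.null(annotateJunctionHomology(base, 60, 140))) break
    seed <- seed + 1
  }
  hits <- oracleScan(base)
  win <- 20
  inWinA <- (hits$aStart >= 60 - win & hits$aStart <= 60 + win) |
            (hits$bStart >= 60 - win & hits$bStart <= 60 + win)
  inWinB <- (hits$aEnd >= 140 - win & hits$aEnd <= 140 + win) |
            (hits$bEnd >= 140 - win & hits$bEnd <= 140 + win)
  expect_false(any(inWinA & inWinB))
  expect_null(annotateJunctionHomology(base, 60, 140))
  planted <- plantRepeatPair(base, 9, 55, 140, mismatches = 0, indels = 0,
                             seed = 1000 + seed)
  ann <- annotateJunctionHomology(planted, 60, 140)
  expect_false(is.null(ann))
  expect_gte(ann$length, 9)
})
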