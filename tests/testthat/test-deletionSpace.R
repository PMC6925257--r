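# Deletion-space combinatorics: classifiers, closed-form counts against the
# brute-force oracle, circular invariances, and the rate ratio.

toyMap <- function(L = 60, shift = 0) {
  f <- data.frame(name = c("oriV", "rep", "aadA", "gfp"),
                  role = c("origin", "rep_gene", "marker", "accessory"),
                  start = (c(0, 10, 25, 35) + shift) %% L,
                  end = NA)
  f$end <- f$start + c(6, 10, 5, 15)
  plasmidMap(L, data.frame(name = f$name, role = f$role, start = f$start,
                           width = c(6, 10, 5, 15)))
}

test_that("SP classifier clauses hold on the toy map", {
  map <- toyMap()
  ## arc covering accessory + marker + part of rep, sparing the origin
  expect_true(isSpDeletion(15, 52, map))
  ## no rep base clipped
  expect_false(isSpDeletion(21, 52, map))
  ## origin clipped
  expect_false(isSpDeletion(15, 2, map))
  ## marker not fully contained
  expect_false(isSpDeletion(27, 52, map))
})

test_that("DP classifier clauses hold on the toy map", {
  map <- toyMap()
  ## clips the accessory, spares the protected backbone arc
  expect_true(isDpDeletion(35, 45, map))
  expect_true(isDpDeletion(40, 50, map))
  ## nicks the marker
  expect_false(isDpDeletion(29, 45, map))
  ## no accessory base removed
  expect_false(isDpDeletion(51, 58, map))
})

test_that("a two-accessory map requires clipping every accessory gene", {
  f <- data.frame(name = c("oriV", "repA", "aadA", "lacI", "gfp"),
                  role = c("origin", "rep_gene", "marker", "accessory",
                           "accessory"),
                  start = c(0, 10, 25, 33, 44),
                  end = c(6, 20, 30, 40, 52))
  map <- plasmidMap(60, f)
  expect_true(isDpDeletion(36, 46, map))    # part of lacI and part of gfp
  expect_false(isDpDeletion(34, 42, map))   # lacI only
  expect_false(isDpDeletion(45, 50, map))   # gfp only
})

test_that("closed-form counts equal brute-force enumeration", {
  map <- toyMap()
  expect_identical(countDeletionSpace(map, "sp"), bruteDeletionCount(map, "sp"))
  expect_identical(countDeletionSpace(map, "dp"), bruteDeletionCount(map, "dp"))
  ## the canonical layout factorizes into (valid starts) x (valid ends)
  expect_identical(countDeletionSpace(map, "sp"), 154L)   # 14 starts x 11 ends
  ## maps with multiple rep genes and accessories, including a wrapping one
  f <- data.frame(name = c("ori", "repA", "repB", "mark", "acc1", "acc2"),
                  role = c("origin", "rep_gene", "rep_gene", "marker",
                           "accessory", "accessory"),
                  start = c(5, 14, 24, 36, 48, 66),
                  width = c(6, 8, 8, 8, 10, 12))
  map2 <- plasmidMap(80, f)
  expect_identical(countDeletionSpace(map2, "sp"), bruteDeletionCount(map2, "sp"))
  expect_identical(countDeletionSpace(map2, "dp"), bruteDeletionCount(map2, "dp"))
})

test_that("counts are invariant under rotation of the map", {
  for (shift in c(7, 23, 41)) {
    expect_identical(countDeletionSpace(toyMap(shift = shift), "sp"),
                     countDeletionSpace(toyMap(), "sp"))
    expect_identical(countDeletionSpace(toyMap(shift = shift), "dp"),
                     countDeletionSpace(toyMap(), "dp"))
  }
})

test_that("SP and DP arc sets are disjoint", {
  map <- toyMap()
  L <- plasmidLength(map)
  grid <- expand.grid(s = 0:(L - 1), e = 0:(L - 1))
  grid <- grid[grid$s != grid$e, ]
  both <- isSpDeletion(grid$s, grid$e, map) & isDpDeletion(grid$s, grid$e, map)
  expect_false(any(both))
})

test_that("a map without accessory genes has an empty DP space", {
  f <- data.frame(name = c("oriV", "rep", "aadA"),
                  role = c("origin", "rep_gene", "marker"),
                  start = c(0, 10, 25), end = c(6, 20, 30))
  map <- plasmidMap(60, f)
  expect_identical(countDeletionSpace(map, "dp"), 0L)
  expect_error(spDpRateRatio(map), class = "undefinedRatio")
})

test_that("the rate ratio scales with the endpoint-window product", {
  ## stretching the free arcs scales starts x ends for both classes; the
  ## ratio follows the product formula
  mk <- function(scale) {
    plasmidMap(60 * scale, data.frame(
      name = c("oriV", "rep", "aadA", "gfp"),
      role = c("origin", "rep_gene", "marker", "accessory"),
      start = c(0, 10, 25, 35) * scale,
      end = c(6, 20, 30, 50) * scale))
  }
  m1 <- mk(1); m2 <- mk(2)
  sp1 <- countDeletionSpace(m1, "sp"); dp1 <- countDeletionSpace(m1, "dp")
  sp2 <- countDeletionSpace(m2, "sp"); dp2 <- countDeletionSpace(m2, "dp")
  ## SP endpoint windows both doubled: count x4 (up to boundary rounding)
  expect_equal(sp2 / sp1, 4, tolerance = 0.15)
  expect_equal(spDpRateRatio(m2) / spDpRateRatio(m1),
               (sp2 / sp1) / (dp2 / dp1), tolerance = 1e-9)
})

test_that("endpoint regions match the set of classified arcs", {
  map <- toyMap()
  er <- endpointRegions(map, "sp")
  L <- plasmidLength(map)
  grid <- expand.grid(s = 0:(L - 1), e = 0:(L - 1))
  grid <- grid[grid$s != grid$e, ]
  ok <- isSpDeletion(grid$s, grid$e, map)
  starts <- sort(unique(grid$s[ok]))
  inRegion <- function(pos, iv)
    any(((pos - iv$start) %% L) < ((iv$end - iv$start - 1) %% L + 1))
  expect_true(all(vapply(starts, inRegion, TRUE, iv = er$startRegion)))
  ends <- sort(unique(grid$e[ok]))
  expect_true(all(vapply(ends, inRegion, TRUE, iv = er$endRegion)))
  ## and nothing outside
  outside <- setdiff(0:(L - 1), starts)
  expect_false(any(vapply(outside, inRegion, TRUE, iv = er$startRegion)))
})

test_that("toy maps from the generator satisfy the classifiers' expectations", {
  map <- makeToyPlasmidMap(300)
  expect_identical(countDeletionSpace(map, "sp"), bruteDeletionCount(map, "sp"))
  expect_identical(countDeletionSpace(map, "dp"), bruteDeletionCount(map, "dp"))
  expect_gt(spDpRateRatio(map), 0)
  noAcc <- makeToyPlasmidMap(300, nAccessory = 0)
  expect_identical(countDeletionSpace(noAcc, "dp"), 0L)
})
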