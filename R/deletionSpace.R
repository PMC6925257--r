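## Combinatorics of deletion opportunities on an annotated circular plasmid:
## which (start, end) arcs produce a satellite plasmid (SP) versus an
## accessory-gene deletion plasmid (DP), counted at base resolution.
##
## An SP deletion removes every accessory gene and the marker entirely,
## clips at least one base of a replication gene, and leaves the origin
## untouched: the residual plasmid keeps oriV but loses autonomy. A DP
## deletion removes at least one base of every accessory gene while leaving
## the whole backbone arc from the origin through the replication genes to
## the marker intact, so the plasmid stays autonomous and selectable.

## relative position of feature starts to an arc start: u = (fs - s) mod L
## arc [s, s+w) contains feature (fs, fw)  iff  u + fw <= w
## arc avoids feature                      iff  w <= u and u <= L - fw
## arc overlaps feature                    iff  u < w or u > L - fw

#' Classify a deletion on a plasmid map
#'
#' `isSpDeletion()` tests whether removing the arc `[start, end)` yields a
#' satellite plasmid: the arc contains every `accessory` and every `marker`
#' feature entirely, overlaps at least one base of a `rep_gene`, and does
#' not touch any `origin` base. `isDpDeletion()` tests for an accessory-gene
#' deletion plasmid: the arc overlaps at least one base of every `accessory`
#' feature and does not touch the protected backbone arc (the arc spanning
#' origin, replication genes and marker that does not contain the accessory
#' genes).
#'
#' @param start,end 0-based half-open endpoints of the removed arc (vectors
#'   are recycled together).
#' @param map a [PlasmidMap-class].
#' @return logical vector.
#' @export
isSpDeletion <- function(start, end, map) {
  L <- plasmidLength(map)
  w <- (end - start - 1) %% L + 1
  s <- start %% L
  ft <- plasmidFeatures(map)
  ok <- w >= 1 & w <= L - 1
  for (i in which(ft$role %in% c("accessory", "marker"))) {
    u <- (ft$start[i] - s) %% L
    ok <- ok & (u + ft$width[i] <= w)
  }
  for (i in which(ft$role == "origin")) {
    u <- (ft$start[i] - s) %% L
    ok <- ok & (w <= u & u <= L - ft$width[i])
  }
  repHit <- rep(FALSE, length(ok))
  for (i in which(ft$role == "rep_gene")) {
    u <- (ft$start[i] - s) %% L
    repHit <- repHit | (u < w | u > L - ft$width[i])
  }
  ok & repHit
}

## the protected backbone arc: minimal arc covering all origin/rep_gene/
## marker features that contains no accessory feature. Computed as the
## complement of the widest gap between consecutive protected features that
## holds all accessory features.
.protectedArc <- function(map) {
  ft <- plasmidFeatures(map)
  prot <- ft[ft$role %in% c("origin", "rep_gene", "marker"), , drop = FALSE]
  if (nrow(prot) == 0) return(NULL)
  L <- plasmidLength(map)
  ord <- order(prot$start)
  starts <- prot$start[ord]
  ends <- (prot$start + prot$width)[ord]
  ## gaps between consecutive protected features around the circle
  gapFrom <- ends
  gapTo <- c(starts[-1], starts[1] + L)
  gapW <- (gapTo - gapFrom) %% L
  acc <- ft[ft$role == "accessory", , drop = FALSE]
  inGap <- vapply(seq_along(gapFrom), function(i) {
    if (gapW[i] <= 0) return(FALSE)
    all(((acc$start - gapFrom[i]) %% L) + acc$width <= gapW[i]) || nrow(acc) == 0
  }, TRUE)
  pick <- which(inGap)[which.max(gapW[inGap])]
  if (length(pick) == 0) pick <- which.max(gapW)
  ## protected arc = complement of the chosen gap
  arcStart <- gapTo[pick] %% L
  arcWidth <- L - gapW[pick]
  c(start = arcStart, width = arcWidth)
}

#' @rdname isSpDeletion
#' @export
isDpDeletion <- function(start, end, map) {
  L <- plasmidLength(map)
  w <- (end - start - 1) %% L + 1
  s <- start %% L
  ft <- plasmidFeatures(map)
  acc <- which(ft$role == "accessory")
  if (length(acc) == 0) return(rep(FALSE, length(s)))
  ok <- w >= 1 & w <= L - 1
  for (i in acc) {   # clip at least one base of every accessory gene
    u <- (ft$start[i] - s) %% L
    ok <- ok & (u < w | u > L - ft$width[i])
  }
  pa <- .protectedArc(map)
  if (!is.null(pa)) {
    u <- (pa["start"] - s) %% L
    ok <- ok & (w <= u & u <= L - pa["width"])
  }
  ok
}

#' Count the deletion space of a plasmid map
#'
#' Counts all (start, end) base-resolution coordinate combinations on the
#' circle whose removed arc satisfies a deletion classifier. The count is
#' computed in closed form from region boundaries: for every start the set
#' of valid arc widths is a contiguous interval derived from the
#' containment, avoidance and overlap constraints, so the total is a sum of
#' interval lengths (verified against brute-force enumeration in the test
#' suite).
#'
#' @param map a [PlasmidMap-class].
#' @param classifier `"sp"`, `"dp"`, or a function `(start, end, map)`
#'   returning a logical.
#' @return integer count of (start, end) combinations.
#' @export
countDeletionSpace <- function(map, classifier = c("sp", "dp")) {
  if (is.function(classifier)) {
    L <- plasmidLength(map)
    grid <- expand.grid(s = 0:(L - 1), e = 0:(L - 1))
    grid <- grid[grid$s != grid$e, ]
    return(sum(classifier(grid$s, grid$e, map)))
  }
  classifier <- match.arg(classifier)
  b <- .validWidthBounds(map, classifier)
  if (is.null(b)) return(0L)
  as.integer(sum(pmax(0, b$hi - b$lo + 1)))
}

## per-start interval of valid arc widths [lo, hi] for a deletion class
.validWidthBounds <- function(map, classifier) {
  L <- plasmidLength(map)
  ft <- plasmidFeatures(map)
  s <- 0:(L - 1)
  lo <- rep(1, L); hi <- rep(L - 1, L)
  bound <- function(lo, hi, type, fs, fw) {
    u <- (fs - s) %% L
    switch(type,
      contain = lo <- pmax(lo, u + fw),
      avoid   = { hi <- pmin(hi, u); hi[u > L - fw] <- 0 },
      overlap = { lo2 <- u + 1; lo2[u > L - fw] <- 1; lo <- pmax(lo, lo2) })
    list(lo = lo, hi = hi)
  }
  if (classifier == "sp") {
    for (i in which(ft$role %in% c("accessory", "marker"))) {
      b <- bound(lo, hi, "contain", ft$start[i], ft$width[i]); lo <- b$lo; hi <- b$hi
    }
    for (i in which(ft$role == "origin")) {
      b <- bound(lo, hi, "avoid", ft$start[i], ft$width[i]); lo <- b$lo; hi <- b$hi
    }
    ## at least one rep gene overlapped: per start, the weakest lower bound
    reps <- which(ft$role == "rep_gene")
    if (length(reps) == 0) return(NULL)
    loRep <- rep(Inf, L)
    for (i in reps) {
      u <- (ft$start[i] - s) %% L
      cand <- u + 1; cand[u > L - ft$width[i]] <- 1
      loRep <- pmin(loRep, cand)
    }
    lo <- pmax(lo, loRep)
  } else {
    acc <- which(ft$role == "accessory")
    if (length(acc) == 0) return(NULL)
    for (i in acc) {
      b <- bound(lo, hi, "overlap", ft$start[i], ft$width[i]); lo <- b$lo; hi <- b$hi
    }
    pa <- .protectedArc(map)
    if (!is.null(pa)) {
      b <- bound(lo, hi, "avoid", pa["start"], pa["width"]); lo <- b$lo; hi <- b$hi
    }
  }
  list(lo = pmax(lo, 1), hi = pmin(hi, L - 1))
}

#' Ratio of satellite-forming to accessory-deletion opportunities
#'
#' The number of deletion start-end combinations producing a satellite
#' plasmid divided by the number producing an accessory-gene deletion
#' plasmid: the mutational-target-size bias favoring satellite plasmids.
#'
#' @param map a [PlasmidMap-class].
#' @return numeric ratio.
#' @export
spDpRateRatio <- function(map) {
  dp <- countDeletionSpace(map, "dp")
  if (dp == 0)
    stop(structure(class = c("undefinedRatio", "error", "condition"),
                   list(message = "no DP-forming deletions on this map",
                        call = sys.call())))
  countDeletionSpace(map, "sp") / dp
}

#' Deletion endpoint regions of a plasmid map
#'
#' The sets of start and end positions over all deletions of a class,
#' returned as circular intervals (0-based half-open) for use as the region
#' arguments of [countCrossRegionRepeats()] or for export to a BED-like
#' file.
#'
#' @param map a [PlasmidMap-class].
#' @param classifier `"sp"` or `"dp"`.
#' @return list with data.frames `startRegion` and `endRegion`.
#' @export
endpointRegions <- function(map, classifier = c("sp", "dp")) {
  classifier <- match.arg(classifier)
  L <- plasmidLength(map)
  b <- .validWidthBounds(map, classifier)
  empty <- data.frame(start = integer(), end = integer())
  if (is.null(b)) return(list(startRegion = empty, endRegion = empty))
  valid <- b$hi >= b$lo
  startFlag <- valid
  ## end positions e = (s + w) mod L for w in [lo, hi]: circular diff array
  dif <- numeric(L)
  for (s in which(valid) - 1L) {
    from <- (s + b$lo[s + 1]) %% L
    len <- b$hi[s + 1] - b$lo[s + 1] + 1
    dif[from + 1] <- dif[from + 1] + 1
    stopAt <- from + len
    if (stopAt < L) dif[stopAt + 1] <- dif[stopAt + 1] - 1
    else if (stopAt > L) { dif[1] <- dif[1] + 1; dif[stopAt - L + 1] <- dif[stopAt - L + 1] - 1 }
  }
  endFlag <- cumsum(dif) > 0
  toIntervals <- function(flag) {
    if (!any(flag)) return(empty)
    ## merge circular runs
    r <- rle(flag)
    idx <- cumsum(c(1, r$lengths))
    iv <- data.frame(start = idx[-length(idx)][r$values] - 1,
                     end = (idx[-1][r$values]) - 1)
    if (nrow(iv) > 1 && flag[1] && flag[L]) {   # wrap: merge first and last
      iv$start[1] <- iv$start[nrow(iv)] - L
      iv <- iv[-nrow(iv), , drop = FALSE]
    }
    iv$start <- iv$start %% L
    iv
  }
  list(startRegion = toIntervals(startFlag), endRegion = toIntervals(endFlag))
}
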