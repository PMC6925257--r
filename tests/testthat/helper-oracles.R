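# Independent oracles used across the suite. These re-derive expected
# results from first principles (direct enumeration, naive alignment,
# eigen analysis of the exact state chain) without touching the package's
# implementation paths.

## ---------------------------------------------------------------------
## Brute-force microhomology oracle: enumerate every candidate alignment
## (all starts, all offsets, all ends, all single-gap placements) by
## column-wise comparison, keep the valid ones, then filter to
## containment-maximal locus pairs and deduplicate identical pairs by
## score. Only intended for sequences up to a few hundred bases.
## ---------------------------------------------------------------------
oracleScan <- function(sequence, minLen = 7, maxIndel = 1, maxMM = 5,
                       minIdent = 0.75) {
  chars <- strsplit(toupper(as.character(sequence)), "")[[1]]
  L <- length(chars)
  base <- match(chars, c("A", "C", "G", "T"))
  base[is.na(base)] <- 99L
  eq <- function(i, j) {
    a <- base[(i %% L) + 1]; b <- base[(j %% L) + 1]
    a < 5 & b < 5 & a == b
  }
  cand <- list()
  add <- function(s1, l1, s2, l2, cols, mm, ind) {
    if (s2 < s1) { tmp <- s1; s1 <- s2; s2 <- tmp; tmp <- l1; l1 <- l2; l2 <- tmp }
    cand[[length(cand) + 1]] <<- c(s1, l1, s2, l2, cols, mm, ind)
  }
  valid <- function(cols, mm)
    cols >= minLen && mm <= maxMM && (cols - mm) + 1e-9 >= minIdent * cols
  for (d in 1:(L - 1)) {
    cap <- L - d
    for (p in 0:(L - 1)) {
      if (!eq(p, p + d)) next
      ## ungapped alignments: only the furthest valid end needs keeping
      ## (shorter ends from the same start are nested within it)
      mm <- 0; best <- NULL
      for (t in 0:(cap - 1)) {
        if (!eq(p + t, p + d + t)) mm <- mm + 1
        if (mm > maxMM) break
        if (eq(p + t, p + d + t) && valid(t + 1, mm)) best <- c(t, mm)
      }
      if (!is.null(best))
        add(p %% L, best[1] + 1, (p + d) %% L, best[1] + 1, best[1] + 1,
            best[2], 0)
      ## single gap in the second copy after g prefix columns
      if (maxIndel >= 1) {
        for (g in 1:(cap - 2)) {
          pmm <- if (g >= 2) sum(!eq(p + 1:(g - 1), p + d + 1:(g - 1))) else 0
          if (pmm + 1 > maxMM) break
          mm <- pmm + 1
          scap <- cap - 1 - g
          if (scap < 1) next
          best <- NULL
          for (t in 0:(scap - 1)) {
            if (!eq(p + g + t, p + d + 1 + g + t)) mm <- mm + 1
            if (mm > maxMM) break
            cols <- g + 1 + t + 1
            if (eq(p + g + t, p + d + 1 + g + t) && valid(cols, mm))
              best <- c(t, mm)
          }
          if (!is.null(best))
            add(p %% L, g + best[1] + 1, (p + d) %% L, g + best[1] + 2,
                g + 1 + best[1] + 1, best[2], 1)
        }
      }
    }
  }
  if (!length(cand))
    return(data.frame(aStart = integer(), aEnd = integer(), bStart = integer(),
                      bEnd = integer(), length = integer(),
                      mismatches = integer(), indels = integer()))
  m <- do.call(rbind, cand)
  colnames(m) <- c("s1", "l1", "s2", "l2", "cols", "mm", "ind")
  m <- m[order(-m[, "cols"], m[, "mm"], m[, "ind"], m[, "s1"], m[, "s2"],
               m[, "l1"], m[, "l2"]), , drop = FALSE]
  contains <- function(as, al, bs, bl)   # locus b within locus a, circular
    ((bs - as) %% L) + bl <= al
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    if (!keep[i]) next
    for (k in seq_len(i - 1)) {
      if (!keep[k]) next
      straight <- contains(m[k, "s1"], m[k, "l1"], m[i, "s1"], m[i, "l1"]) &&
                  contains(m[k, "s2"], m[k, "l2"], m[i, "s2"], m[i, "l2"])
      crossed <- contains(m[k, "s2"], m[k, "l2"], m[i, "s1"], m[i, "l1"]) &&
                 contains(m[k, "s1"], m[k, "l1"], m[i, "s2"], m[i, "l2"])
      if (straight || crossed) { keep[i] <- FALSE; break }
    }
  }
  m <- m[keep, , drop = FALSE]
  out <- data.frame(aStart = m[, "s1"], aEnd = m[, "s1"] + m[, "l1"],
                    bStart = m[, "s2"], bEnd = m[, "s2"] + m[, "l2"],
                    length = m[, "cols"], mismatches = m[, "mm"],
                    indels = m[, "ind"])
  attr(out, "seqLength") <- L
  out
}

## normalized key set for comparing two match tables
matchKeys <- function(df)
  sort(sprintf("%d:%d:%d:%d:%d:%d:%d", df$aStart, df$aEnd, df$bStart,
               df$bEnd, df$length, df$mismatches, df$indels))

## ---------------------------------------------------------------------
## Brute-force deletion-space counter: test every (start, end) pair with
## a from-scratch circular-arithmetic classifier.
## ---------------------------------------------------------------------
bruteDeletionCount <- function(map, class = c("sp", "dp")) {
  class <- match.arg(class)
  L <- plasmidLength(map)
  ft <- plasmidFeatures(map)
  inArc <- function(pos, s, w) ((pos - s) %% L) < w       # base inside arc
  featBases <- function(i) (ft$start[i] + seq_len(ft$width[i]) - 1) %% L
  protArc <- NULL
  if (class == "dp") {
    ## protected backbone arc: walk from each protected feature and take the
    ## minimal arc covering all origin/rep/marker bases with no accessory base
    protBases <- unlist(lapply(which(ft$role %in% c("origin", "rep_gene", "marker")),
                               featBases))
    accBases <- unlist(lapply(which(ft$role == "accessory"), featBases))
    best <- NULL
    for (s in unique(protBases)) {
      offs <- sort((protBases - s) %% L)
      w <- max(offs) + 1
      if (!any(((accBases - s) %% L) < w)) {
        if (is.null(best) || w < best[2]) best <- c(s, w)
      }
    }
    protArc <- best
  }
  n <- 0L
  for (s in 0:(L - 1)) for (w in 1:(L - 1)) {
    arcHasAll <- function(i) all(inArc(featBases(i), s, w))
    arcHasAny <- function(i) any(inArc(featBases(i), s, w))
    ok <- if (class == "sp") {
      all(vapply(which(ft$role %in% c("accessory", "marker")), arcHasAll, TRUE)) &&
        !any(vapply(which(ft$role == "origin"), arcHasAny, TRUE)) &&
        any(vapply(which(ft$role == "rep_gene"), arcHasAny, TRUE))
    } else {
      length(which(ft$role == "accessory")) > 0 &&
        all(vapply(which(ft$role == "accessory"), arcHasAny, TRUE)) &&
        (is.null(protArc) ||
           !any(inArc((protArc[1] + seq_len(protArc[2]) - 1) %% L, s, w)))
    }
    if (ok) n <- n + 1L
  }
  n
}

## ---------------------------------------------------------------------
## Mean-field oracle for the two-species chain: expected daughter matrix
## built from the hypergeometric law, equilibrium fitness and composition
## from the leading eigenpair of the per-step operator.
## ---------------------------------------------------------------------
eigenEquilibrium <- function(costAnc = 0.0306, costMut = 0, n = 18,
                             mutantAutonomous = FALSE, mutantMarker = FALSE,
                             dropNonCarrier = FALSE) {
  D <- matrix(0, n + 1, n + 1)
  for (j in 0:n)
    D[j + 1, ] <- 2 * dhyper(0:n, 2 * j, 2 * n - 2 * j, n)
  w <- pmax(0, 1 - (0:n) * costAnc - (n:0) * costMut)
  q <- w
  if (!mutantAutonomous) q[1] <- 0
  A <- t(D) %*% diag(q) + diag(1 - q)
  if (!mutantMarker) A[1, ] <- 0
  if (dropNonCarrier) A[n + 1, ] <- 0
  ev <- eigen(A)
  i <- which.max(Re(ev$values))
  v <- abs(Re(ev$vectors[, i])); v <- v / sum(v)
  list(fitness = Re(ev$values[i]) - 1,
       meanAncestral = sum((0:n) * v),
       meanMutant = n - sum((0:n) * v),
       distribution = v)
}

## does any match cover a planted locus pair (either orientation)?
coversPlanted <- function(hits, truth) {
  any((hits$aStart <= truth$aStart & hits$aEnd >= truth$aEnd &
       hits$bStart <= truth$bStart & hits$bEnd >= truth$bEnd) |
      (hits$aStart <= truth$bStart & hits$aEnd >= truth$bEnd &
       hits$bStart <= truth$aStart & hits$bEnd >= truth$aEnd))
}

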