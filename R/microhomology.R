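## Microhomology scan: near-perfect direct repeats on a circular plasmid
## sequence, overlap resolution, cross-region counting, and junction
## annotation of observed deletions.

#' Repeat search parameters
#'
#' The filter applied to candidate repeat alignments: minimum alignment
#' length (columns), at most one inserted or deleted base, a cap on total
#' mismatches (indels included), and a minimum identity
#' `matches / alignment columns`.
#'
#' @param minLength minimum alignment length in columns (default 7).
#' @param maxIndels maximum indels per alignment (0 or 1; default 1).
#' @param maxMismatches maximum mismatch columns including indels (default 5).
#' @param minIdentity minimum identity fraction (default 0.75).
#' @return a list of class `repeatParams`.
#' @export
repeatParams <- function(minLength = 7, maxIndels = 1, maxMismatches = 5,
                         minIdentity = 0.75) {
  stopifnot(minLength >= 1, minIdentity >= 0, minIdentity <= 1,
            maxIndels %in% 0:1, maxIndels <= maxMismatches)
  structure(list(minLength = as.integer(minLength),
                 maxIndels = as.integer(maxIndels),
                 maxMismatches = as.integer(maxMismatches),
                 minIdentity = minIdentity),
            class = "repeatParams")
}

## encode a sequence (character / DNAString) as integer codes A,C,G,T = 0..3
.encodeSeq <- function(sequence) {
  if (is(sequence, "XString") || is(sequence, "XStringSet"))
    sequence <- as.character(sequence)
  if (length(sequence) != 1L) stop("provide a single circular sequence")
  chars <- strsplit(toupper(sequence), "")[[1]]
  codes <- match(chars, c("A", "C", "G", "T")) - 1L
  codes[is.na(codes)] <- 4L   # N and anything else: never matches
  codes
}

#' Enumerate microhomologies on a circular sequence
#'
#' Finds every containment-maximal pair of same-strand loci whose best
#' banded alignment (at most one indel) passes the [repeatParams()] filter.
#' Coordinates are 0-based half-open on the circle; a locus may wrap, in
#' which case its end exceeds the sequence length. Identity is
#' `matches / alignment columns`, an indel column counting as a non-match.
#'
#' @param sequence circular nucleotide sequence (character string or
#'   `Biostrings::DNAString`); alphabet ACGTN, N never matches.
#' @param params a [repeatParams()] list.
#' @return data.frame with columns `aStart`, `aEnd`, `bStart`, `bEnd`
#'   (0-based half-open), `length` (alignment columns), `mismatches`
#'   (including indels), `indels`, `identity`, sorted by length (desc) then
#'   mismatches; attribute `seqLength`.
#' @examples
#' seq <- paste(rep("ACGT", 20), collapse = "")  # highly repetitive toy
#' hits <- enumerateMicrohomologies(randomPlasmidSequence(300, seed = 1))
#' @export
enumerateMicrohomologies <- function(sequence, params = repeatParams()) {
  codes <- .encodeSeq(sequence)
  L <- length(codes)
  if (L < params$minLength) {
    out <- data.frame(aStart = integer(), aEnd = integer(), bStart = integer(),
                      bEnd = integer(), length = integer(),
                      mismatches = integer(), indels = integer(),
                      identity = numeric())
    attr(out, "seqLength") <- L
    return(out)
  }
  raw <- .scanRepeats(codes, params$minLength, params$maxIndels,
                      params$maxMismatches, params$minIdentity)
  out <- data.frame(aStart = raw$aStart, aEnd = raw$aStart + raw$aWidth,
                    bStart = raw$bStart, bEnd = raw$bStart + raw$bWidth,
                    length = raw$length, mismatches = raw$mismatches,
                    indels = raw$indels,
                    identity = (raw$length - raw$mismatches) / raw$length)
  attr(out, "seqLength") <- L
  out
}

## circular interval overlap: [s1, s1+l1) vs [s2, s2+l2) on a circle of size L
.circOverlaps <- function(s1, l1, s2, l2, L) {
  ((s2 - s1) %% L) < l1 | ((s1 - s2) %% L) < l2
}

## circular containment: inner within outer
.circContains <- function(outerS, outerL, innerS, innerL, L) {
  ((innerS - outerS) %% L) + innerL <= outerL
}

#' Resolve overlapping repeat matches
#'
#' When several valid alignments overlap, only one is counted: matches are
#' ranked by alignment length (longer first), then by mismatches (fewer
#' first), then by coordinates as a deterministic tie-break, and kept
#' greedily when neither locus overlaps a locus of an already-kept match.
#'
#' @param matches data.frame from [enumerateMicrohomologies()].
#' @param seqLength circle size (taken from the `seqLength` attribute when
#'   missing).
#' @return the overlap-free subset, same columns.
#' @export
resolveOverlaps <- function(matches, seqLength = attr(matches, "seqLength")) {
  if (is.null(seqLength)) stop("seqLength needed for circular overlap tests")
  if (nrow(matches) == 0) return(matches)
  ord <- order(-matches$length, matches$mismatches, matches$aStart,
               matches$bStart)
  m <- matches[ord, ]
  keep <- logical(nrow(m))
  ks <- integer(0); kl <- integer(0)   # flat list of kept locus intervals
  for (i in seq_len(nrow(m))) {
    ls <- c(m$aStart[i], m$bStart[i])
    ll <- c(m$aEnd[i] - m$aStart[i], m$bEnd[i] - m$bStart[i])
    hit <- FALSE
    if (length(ks))
      hit <- any(.circOverlaps(rep(ls, each = length(ks)), rep(ll, each = length(ks)),
                               rep(ks, 2), rep(kl, 2), seqLength))
    if (!hit) {
      keep[i] <- TRUE
      ks <- c(ks, ls); kl <- c(kl, ll)
    }
  }
  out <- m[keep, ]
  attr(out, "seqLength") <- seqLength
  out
}

## normalize a region specification to a data.frame of (start, width) on the
## circle; accepts data.frame with start/end, or a 2-column matrix
.asRegions <- function(regions, L) {
  if (is.matrix(regions)) regions <- data.frame(start = regions[, 1], end = regions[, 2])
  if (!all(c("start", "end") %in% names(regions)))
    stop("regions need 'start' and 'end' columns (0-based half-open)")
  data.frame(start = regions$start %% L,
             width = (regions$end - regions$start - 1) %% L + 1)
}

#' Count repeats able to mediate deletions between two regions
#'
#' Counts resolved repeat matches with one locus inside the deletion
#' start-point region set and the other inside the end-point region set: a
#' repeat pair whose annealing could mediate a deletion with endpoints in
#' those regions.
#'
#' @param matches resolved matches (see [resolveOverlaps()]).
#' @param regionStart,regionEnd data.frames of circular intervals with
#'   `start`/`end` columns (0-based half-open).
#' @param seqLength circle size (default from attribute).
#' @return integer count.
#' @export
countCrossRegionRepeats <- function(matches, regionStart, regionEnd,
                                    seqLength = attr(matches, "seqLength")) {
  if (nrow(matches) == 0 || NROW(regionStart) == 0 || NROW(regionEnd) == 0)
    return(0L)
  rs <- .asRegions(regionStart, seqLength)
  re <- .asRegions(regionEnd, seqLength)
  inside <- function(s, l, regions) {
    hit <- rep(FALSE, length(s))
    for (i in seq_len(nrow(regions)))
      hit <- hit | .circContains(regions$start[i], regions$width[i], s, l, seqLength)
    hit
  }
  aIn1 <- inside(matches$aStart, matches$aEnd - matches$aStart, rs)
  bIn1 <- inside(matches$bStart, matches$bEnd - matches$bStart, rs)
  aIn2 <- inside(matches$aStart, matches$aEnd - matches$aStart, re)
  bIn2 <- inside(matches$bStart, matches$bEnd - matches$bStart, re)
  sum((aIn1 & bIn2) | (aIn2 & bIn1))
}

#' Annotate a deletion junction with its flanking microhomology
#'
#' Searches a window around the two endpoints of an observed deletion for
#' the best qualifying repeat spanning them (one copy at each endpoint), the
#' pattern expected when the deletion arose by annealing of a short direct
#' repeat. Ranking follows [resolveOverlaps()]: length, then mismatches,
#' then coordinates.
#'
#' @param sequence circular nucleotide sequence of the unmutated plasmid.
#' @param deletionStart,deletionEnd 0-based endpoints of the removed arc
#'   (half-open).
#' @param params a [repeatParams()].
#' @param window bases searched on either side of each endpoint (default 20).
#' @return one-row data.frame as in [enumerateMicrohomologies()], or `NULL`
#'   when no qualifying repeat flanks the junction.
#' @export
annotateJunctionHomology <- function(sequence, deletionStart, deletionEnd,
                                     params = repeatParams(), window = 20) {
  codes <- .encodeSeq(sequence)
  L <- length(codes)
  hits <- enumerateMicrohomologies(sequence, params)
  if (nrow(hits) == 0) return(NULL)
  winA <- data.frame(start = deletionStart - window, end = deletionStart + window)
  winB <- data.frame(start = deletionEnd - window, end = deletionEnd + window)
  rs <- .asRegions(winA, L); re <- .asRegions(winB, L)
  ovl <- function(s, l, regions)
    .circOverlaps(s, l, regions$start, regions$width, L)
  aW <- hits$aEnd - hits$aStart; bW <- hits$bEnd - hits$bStart
  cross <- (ovl(hits$aStart, aW, rs) & ovl(hits$bStart, bW, re)) |
           (ovl(hits$aStart, aW, re) & ovl(hits$bStart, bW, rs))
  if (!any(cross)) return(NULL)
  hits <- hits[cross, ]
  hits <- hits[order(-hits$length, hits$mismatches, hits$aStart, hits$bStart), ]
  out <- hits[1, ]
  attr(out, "seqLength") <- L
  out
}
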