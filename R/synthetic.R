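## Synthetic fixtures: random circular plasmid sequences, planted
## near-perfect direct repeats with known ground truth, and toy annotated
## maps laid out in pQGS order. Everything is a pure function of its seed.

#' Random circular plasmid sequence
#'
#' Bases are drawn i.i.d. at a given GC fraction. Reproducible from `seed`.
#'
#' @param length sequence length in bases.
#' @param gc GC fraction in \[0, 1\].
#' @param seed integer seed (`NA` uses the current RNG state).
#' @return a `Biostrings::DNAString`.
#' @examples
#' randomPlasmidSequence(50, gc = 0.4, seed = 1)
#' @export
randomPlasmidSequence <- function(length, gc = 0.5, seed = NA) {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  if (!is.na(seed)) set.seed(seed)
  bases <- sample(c("A", "T", "G", "C"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
  Biostrings::DNAString(paste(bases, collapse = ""))
}

#' Plant a near-perfect direct repeat pair into a sequence
#'
#' Writes two copies of a repeat at the requested positions such that their
#' best alignment has exactly the requested column count, total mismatches
#' (indels included), and indels. With one indel the copy at `posB` carries
#' one extra inserted base, so it occupies `length` bases while the copy at
#' `posA` occupies `length - 1`; without indels both occupy `length` bases.
#' First and last alignment columns always match; substituted positions are
#' interior. The planted truth is recorded in the `planted` attribute.
#'
#' @param sequence circular sequence (character or `DNAString`).
#' @param length alignment length in columns.
#' @param posA,posB 0-based start positions of the two copies (must not
#'   overlap).
#' @param mismatches total mismatch columns including indels.
#' @param indels 0 or 1.
#' @param seed integer seed (`NA` uses the current RNG state).
#' @return the modified `DNAString` with attribute `planted` (a one-row
#'   data.frame: positions, widths, length, mismatches, indels, identity).
#' @export
plantRepeatPair <- function(sequence, length, posA, posB, mismatches = 0,
                            indels = 0, seed = NA) {
  if (!is.na(seed)) set.seed(seed)
  stopifnot(indels %in% 0:1, mismatches >= indels)
  chars <- strsplit(toupper(as.character(sequence)), "")[[1]]
  L <- base::length(chars)
  nSub <- mismatches - indels
  widthA <- length - indels
  widthB <- length
  if (nSub > length - 2 - indels)
    stop("infeasible: too many substitutions for this length")
  if (length > L / 2) stop("repeat too long for the sequence")
  span <- function(p, w) (p + 0:(w - 1)) %% L + 1
  if (any(span(posA, widthA) %in% span(posB, widthB)))
    stop("planted loci overlap")
  other <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)
  copyA <- sample(c("A", "C", "G", "T"), widthA, replace = TRUE)
  ## build copy B from copy A: optional insertion, then substitutions
  copyB <- copyA
  gapCol <- NA_integer_
  if (indels == 1) {
    gapCol <- sample(2:(length - 1), 1)          # interior alignment column
    copyB <- append(copyA, other(""), after = gapCol - 1)
  }
  ## substitutable columns: interior, not the gap column
  subCols <- setdiff(2:(length - 1), gapCol)
  if (nSub > 0) {
    pick <- sample(subCols, nSub)
    for (k in seq_len(nSub)) {
      j <- pick[k] - if (!is.na(gapCol) && pick[k] > gapCol) 1L else 0L
      copyB[pick[k]] <- other(copyA[j])
    }
  }
  chars[span(posA, widthA)] <- copyA
  chars[span(posB, widthB)] <- copyB
  out <- Biostrings::DNAString(paste(chars, collapse = ""))
  attr(out, "planted") <- data.frame(
    aStart = posA %% L, aEnd = posA %% L + widthA,
    bStart = posB %% L, bEnd = posB %% L + widthB,
    length = length, mismatches = mismatches, indels = indels,
    identity = (length - mismatches) / length)
  out
}

#' Toy annotated plasmid map in pQGS feature order
#'
#' A miniature circular map with the layout of the study plasmid: origin,
#' replication genes spanning roughly half the circle, then the compact
#' accessory cluster (gfp, lacI), then the marker (aadA), and a short
#' margin back to the origin. With this geometry deletions that create
#' satellite plasmids (endpoints in the wide replication region and the
#' marker-to-origin margin) outnumber accessory-gene deletions (endpoints
#' confined around the accessory cluster), as on the real plasmid.
#'
#' @param length map length in bases (default 2000, a desk scale where
#'   brute-force enumeration of all deletion arcs stays cheap).
#' @param nRep number of replication genes.
#' @param nAccessory number of accessory genes.
#' @return a [PlasmidMap-class].
#' @examples
#' makeToyPlasmidMap(60)
#' @export
makeToyPlasmidMap <- function(length = 2000, nRep = 3, nAccessory = 2) {
  stopifnot(length >= 50, nRep >= 1, nAccessory >= 0)
  at <- function(f) round(f * length)
  feats <- data.frame(name = "oriV", role = "origin",
                      start = at(0.00), end = at(0.04))
  repEdges <- seq(0.06, 0.55, length.out = nRep + 1)
  for (i in seq_len(nRep))
    feats <- rbind(feats, data.frame(
      name = paste0("rep", LETTERS[i]), role = "rep_gene",
      start = at(repEdges[i]), end = at(repEdges[i + 1] - 0.01)))
  if (nAccessory > 0) {
    accEdges <- seq(0.58, 0.78, length.out = nAccessory + 1)
    accNames <- c("gfp", "lacI", paste0("acc", seq_len(max(0, nAccessory - 2))))
    for (i in seq_len(nAccessory))
      feats <- rbind(feats, data.frame(
        name = accNames[i], role = "accessory",
        start = at(accEdges[i]), end = at(accEdges[i + 1] - 0.01)))
  }
  feats <- rbind(feats, data.frame(name = "aadA", role = "marker",
                                   start = at(0.80), end = at(0.86)))
  plasmidMap(length, feats)
}
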