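## Format I/O: plasmid maps from GenBank flat files or a plain TSV dialect,
## FASTA sequences via Biostrings, repeat/region tables as TSV, the
## colony-count fitness calculation, and run manifests.
##
## All coordinates in all outputs are 0-based half-open on the circle;
## GenBank's 1-based inclusive locations are translated at the boundary, and
## origin-spanning join() locations become one wrapping interval.

#' Read an annotated plasmid map
#'
#' Reads either a GenBank flat file (single circular record; the feature
#' table is parsed for gene/CDS/rep_origin features) or the package's TSV
#' map dialect with columns `name`, `role`, `start`, `end`. GenBank feature
#' names are mapped to roles through `roleMapping`, a named character vector
#' `c(featureName = "role", ...)`; names absent from the mapping get role
#' `"other"` (or raise an error when `strict = TRUE`).
#'
#' @param path file path.
#' @param roleMapping named character vector mapping feature names to roles
#'   (`origin`, `rep_gene`, `marker`, `accessory`, `other`).
#' @param strict error on unmapped feature names?
#' @return a [PlasmidMap-class]; for GenBank input with sequence, the
#'   sequence is attached as attribute `sequence` (a `DNAString`).
#' @export
readPlasmidMap <- function(path, roleMapping = NULL, strict = FALSE) {
  firstLine <- readLines(path, n = 1)
  if (grepl("^LOCUS", firstLine))
    .readGenBankMap(path, roleMapping, strict)
  else
    .readTsvMap(path)
}

.readTsvMap <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "role", "start", "end")
  if (!all(need %in% names(tab)))
    stop("map TSV needs columns: ", paste(need, collapse = ", "))
  len <- attr(tab, "seqLength")
  if (is.null(len)) {
    header <- readLines(path, n = 5)
    lenLine <- grep("^#\\s*length=", header, value = TRUE)
    len <- if (length(lenLine)) as.integer(sub(".*length=", "", lenLine[1]))
           else max(tab$end)
  }
  plasmidMap(len, tab)
}

#' Write a plasmid map as TSV
#'
#' @param map a [PlasmidMap-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePlasmidMap <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# length=%d", plasmidLength(map)), con)
  ft <- plasmidFeatures(map)[c("name", "role", "start", "end")]
  suppressWarnings(write.table(ft, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

## minimal GenBank flat-file parsing: LOCUS length/topology, FEATURES with
## location strings (complement/join handled; strand is irrelevant to
## deletion arithmetic), ORIGIN sequence block
.readGenBankMap <- function(path, roleMapping = NULL, strict = FALSE) {
  lines <- readLines(path)
  if (sum(grepl("^LOCUS", lines)) > 1)
    stop("multi-record GenBank files are not supported")
  locus <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  len <- as.integer(locus[3])
  featStart <- grep("^FEATURES", lines)
  originAt <- grep("^ORIGIN", lines)
  endAt <- if (length(originAt)) originAt[1] else grep("^//", lines)[1]
  if (is.na(endAt)) endAt <- length(lines) + 1L
  feats <- list()
  if (length(featStart)) {
    block <- lines[(featStart[1] + 1):(endAt - 1)]
    keyLine <- grepl("^\\s{1,10}\\S+\\s+\\S", block) & !grepl("^\\s{12,}", block)
    idx <- which(keyLine)
    for (k in seq_along(idx)) {
      hdr <- strsplit(trimws(block[idx[k]]), "\\s+")[[1]]
      type <- hdr[1]
      to <- if (k < length(idx)) idx[k + 1] - 1 else length(block)
      body <- block[idx[k]:to]
      loc <- sub("^\\s*\\S+\\s+", "", body[1])
      ## continuation lines of the location (no qualifier yet)
      j <- 2
      while (j <= length(body) && !grepl("^\\s+/", body[j])) {
        loc <- paste0(loc, trimws(body[j])); j <- j + 1
      }
      quals <- body[grepl("^\\s+/", body)]
      getQ <- function(q) {
        m <- grep(paste0("^\\s+/", q, "="), quals, value = TRUE)
        if (!length(m)) return(NA_character_)
        gsub('"', "", sub(paste0("^\\s+/", q, "="), "", m[1]))
      }
      name <- getQ("label")
      if (is.na(name)) name <- getQ("gene")
      if (is.na(name)) name <- getQ("standard_name")
      if (is.na(name)) name <- type
      iv <- .parseGenBankLocation(loc, len)
      if (!is.null(iv))
        feats[[length(feats) + 1]] <- data.frame(
          name = name, type = type, start = iv[1], end = iv[2])
    }
  }
  ft <- do.call(rbind, feats)
  ft <- ft[ft$type %in% c("gene", "CDS", "rep_origin", "oriT", "misc_feature"), ,
           drop = FALSE]
  ## collapse gene/CDS duplicates of the same name, prefer gene extents
  ft <- ft[!duplicated(ft$name), , drop = FALSE]
  role <- rep("other", nrow(ft))
  if (!is.null(roleMapping)) {
    hit <- match(ft$name, names(roleMapping))
    role[!is.na(hit)] <- roleMapping[hit[!is.na(hit)]]
    if (strict && any(is.na(hit)))
      stop("unmapped feature names: ",
           paste(ft$name[is.na(hit)], collapse = ", "))
  }
  role[ft$type == "rep_origin"] <- "origin"
  map <- plasmidMap(len, data.frame(name = ft$name, role = role,
                                    start = ft$start, end = ft$end))
  if (length(originAt)) {
    seqBlock <- lines[(originAt[1] + 1):(grep("^//", lines)[1] - 1)]
    seqChars <- gsub("[^A-Za-z]", "", paste(seqBlock, collapse = ""))
    attr(map, "sequence") <- Biostrings::DNAString(toupper(seqChars))
  }
  map
}

## "101..160", "complement(...)", "join(a..b,c..d)" -> 0-based half-open
## [start, end); an origin-spanning join becomes one wrapping interval
.parseGenBankLocation <- function(loc, len) {
  loc <- gsub("complement\\(|\\)$", "", loc)
  loc <- gsub("^join\\(", "", loc)
  loc <- gsub("[<>]", "", loc)
  parts <- strsplit(loc, ",")[[1]]
  rng <- t(vapply(parts, function(p) {
    nums <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (anyNA(nums)) return(c(NA_integer_, NA_integer_))
    c(nums[1] - 1L, nums[length(nums)])    # 1-based inclusive -> half-open
  }, integer(2)))
  if (anyNA(rng)) return(NULL)
  if (nrow(rng) == 1) return(rng[1, ])
  ## join spanning the origin: last segment ends at len, first starts at 0
  if (rng[1, 2] == len && rng[nrow(rng), 1] == 0)
    return(c(rng[1, 1], len + rng[nrow(rng), 2]))
  c(min(rng[, 1]), max(rng[, 2]))
}

#' Write repeat matches as TSV
#'
#' Columns `locus_a_start`, `locus_a_end`, `locus_b_start`, `locus_b_end`,
#' `length`, `mismatches`, `indels`, `identity`, 0-based half-open.
#'
#' @param matches data.frame from [enumerateMicrohomologies()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRepeatTable <- function(matches, path) {
  out <- data.frame(locus_a_start = matches$aStart, locus_a_end = matches$aEnd,
                    locus_b_start = matches$bStart, locus_b_end = matches$bEnd,
                    length = matches$length, mismatches = matches$mismatches,
                    indels = matches$indels,
                    identity = round(matches$identity, 4))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Relative fitness from colony counts of a competition assay
#'
#' The ratio of realized Malthusian parameters of two competitors grown in
#' co-culture: `ln(af * D / a0) / ln(bf * D / b0)` where `a0`, `af` are the
#' focal strain's initial and final counts, `b0`, `bf` the reference
#' strain's, and `D` the total fold dilution over the assay.
#'
#' @param a0,af focal colony counts before and after growth.
#' @param b0,bf reference colony counts before and after growth.
#' @param totalDilution total fold dilution during the assay.
#' @return relative fitness of the focal strain.
#' @examples
#' fitnessFromCounts(100, 400, 100, 200, totalDilution = 1)  # 2.0
#' @export
fitnessFromCounts <- function(a0, af, b0, bf, totalDilution = 1) {
  if (any(c(a0, af, b0, bf) <= 0))
    stop("undefined fitness: all colony counts must be positive")
  log(af * totalDilution / a0) / log(bf * totalDilution / b0)
}

#' Write a run manifest
#'
#' Records the package version, the resolved configuration, seed, timestamp
#' and output files of a command-line run as JSON, so that a stochastic run
#' can be reproduced bit for bit.
#'
#' @param path manifest file path.
#' @param config named list of resolved parameters.
#' @param seed integer seed used.
#' @param outputs character vector of output files written.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(path, config, seed, outputs = character()) {
  manifest <- list(tool = "satdyn",
                   version = as.character(packageVersion("satdyn")),
                   config = config, seed = seed,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read or write a plasmid model as a key-value table
#'
#' The model file is a TSV with columns `name`, `autonomous`,
#' `carriesMarker`, `perCopyCost` and a header comment `# copyNumber=<n>`.
#' The bundled preset encoding the calibrated pQGS model ships at
#' `system.file("extdata", "pqgs_model.tsv", package = "satdyn")`.
#'
#' @param path file path.
#' @return [readPlasmidModel()] a [PlasmidModel-class];
#'   [writePlasmidModel()] `path`, invisibly.
#' @export
readPlasmidModel <- function(path) {
  header <- readLines(path, n = 5)
  cnLine <- grep("^#\\s*copyNumber=", header, value = TRUE)
  cn <- if (length(cnLine)) as.integer(sub(".*copyNumber=", "", cnLine[1])) else 18L
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  plasmidModel(tab, copyNumber = cn)
}

#' @rdname readPlasmidModel
#' @param model a [PlasmidModel-class].
#' @export
writePlasmidModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# copyNumber=%d", copyNumber(model)), con)
  suppressWarnings(write.table(model@species, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read a simulation configuration from a YAML/JSON key-value file
#'
#' Keys mirror the arguments of [simulationConfig()]; absent keys keep their
#' defaults.
#'
#' @param path file path to a YAML (or JSON) mapping.
#' @return a [SimulationConfig-class].
#' @export
readSimulationConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- lapply(vals, function(v) if (is.integer(v)) as.numeric(v) else v)
  known <- names(formals(simulationConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(simulationConfig, vals)
}
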