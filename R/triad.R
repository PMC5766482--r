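#' I91 reference domain sequence
#'
#' The 89-residue titin I91 (also known as I27) domain sequence from PDB
#' entry 1TIT, packaged as the alignment reference. Cysteines of other Ig
#' domains are numbered by the column they occupy when aligned to this
#' sequence; the conserved triad maps to columns 23 (CysB), 73 (CysF) and
#' 80 (CysG).
#'
#' @return An \code{AAString} of length 89.
#' @examples
#' nchar(i91Reference())  # 89
#' @export
i91Reference <- function() {
  f <- system.file("extdata", "I91_1TIT.fasta", package = "titinIso")
  Biostrings::readAAStringSet(f)[[1]]
}

#' Reference alignment columns of the cysteine triad
#'
#' @return Named integer vector with elements \code{B}, \code{F}, \code{G}
#'   (columns 23, 73, 80 of the I91 reference).
#' @export
triadReferenceColumns <- function() c(B = 23L, F = 73L, G = 80L)

#' Default titin band boundaries
#'
#' Approximate residue spans of the Z-disk, I-band, A-band and M-band in
#' canonical (N2BA) titin numbering. These are conventional, editable
#' defaults for assigning regions to domain annotations that lack one.
#'
#' @return A data.frame with columns \code{region}, \code{start},
#'   \code{end}.
#' @export
titinRegionTable <- function() {
  data.frame(region = c("Z-disk", "I-band", "A-band", "M-band"),
             start = c(1, 2169, 14522, 33335),
             end = c(2168, 14521, 33334, 34350))
}

#' The 12 manually curated Ig domains of canonical titin
#'
#' Residue spans (1-based inclusive, canonical Q8WZ42 numbering) of the 12
#' Ig domains absent from the automatic annotation, including I91 at
#' 12674-12765; shipped as a packaged fixture table.
#'
#' @return A data.frame with columns \code{id}, \code{start}, \code{end},
#'   \code{region}.
#' @export
manualIgDomains <- function() {
  f <- system.file("extdata", "manual_ig_domains.tsv", package = "titinIso")
  utils::read.delim(f, stringsAsFactors = FALSE)
}

## Assign a band label to a domain midpoint from a region table.
.assignRegion <- function(start, end, regions = titinRegionTable()) {
  mid <- (start + end) / 2
  i <- vapply(mid, function(m) {
    w <- which(m >= regions$start & m <= regions$end)
    if (length(w)) w[1] else NA_integer_
  }, 0L)
  regions$region[i]
}

#' Extract annotated Ig-domain sequences from a parent sequence
#'
#' Cuts the annotated domain subsequences out of a parent protein
#' sequence, assigning band regions where the annotation lacks them and
#' warning when the strictly conserved tryptophan expected near reference
#' position 35 is absent from a domain.
#'
#' @param fasta path to a FASTA file with the parent sequence, or an
#'   \code{AAString}/\code{AAStringSet} (first sequence used).
#' @param annotation a data.frame with columns \code{id}, \code{start},
#'   \code{end} (1-based inclusive) and optionally \code{region}, or the
#'   path to such a TSV.
#' @param regions region table used when \code{annotation$region} is
#'   missing.
#' @return An \code{AAStringSet} named by domain id, with the completed
#'   annotation attached as attribute \code{"annotation"}.
#' @export
loadDomains <- function(fasta, annotation, regions = titinRegionTable()) {
  parent <- if (is.character(fasta))
    Biostrings::readAAStringSet(fasta)[[1]]
  else if (is(fasta, "AAStringSet")) fasta[[1]]
  else fasta
  ann <- if (is.character(annotation))
    utils::read.delim(annotation, stringsAsFactors = FALSE)
  else annotation
  need <- c("id", "start", "end")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns id, start, end")
  if (any(ann$start >= ann$end))
    stop("annotation must satisfy start < end")
  L <- length(parent)
  bad <- which(ann$start < 1 | ann$end > L)
  if (length(bad))
    stop("annotation out of sequence bounds for domain(s): ",
         paste(ann$id[bad], collapse = ", "))
  if (is.null(ann$region))
    ann$region <- .assignRegion(ann$start, ann$end, regions)
  seqs <- Biostrings::AAStringSet(
    vapply(seq_len(nrow(ann)), function(i)
      as.character(Biostrings::subseq(parent, ann$start[i], ann$end[i])),
      ""))
  names(seqs) <- ann$id
  # crude anchor check: a Trp should sit near reference position 35
  noW <- vapply(seq_along(seqs), function(i) {
    s <- as.character(seqs[[i]])
    w <- substring(s, 20, min(nchar(s), 50))
    !grepl("W", w, fixed = TRUE)
  }, NA)
  if (any(noW))
    warning("no conserved tryptophan near position 35 in domain(s): ",
            paste(ann$id[noW], collapse = ", "))
  attr(seqs, "annotation") <- ann
  seqs
}

#' Map a domain sequence onto the I91 reference numbering
#'
#' Global pairwise alignment (Needleman-Wunsch with affine gaps,
#' BLOSUM62-style scoring) of a domain against the I91 reference, returning
#' the reference column occupied by each domain residue.
#'
#' @param domainSeq an \code{AAString} or character scalar.
#' @param refSeq the reference sequence (default \code{\link{i91Reference}}).
#' @param gapOpening,gapExtension affine gap penalties (defaults 11 and 1).
#' @param matrix substitution matrix name (default \code{"BLOSUM62"}).
#' @param scoreFloor alignments scoring below this are flagged
#'   unclassifiable (default 40).
#' @return An integer vector of length \code{nchar(domainSeq)} giving the
#'   reference column per domain position (NA where the residue falls in a
#'   gap), with attributes \code{"score"} and \code{"unclassifiable"}.
#' @examples
#' m <- mapToReference(i91Reference())
#' identical(as.integer(m), seq_len(89))
#' @export
mapToReference <- function(domainSeq, refSeq = i91Reference(),
                           gapOpening = 11, gapExtension = 1,
                           matrix = "BLOSUM62", scoreFloor = 40) {
  dchr <- as.character(domainSeq)
  rchr <- as.character(refSeq)
  if (!nchar(dchr) || !nchar(rchr)) stop("sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    pattern = dchr, subject = rchr, type = "global",
    substitutionMatrix = matrix, gapOpening = gapOpening,
    gapExtension = gapExtension)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  map <- rep(NA_integer_, nchar(dchr))
  ip <- 0L; ir <- 0L
  for (k in seq_along(ap)) {
    pGap <- ap[k] == "-"; rGap <- as_[k] == "-"
    if (!pGap) ip <- ip + 1L
    if (!rGap) ir <- ir + 1L
    if (!pGap && !rGap) map[ip] <- ir
  }
  attr(map, "score") <- Biostrings::score(pa)
  attr(map, "unclassifiable") <- Biostrings::score(pa) < scoreFloor
  map
}

#' Classify a domain by its CysB/CysF/CysG content
#'
#' A cysteine counts as CysB, CysF or CysG when its mapped reference
#' column lies within \code{tolerance} columns of 23, 73 or 80. The class
#' is determined by the matched subset: all three, one of the three pairs,
#' a single triad cysteine, or none. Domains whose alignment was flagged
#' unclassifiable get class \code{"UNALIGNED"}.
#'
#' @param map alignment map from \code{\link{mapToReference}}.
#' @param seq the domain sequence (same one used to build \code{map}).
#' @param tolerance column tolerance (default 2).
#' @param refCols reference columns, named \code{B}, \code{F}, \code{G}.
#' @return A list with \code{class}, \code{matched} (named positions of
#'   the matched cysteines within the domain) and \code{otherCys}
#'   (positions of cysteines not matching any triad column).
#' @export
classifyDomain <- function(map, seq, tolerance = 2,
                           refCols = triadReferenceColumns()) {
  s <- strsplit(as.character(seq), "")[[1]]
  if (length(s) != length(map))
    stop("map and sequence lengths disagree")
  if (isTRUE(attr(map, "unclassifiable")))
    return(list(class = "UNALIGNED", matched = integer(0),
                otherCys = which(s == "C")))
  cysPos <- which(s == "C")
  cols <- map[cysPos]
  matched <- integer(0)
  for (nm in names(refCols)) {
    hit <- cysPos[!is.na(cols) & abs(cols - refCols[[nm]]) <= tolerance]
    if (length(hit)) {
      matched[nm] <- hit[1]
      drop <- cysPos == hit[1]
      cysPos <- cysPos[!drop]; cols <- cols[!drop]
    }
  }
  got <- names(matched)
  cls <- if (all(c("B", "F", "G") %in% got)) "TRIAD"
  else if (all(c("B", "F") %in% got)) "PAIR_BF"
  else if (all(c("F", "G") %in% got)) "PAIR_FG"
  else if (all(c("B", "G") %in% got)) "PAIR_BG"
  else if ("B" %in% got) "SINGLE_B"
  else if ("F" %in% got) "SINGLE_F"
  else if ("G" %in% got) "SINGLE_G"
  else "NONE"
  list(class = cls, matched = matched, otherCys = cysPos)
}

#' Scan a set of Ig domains for the cysteine triad
#'
#' Convenience pipeline: aligns every domain in \code{domains} to the
#' reference and classifies it.
#'
#' @param domains an \code{AAStringSet} from \code{\link{loadDomains}}.
#' @param ... passed to \code{\link{mapToReference}} and
#'   \code{\link{classifyDomain}} (e.g. \code{tolerance},
#'   \code{gapOpening}).
#' @param refSeq reference sequence.
#' @param tolerance classification column tolerance.
#' @return A data.frame with one row per domain: \code{id}, \code{start},
#'   \code{end}, \code{region}, \code{class}, \code{nCys}, and logical
#'   columns \code{hasB}, \code{hasF}, \code{hasG}; the per-domain maps as
#'   attribute \code{"maps"}.
#' @export
scanTriads <- function(domains, refSeq = i91Reference(), tolerance = 2,
                       ...) {
  ann <- attr(domains, "annotation")
  if (is.null(ann))
    ann <- data.frame(id = names(domains),
                      start = NA_real_, end = NA_real_,
                      region = NA_character_)
  maps <- vector("list", length(domains))
  cls <- character(length(domains))
  nCys <- integer(length(domains))
  has <- matrix(FALSE, length(domains), 3,
                dimnames = list(NULL, c("B", "F", "G")))
  for (i in seq_along(domains)) {
    maps[[i]] <- mapToReference(domains[[i]], refSeq, ...)
    cl <- classifyDomain(maps[[i]], domains[[i]], tolerance = tolerance)
    cls[i] <- cl$class
    nCys[i] <- sum(strsplit(as.character(domains[[i]]), "")[[1]] == "C")
    has[i, names(cl$matched)] <- TRUE
  }
  out <- data.frame(id = names(domains), start = ann$start, end = ann$end,
                    region = ann$region, class = cls, nCys = nCys,
                    hasB = has[, "B"], hasF = has[, "F"], hasG = has[, "G"],
                    stringsAsFactors = FALSE)
  attr(out, "maps") <- maps
  out
}

#' Per-column cysteine conservation profile
#'
#' Fraction of domains carrying a cysteine at each reference column,
#' optionally restricted to one band region.
#'
#' @param scan result of \code{\link{scanTriads}} (needs the
#'   \code{"maps"} attribute) or a list of maps plus sequences.
#' @param domains the \code{AAStringSet} the scan was computed from.
#' @param region optional region filter (e.g. \code{"I-band"}); NULL uses
#'   all domains.
#' @param refLength number of reference columns (default 89).
#' @return A data.frame with columns \code{column} and \code{freq}.
#' @export
conservationProfile <- function(scan, domains, region = NULL,
                                refLength = 89L) {
  maps <- attr(scan, "maps")
  keep <- if (is.null(region)) rep(TRUE, nrow(scan))
          else !is.na(scan$region) & scan$region == region
  if (!any(keep)) stop("no domains in the requested region")
  counts <- integer(refLength)
  for (i in which(keep)) {
    s <- strsplit(as.character(domains[[i]]), "")[[1]]
    cols <- maps[[i]][s == "C"]
    cols <- cols[!is.na(cols) & cols >= 1 & cols <= refLength]
    counts[cols] <- counts[cols] + 1L
  }
  data.frame(column = seq_len(refLength), freq = counts / sum(keep))
}

#' Cysteine-class composition per titin isoform
#'
#' Tallies domain classes for the I-band of each isoform definition. An
#' isoform definition is a list with an optional element \code{exclude}, a
#' residue range c(start, end) of the parent sequence spliced out of that
#' isoform (domains falling inside are dropped).
#'
#' @param scan result of \code{\link{scanTriads}} with positional
#'   annotation.
#' @param isoforms named list of isoform definitions. The default defines
#'   N2BA (full canonical sequence) and N2B (middle I-band and most of
#'   PEVK spliced out).
#' @param region band to tabulate (default \code{"I-band"}).
#' @return A data.frame with one row per isoform and class, plus columns
#'   \code{n} and \code{triadFraction} (fraction of that isoform's I-band
#'   domains with class TRIAD, repeated per row).
#' @export
isoformComposition <- function(scan,
                               isoforms = list(
                                 N2BA = list(exclude = NULL),
                                 N2B = list(exclude = c(4290, 11850))),
                               region = "I-band") {
  if (!is.list(isoforms) || is.null(names(isoforms)) ||
      any(!nzchar(names(isoforms))))
    stop("isoforms must be a named list of definitions")
  classLevels <- c("TRIAD", "PAIR_BF", "PAIR_FG", "PAIR_BG", "SINGLE_B",
                   "SINGLE_F", "SINGLE_G", "NONE", "UNALIGNED")
  rows <- list()
  for (nm in names(isoforms)) {
    def <- isoforms[[nm]]
    if (!is.list(def)) stop("unknown isoform definition for ", nm)
    keep <- !is.na(scan$region) & scan$region == region
    if (!is.null(def$exclude)) {
      mid <- (scan$start + scan$end) / 2
      keep <- keep & !(mid >= def$exclude[1] & mid <= def$exclude[2])
    }
    tab <- table(factor(scan$class[keep], levels = classLevels))
    tf <- if (sum(keep)) unname(tab["TRIAD"]) / sum(keep) else 0
    rows[[nm]] <- data.frame(isoform = nm, class = names(tab),
                             n = as.integer(tab), triadFraction = tf,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
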