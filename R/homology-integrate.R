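# Homology evidence: filtering, conflict removal, reciprocal validation,
# the DIRS rule, secondary expansion and the final three-source merge.

#' Filter homology hits by E-value and alignment length
#'
#' A hit is retained iff `evalue <= eMax` and `length >= minHitLen`; both
#' boundaries are inclusive. Retained hits are projected to genomic
#' intervals (subject coordinates) with `source = "homology"`.
#'
#' @param hits a `data.frame` as returned by [readBlastTab()]: at least
#'   `sseqid`, `sstart`, `send`, `length`, `evalue` (optionally `strand`,
#'   `qseqid`).
#' @param params a [FilterParams].
#' @return a `GRanges` annotation set (source `homology`, score = E-value).
#' @export
filterHomologyHits <- function(hits, params = FilterParams()) {
  if (any(hits$evalue < 0)) stop("negative E-value in hit table")
  if (any(hits$length < 1)) stop("alignment length must be >= 1")
  keep <- hits$evalue <= params@eMax & hits$length >= params@minHitLen
  h <- hits[keep, , drop = FALSE]
  if (!nrow(h)) return(annotationSet(GRanges(), source = character(0)))
  gr <- GRanges(h$sseqid, IRanges(h$sstart, h$send),
                strand = if (!is.null(h$strand)) h$strand else "*")
  out <- annotationSet(gr, source = "homology", score = h$evalue,
                       label = if (!is.null(h$qseqid)) h$qseqid else
                         NA_character_)
  out
}

#' Remove elements with high coverage by other repeat classes
#'
#' An element (e.g. a merged homology interval) is removed when at least
#' `conflictCov` of its span is covered by non-LTR repeat records — the
#' classic false-positive mode being LINE elements picked up through their
#' reverse transcriptase domain. Removals are logged with the dominating
#' conflicting class.
#'
#' @param elements a `GRanges` annotation set.
#' @param otherRepeats a `GRanges` of non-LTR repeat records (e.g. the
#'   `other` partition from [readRepeatMaskerOut()]), with a `repeat_class`
#'   metadata column when class logging is wanted.
#' @param params a [FilterParams] (`conflictCov`).
#' @return the retained `GRanges`, with attribute `"removed"`: a
#'   `data.frame` logging removed records and their dominating class.
#' @export
applyConflictFilter <- function(elements, otherRepeats,
                                params = FilterParams()) {
  if (!length(elements) || !length(otherRepeats)) {
    attr(elements, "removed") <- data.frame(chrom = character(0),
                                            start = integer(0),
                                            end = integer(0),
                                            covered = numeric(0),
                                            class = character(0))
    return(elements)
  }
  red <- reduce(granges(otherRepeats), ignore.strand = TRUE)
  ov <- findOverlaps(elements, red, ignore.strand = TRUE)
  coveredBp <- numeric(length(elements))
  if (length(ov)) {
    w <- width(pintersect(elements[queryHits(ov)], red[subjectHits(ov)],
                          ignore.strand = TRUE))
    agg <- tapply(w, queryHits(ov), sum)
    coveredBp[as.integer(names(agg))] <- agg
  }
  frac <- coveredBp / width(elements)
  removed <- which(frac >= params@conflictCov)
  domClass <- rep(NA_character_, length(removed))
  if (length(removed) && !is.null(mcols(otherRepeats)$repeat_class)) {
    ov2 <- findOverlaps(elements[removed], otherRepeats,
                        ignore.strand = TRUE)
    w2 <- width(pintersect(elements[removed][queryHits(ov2)],
                           otherRepeats[subjectHits(ov2)],
                           ignore.strand = TRUE))
    cls <- mcols(otherRepeats)$repeat_class[subjectHits(ov2)]
    for (i in seq_along(removed)) {
      sel <- queryHits(ov2) == i
      if (any(sel)) {
        byCls <- tapply(w2[sel], cls[sel], sum)
        domClass[i] <- names(byCls)[which.max(byCls)]
      }
    }
  }
  log <- data.frame(chrom = as.character(seqnames(elements))[removed],
                    start = start(elements)[removed],
                    end = end(elements)[removed],
                    covered = frac[removed], class = domClass,
                    stringsAsFactors = FALSE)
  kept <- if (length(removed)) elements[-removed] else elements
  attr(kept, "removed") <- log
  kept
}

#' Reciprocal validation against a reference LTR retrotransposon library
#'
#' Each element's best reciprocal hit (highest bit-score; ties by lowest
#' E-value then longest alignment) is compared to the E-value threshold.
#' Elements whose best hit passes are flagged validated; the rest are
#' flagged, not dropped — [finalizeAnnotation()] retains them only when they
#' carry structural support.
#'
#' @param elements a `GRanges`; element keys are `mcols(elements)$element_id`
#'   when present, else `chrom:start-end`.
#' @param libraryHits `data.frame` of reciprocal hits with columns
#'   `element_id`, `evalue`, and optionally `bitscore`, `length`.
#' @param params a [FilterParams] (`eMax`).
#' @return `elements` with a logical metadata column `validated`.
#' @export
reciprocalValidate <- function(elements, libraryHits,
                               params = FilterParams()) {
  ids <- mcols(elements)$element_id
  if (is.null(ids))
    ids <- sprintf("%s:%d-%d", as.character(seqnames(elements)),
                   start(elements), end(elements))
  validated <- rep(FALSE, length(elements))
  if (!is.null(libraryHits) && nrow(libraryHits)) {
    bs <- if (!is.null(libraryHits$bitscore)) libraryHits$bitscore else
      -log10(pmax(libraryHits$evalue, 1e-300))
    ln <- if (!is.null(libraryHits$length)) libraryHits$length else 0L
    ord <- order(libraryHits$element_id, -bs, libraryHits$evalue, -ln)
    h <- libraryHits[ord, , drop = FALSE]
    best <- h[!duplicated(h$element_id), , drop = FALSE]
    pass <- best$element_id[best$evalue <= params@eMax]
    validated <- ids %in% pass
  }
  mcols(elements)$element_id <- ids
  mcols(elements)$validated <- validated
  elements
}

#' Apply the DIRS acceptance rule to one element's domain hits
#'
#' A putative DIRS element (tyrosine-recombinase retrotransposon lacking
#' classical LTR structure) is accepted iff it has a reverse transcriptase
#' hit at `E <= dirsRtE` and a methyl transferase or tyrosine recombinase
#' hit at `E <= dirsAuxE` (both boundaries inclusive).
#'
#' @param domainHits `data.frame` of hits for one element with columns
#'   `domain` (`"RT"`, `"MT"`, `"YR"`, ...) and `e_value`.
#' @param params a [FilterParams].
#' @return `TRUE`/`FALSE`.
#' @examples
#' callDirs(data.frame(domain = c("RT", "YR"), e_value = c(1e-16, 1e-13)))
#' @export
callDirs <- function(domainHits, params = FilterParams()) {
  if (is.null(domainHits) || !nrow(domainHits)) return(FALSE)
  rt <- domainHits$domain == "RT" & domainHits$e_value <= params@dirsRtE
  aux <- domainHits$domain %in% c("MT", "YR") &
    domainHits$e_value <= params@dirsAuxE
  any(rt) && any(aux)
}

#' Expand annotation from structurally intact element queries
#'
#' Homology hits obtained by searching accepted structural elements against
#' the genome are filtered with the primary E-value/length thresholds; hits
#' falling entirely inside the existing annotation are absorbed (no new
#' record), and the remainder become `source = "secondary"` records tagged
#' with their query element.
#'
#' @param genomeHits `data.frame` of hits (as [readBlastTab()]), `qseqid`
#'   naming the query structural element.
#' @param existing `GRanges` of already-annotated intervals.
#' @param params a [FilterParams].
#' @return a `GRanges` annotation set with source `secondary` and `label` =
#'   query element id.
#' @export
secondaryExpand <- function(genomeHits, existing, params = FilterParams()) {
  filt <- filterHomologyHits(genomeHits, params)
  if (!length(filt)) return(filt)
  mcols(filt)$source <- "secondary"
  if (length(existing)) {
    inside <- overlapsAny(filt, reduce(granges(existing),
                                       ignore.strand = TRUE),
                          type = "within", ignore.strand = TRUE)
    filt <- filt[!inside]
  }
  filt
}

#' Combine the three evidence streams into the final annotation
#'
#' Unvalidated homology records lacking structural support (no overlap with
#' any structural element) are dropped and logged; the remaining homology,
#' structural and secondary records are merged with [mergeAnnotations()] and
#' a provenance coverage table is computed with [coverageSummary()].
#'
#' @param homology,structural,secondary `GRanges` annotation sets (the
#'   homology set may carry a `validated` column from
#'   [reciprocalValidate()]; when absent all records count as validated).
#' @param params a [FilterParams] (`mergeGap`).
#' @return a list with `annotation` (merged `GRanges`), `provenance` (the
#'   [coverageSummary()] list) and `dropped` (unvalidated homology records
#'   removed).
#' @export
finalizeAnnotation <- function(homology, structural, secondary = GRanges(),
                               params = FilterParams()) {
  dropped <- GRanges()
  if (length(homology) && !is.null(mcols(homology)$validated)) {
    unval <- !mcols(homology)$validated
    structSupport <- overlapsAny(homology, structural, ignore.strand = TRUE)
    drop <- unval & !structSupport
    dropped <- homology[drop]
    homology <- homology[!drop]
  }
  sets <- list(homology = granges(homology),
               structural = granges(structural),
               secondary = granges(secondary))
  merged <- mergeAnnotations(
    annotationSet(do.call(c, unname(sets)),
                  source = rep(names(sets), vapply(sets, length, 0L))),
    maxGap = params@mergeGap)
  list(annotation = merged, provenance = coverageSummary(sets),
       dropped = dropped)
}
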