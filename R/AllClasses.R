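#' GenomeIndex: chromosome sizes and assembly gaps
#'
#' Lightweight container for an assembly: an ordered set of chromosome
#' lengths plus optional assembly-gap intervals. All coordinate-aware
#' operations in the package validate against it.
#'
#' @slot seqinfo a [GenomeInfoDb::Seqinfo] holding chromosome names and
#'   lengths.
#' @slot gaps a [GenomicRanges::GRanges] of assembly gaps (may be empty);
#'   every gap must lie within its chromosome.
#'
#' @examples
#' gi <- GenomeIndex(c(chr1 = 1e6, chr2 = 5e5))
#' genomeLength(gi)
#' @export
setClass("GenomeIndex",
  representation(seqinfo = "Seqinfo", gaps = "GRanges"))

setValidity("GenomeIndex", function(object) {
  sl <- seqlengths(object@seqinfo)
  if (length(sl) == 0L) return("no chromosomes")
  if (anyNA(sl) || any(sl <= 0)) return("all chromosome lengths must be > 0")
  if (anyDuplicated(names(sl))) return("chromosome names must be unique")
  g <- object@gaps
  if (length(g)) {
    bad <- !(as.character(seqnames(g)) %in% names(sl))
    if (any(bad)) return("gap on unknown chromosome")
    lim <- sl[as.character(seqnames(g))]
    if (any(start(g) < 1L | end(g) > lim))
      return("assembly gap outside chromosome bounds")
  }
  TRUE
})

#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param gaps optional `GRanges` of assembly gaps.
#' @rdname GenomeIndex-class
#' @export
GenomeIndex <- function(chromLengths, gaps = GRanges()) {
  if (is.null(names(chromLengths)) || any(!nzchar(names(chromLengths))))
    stop("chromLengths must be a named vector")
  si <- Seqinfo(seqnames = names(chromLengths),
                seqlengths = as.integer(chromLengths))
  new("GenomeIndex", seqinfo = si, gaps = gaps)
}

#' @param x,object a `GenomeIndex`.
#' @rdname GenomeIndex-class
#' @export
chromLengths <- function(x) seqlengths(x@seqinfo)

#' Total assembled (non-gap) length in bp
#' @rdname GenomeIndex-class
#' @export
genomeLength <- function(x) {
  sum(as.numeric(chromLengths(x))) - sum(as.numeric(width(reduce(x@gaps))))
}

#' Assembled (non-gap) intervals per chromosome
#' @rdname GenomeIndex-class
#' @export
assembledRegions <- function(x) {
  full <- GRanges(names(chromLengths(x)),
                  IRanges(1L, chromLengths(x)), seqinfo = x@seqinfo)
  if (!length(x@gaps)) return(full)
  g <- x@gaps
  seqlevels(g) <- seqlevels(x@seqinfo)
  seqinfo(g) <- x@seqinfo
  GenomicRanges::setdiff(full, g, ignore.strand = TRUE)
}

setMethod("show", "GenomeIndex", function(object) {
  sl <- chromLengths(object)
  cat("GenomeIndex with", length(sl), "chromosomes,",
      format(sum(as.numeric(sl)), big.mark = ","), "bp",
      sprintf("(%d gap intervals)\n", length(object@gaps)))
})

#' Parameters of the structural LTR-pair detector
#'
#' Distance and similarity constraints for calling candidate LTR pairs, and
#' the evidence threshold for accepting an element. Defaults follow the
#' constraints commonly used for vertebrate LTR retrotransposons: LTRs of
#' 80-2000 bp with at least 75 % pairwise identity, element spans of
#' 1-25 kb.
#'
#' @slot minLtrLen,maxLtrLen admissible LTR lengths (bp).
#' @slot minLtrSimilarity minimum LTR-LTR identity fraction in (0, 1].
#' @slot minElementSpan,maxElementSpan admissible full-element spans (bp).
#' @slot seedKmer exact seed k-mer length for candidate generation.
#' @slot evidenceMin number of structural evidence flags (of TG..CA, TSD,
#'   PBS, PPT, poly-A) required to accept an element lacking protein-domain
#'   support.
#' @export
setClass("DetectorParams", representation(
  minLtrLen = "integer", maxLtrLen = "integer",
  minLtrSimilarity = "numeric",
  minElementSpan = "integer", maxElementSpan = "integer",
  seedKmer = "integer", evidenceMin = "integer"))

setValidity("DetectorParams", function(object) {
  if (object@minLtrLen <= 0L || object@minLtrLen > object@maxLtrLen)
    return("need 0 < minLtrLen <= maxLtrLen")
  if (object@minLtrSimilarity <= 0 || object@minLtrSimilarity > 1)
    return("minLtrSimilarity must be in (0, 1]")
  if (object@minElementSpan >= object@maxElementSpan)
    return("minElementSpan must be < maxElementSpan")
  if (object@seedKmer < 8L || object@seedKmer > 15L)
    return("seedKmer must be in [8, 15]")
  TRUE
})

#' @param minLtrLen,maxLtrLen,minLtrSimilarity,minElementSpan,maxElementSpan
#'   see slots.
#' @param seedKmer,evidenceMin see slots.
#' @rdname DetectorParams-class
#' @export
DetectorParams <- function(minLtrLen = 80L, maxLtrLen = 2000L,
                           minLtrSimilarity = 0.75,
                           minElementSpan = 1000L, maxElementSpan = 25000L,
                           seedKmer = 12L, evidenceMin = 2L) {
  new("DetectorParams",
      minLtrLen = as.integer(minLtrLen), maxLtrLen = as.integer(maxLtrLen),
      minLtrSimilarity = minLtrSimilarity,
      minElementSpan = as.integer(minElementSpan),
      maxElementSpan = as.integer(maxElementSpan),
      seedKmer = as.integer(seedKmer), evidenceMin = as.integer(evidenceMin))
}

setMethod("show", "DetectorParams", function(object) {
  cat(sprintf(paste0(
    "DetectorParams: LTR %d-%d bp, similarity >= %.2f, span %d-%d bp,",
    " seed k=%d, evidenceMin=%d\n"),
    object@minLtrLen, object@maxLtrLen, object@minLtrSimilarity,
    object@minElementSpan, object@maxElementSpan,
    object@seedKmer, object@evidenceMin))
})

#' Homology filtering thresholds
#'
#' Thresholds for retaining homology hits and for the downstream integration
#' steps: the E-value and length filters applied to BLAST-style hits, the
#' merge gap, the conflict-filter coverage fraction, and the DIRS domain
#' E-value rules (reverse transcriptase plus methyl transferase or tyrosine
#' recombinase). All threshold comparisons are inclusive.
#'
#' @slot eMax maximum E-value for a retained hit (default 1e-10).
#' @slot minHitLen minimum alignment length (bp, default 100).
#' @slot mergeGap maximum inter-interval gap merged (bp, default 10;
#'   intervals fewer than 11 bp apart are merged).
#' @slot conflictCov fraction of an element's span covered by non-LTR repeat
#'   classes above which the element is removed (default 0.5).
#' @slot dirsRtE,dirsAuxE E-value bounds of the DIRS rule (1e-15, 1e-12).
#' @export
setClass("FilterParams", representation(
  eMax = "numeric", minHitLen = "integer", mergeGap = "integer",
  conflictCov = "numeric", dirsRtE = "numeric", dirsAuxE = "numeric"))

setValidity("FilterParams", function(object) {
  if (object@eMax <= 0 || object@dirsRtE <= 0 || object@dirsAuxE <= 0)
    return("E-value thresholds must be > 0")
  if (object@minHitLen <= 0L) return("minHitLen must be > 0")
  if (object@mergeGap < 0L) return("mergeGap must be >= 0")
  if (object@conflictCov <= 0 || object@conflictCov > 1)
    return("conflictCov must be in (0, 1]")
  TRUE
})

#' @param eMax,minHitLen,mergeGap,conflictCov,dirsRtE,dirsAuxE see slots.
#' @rdname FilterParams-class
#' @export
FilterParams <- function(eMax = 1e-10, minHitLen = 100L, mergeGap = 10L,
                         conflictCov = 0.5, dirsRtE = 1e-15,
                         dirsAuxE = 1e-12) {
  new("FilterParams", eMax = eMax, minHitLen = as.integer(minHitLen),
      mergeGap = as.integer(mergeGap), conflictCov = conflictCov,
      dirsRtE = dirsRtE, dirsAuxE = dirsAuxE)
}

setMethod("show", "FilterParams", function(object) {
  cat(sprintf(
    "FilterParams: E <= %g, len >= %d, mergeGap %d, conflictCov %.2f\n",
    object@eMax, object@minHitLen, object@mergeGap, object@conflictCov))
})

#' Evidence E-value thresholds for motif and domain hits
#'
#' @slot ntEMax maximum E-value for nucleotide motif (pHMM-style) hits
#'   (default 1e-5).
#' @slot protEMax maximum E-value for protein domain hits (default 1e-10).
#' @export
setClass("EvidenceThresholds",
  representation(ntEMax = "numeric", protEMax = "numeric"))

setValidity("EvidenceThresholds", function(object) {
  if (object@ntEMax <= 0 || object@protEMax <= 0)
    return("thresholds must be > 0")
  TRUE
})

#' @param ntEMax,protEMax see slots.
#' @rdname EvidenceThresholds-class
#' @export
EvidenceThresholds <- function(ntEMax = 1e-5, protEMax = 1e-10) {
  new("EvidenceThresholds", ntEMax = ntEMax, protEMax = protEMax)
}

setMethod("show", "EvidenceThresholds", function(object) {
  cat(sprintf("EvidenceThresholds: nucleotide E <= %g, protein E <= %g\n",
              object@ntEMax, object@protEMax))
})

# pipeline provenance tags; the universal source vocabulary
.SOURCES <- c("homology", "structural", "secondary")

# retroviral genera and LTR retrotransposon families used in lineage calls
.LINEAGES <- c("alpharetrovirus", "betaretrovirus", "gammaretrovirus",
               "deltaretrovirus", "epsilonretrovirus", "lentivirus",
               "spumavirus", "Ty1/Copia", "Ty3/Gypsy", "Bel/Pao", "DIRS",
               "unclassified")
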