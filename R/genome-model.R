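#' Build a validated annotation set
#'
#' Annotation sets are `GRanges` carrying a `source` provenance tag (one of
#' `homology`, `structural`, `secondary`), a `score` (E-value or similarity)
#' and a free-text `label`. When a [GenomeIndex] is supplied every record is
#' checked against chromosome bounds.
#'
#' @param gr a `GRanges` (strand may be `*`).
#' @param source provenance tag, recycled; one of
#'   `"homology"`, `"structural"`, `"secondary"`.
#' @param score optional numeric score, recycled.
#' @param label optional character label, recycled.
#' @param genome optional [GenomeIndex] for bounds checking.
#' @return a sorted `GRanges` with `source`, `score` and `label` metadata
#'   columns.
#' @examples
#' gr <- GRanges("chr1", IRanges(c(101, 206), c(200, 300)))
#' annotationSet(gr, source = "homology")
#' @export
annotationSet <- function(gr, source = "homology", score = NA_real_,
                          label = NA_character_, genome = NULL) {
  stopifnot(is(gr, "GRanges"))
  source <- rep_len(as.character(source), length(gr))
  bad <- !(source %in% .SOURCES)
  if (any(bad))
    stop("unknown source tag(s): ", paste(unique(source[bad]), collapse = ", "))
  mcols(gr)$source <- source
  mcols(gr)$score <- rep_len(as.numeric(score), length(gr))
  mcols(gr)$label <- rep_len(as.character(label), length(gr))
  if (!is.null(genome)) checkBounds(gr, genome)
  sort(gr, ignore.strand = TRUE)
}

#' Check that every record lies within its chromosome
#'
#' @param gr a `GRanges`.
#' @param genome a [GenomeIndex].
#' @return invisibly `TRUE`; errors naming the first offending record
#'   otherwise.
#' @export
checkBounds <- function(gr, genome) {
  stopifnot(is(genome, "GenomeIndex"))
  sl <- chromLengths(genome)
  chrom <- as.character(seqnames(gr))
  unknown <- which(!(chrom %in% names(sl)))
  if (length(unknown))
    stop("record ", unknown[1L], " on unknown chromosome '",
         chrom[unknown[1L]], "'")
  out <- which(start(gr) < 1L | end(gr) > sl[chrom])
  if (length(out))
    stop("record ", out[1L], " (", chrom[out[1L]], ":", start(gr)[out[1L]],
         "-", end(gr)[out[1L]], ") extends beyond chromosome bounds")
  invisible(TRUE)
}

#' Merge annotation intervals separated by at most a small gap
#'
#' Overlapping intervals, and intervals fewer than `maxGap + 1` intervening
#' bases apart, are unioned transitively. The default `maxGap = 10` merges
#' records fewer than 11 bp apart. Merging is strand-agnostic: loci, not
#' transcripts, are being annotated, and fragment hits may be reported on
#' either strand.
#'
#' @param records a `GRanges` (any metadata is dropped; the merged set keeps
#'   the set of contributing `source` tags per merged interval when present).
#' @param maxGap maximum number of intervening bases still merged (bp >= 0).
#' @param genome optional [GenomeIndex] for bounds checking.
#' @return a sorted `GRanges` in which consecutive intervals on a chromosome
#'   are separated by more than `maxGap` bases.
#' @examples
#' gr <- GRanges("chr1", IRanges(c(101, 206), c(200, 300)))
#' mergeAnnotations(gr, maxGap = 10)   # one interval 101-300
#' mergeAnnotations(GRanges("chr1", IRanges(c(101, 212), c(200, 300))), 10)
#' @export
mergeAnnotations <- function(records, maxGap = 10L, genome = NULL) {
  stopifnot(is(records, "GRanges"), maxGap >= 0)
  if (!is.null(genome)) checkBounds(records, genome)
  if (!length(records)) return(granges(records))
  merged <- reduce(records, min.gapwidth = as.integer(maxGap) + 1L,
                   ignore.strand = TRUE)
  if (!is.null(mcols(records)$source)) {
    ov <- findOverlaps(merged, records, maxgap = 0L, ignore.strand = TRUE)
    src <- split(mcols(records)$source[subjectHits(ov)], queryHits(ov))
    tags <- character(length(merged))
    tags[as.integer(names(src))] <-
      vapply(src, function(s) paste(sort(unique(s)), collapse = ","), "")
    mcols(merged)$source <- tags
  }
  sort(merged, ignore.strand = TRUE)
}

#' Overlap elements with features, optionally requiring the same orientation
#'
#' Reports every (element, feature) pair sharing at least one base on the
#' same chromosome. In `same-orientation` mode both records must be stranded
#' and carry equal strands; unstranded records never match in that mode.
#'
#' @param elements,features `GRanges`.
#' @param mode `"any"` (ignore strand) or `"same-orientation"`.
#' @return a `data.frame` with columns `element` and `feature` (indices into
#'   the inputs).
#' @export
strandIntersect <- function(elements, features,
                            mode = c("any", "same-orientation")) {
  mode <- match.arg(mode)
  ov <- findOverlaps(elements, features, ignore.strand = TRUE)
  q <- queryHits(ov); s <- subjectHits(ov)
  if (mode == "same-orientation") {
    es <- as.character(strand(elements))[q]
    fs <- as.character(strand(features))[s]
    keep <- es != "*" & fs != "*" & es == fs
    q <- q[keep]; s <- s[keep]
  }
  data.frame(element = q, feature = s)
}

#' Shortest edge-to-edge distance from each element to any feature
#'
#' Returns 0 for elements overlapping a feature, otherwise the number of
#' bases between the element and the nearest feature on the same chromosome.
#' Elements on chromosomes or contigs carrying no features get `NA`
#' ("non-defined"): such contigs cannot be assigned a distance at all.
#'
#' @param elements,features `GRanges`; strand is ignored.
#' @return numeric vector, one distance (bp) per element; `NA` = non-defined.
#' @export
nearestFeatureDistance <- function(elements, features) {
  d <- rep(NA_real_, length(elements))
  if (!length(elements) || !length(features)) return(d)
  hasFeat <- as.character(seqnames(elements)) %in%
    unique(as.character(seqnames(features)))
  hit <- suppressWarnings(
    distanceToNearest(elements, features, ignore.strand = TRUE))
  d[queryHits(hit)] <- mcols(hit)$distance
  d[!hasFeat] <- NA_real_
  ovl <- suppressWarnings(
    overlapsAny(elements, features, ignore.strand = TRUE))
  d[ovl] <- 0
  d
}

#' Coverage accounting across provenance sources
#'
#' Computes the per-source covered length, all pairwise overlap lengths, the
#' exclusive length of every observed source combination, and the union.
#' Exclusive combination categories partition the union exactly.
#'
#' @param sets named list of `GRanges`, one per source.
#' @return a list with elements `bySource` (named bp totals), `pairwise`
#'   (data.frame a, b, overlap_bp), `exclusive` (named bp per combination,
#'   names like `"homology+structural"`), and `union` (bp).
#' @examples
#' s <- list(homology   = GRanges("chr1", IRanges(1, 10000)),
#'           structural = GRanges("chr1", IRanges(8001, 13000)))
#' coverageSummary(s)
#' @export
coverageSummary <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  red <- lapply(sets, function(g) reduce(granges(g), ignore.strand = TRUE))
  bySource <- vapply(red, function(g) sum(as.numeric(width(g))), 0)
  nm <- names(sets)
  pairs <- if (length(nm) >= 2L) utils::combn(nm, 2L) else
    matrix(character(0), nrow = 2L)
  pairwise <- data.frame(
    a = pairs[1L, ], b = pairs[2L, ],
    overlap_bp = apply(pairs, 2L, function(p) {
      ov <- GenomicRanges::intersect(red[[p[1L]]], red[[p[2L]]],
                                     ignore.strand = TRUE)
      sum(as.numeric(width(ov)))
    }))
  # per-base membership signature via stacked coverage with powers of two
  weighted <- mapply(function(g, w) {
    mcols(g)$w <- rep(w, length(g))
    g
  }, red, 2^(seq_along(red) - 1L), SIMPLIFY = FALSE)
  all <- do.call(c, unname(weighted))
  if (!length(all)) {
    return(list(bySource = bySource, pairwise = pairwise,
                exclusive = setNames(numeric(0), character(0)), union = 0))
  }
  cov <- coverage(all, weight = mcols(all)$w)
  tot <- numeric(0)
  for (r in as.list(cov)) {
    v <- as.integer(runValue(r)); l <- as.numeric(runLength(r))
    keep <- v > 0L
    if (!any(keep)) next
    t1 <- tapply(l[keep], v[keep], sum)
    for (nmv in names(t1))
      tot[nmv] <- (if (nmv %in% names(tot)) tot[[nmv]] else 0) + t1[[nmv]]
  }
  comboName <- vapply(as.integer(names(tot)), function(code) {
    paste(nm[bitwAnd(code, 2^(seq_along(nm) - 1L)) > 0L], collapse = "+")
  }, "")
  exclusive <- setNames(as.numeric(tot), comboName)
  list(bySource = bySource, pairwise = pairwise, exclusive = exclusive,
       union = sum(exclusive))
}

#' Read and write annotation sets as BED or GFF3
#'
#' Thin wrappers over [rtracklayer::import()]/[rtracklayer::export()] that
#' preserve the `source` provenance tag (stored in the GFF3 source column /
#' BED name field) and round-trip coordinates exactly.
#'
#' @param path file path; format chosen by extension (`.bed`, `.gff3`,
#'   `.gff`).
#' @param gr a `GRanges` as built by [annotationSet()].
#' @return `readAnnotations`: a `GRanges`; `writeAnnotations`: invisibly the
#'   path.
#' @export
readAnnotations <- function(path) {
  fmt <- tolower(tools::file_ext(path))
  gr <- import(path)
  if (fmt == "bed") {
    if (!is.null(mcols(gr)$name)) {
      nm <- as.character(mcols(gr)$name)
      mcols(gr)$source <- ifelse(nm %in% .SOURCES, nm, NA_character_)
    }
  } else if (!is.null(mcols(gr)$source)) {
    mcols(gr)$source <- as.character(mcols(gr)$source)
  }
  gr
}

#' @rdname readAnnotations
#' @export
writeAnnotations <- function(gr, path) {
  fmt <- tolower(tools::file_ext(path))
  out <- gr
  if (fmt == "bed") {
    mcols(out) <- NULL
    if (!is.null(mcols(gr)$source)) mcols(out)$name <- mcols(gr)$source
    if (!is.null(mcols(gr)$score)) {
      sc <- mcols(gr)$score
      mcols(out)$score <- ifelse(is.na(sc), 0, pmin(pmax(sc, 0), 1000))
    }
    export(out, path, format = "bed")
  } else {
    if (is.null(mcols(out)$type)) mcols(out)$type <- "dispersed_repeat"
    export(out, path, format = "gff3")
  }
  invisible(path)
}
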