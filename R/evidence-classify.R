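# Lineage classification from nucleotide-motif and protein-domain evidence,
# with protein (especially reverse transcriptase) precedence.

#' Filter an element's motif/domain evidence against E-value thresholds
#'
#' Nucleotide hits are retained at `E <= ntEMax`, protein hits at
#' `E <= protEMax` (inclusive). The filtered bundle feeds both structural
#' acceptance and lineage classification.
#'
#' @param elementId element identifier (recorded on the bundle).
#' @param ntHits,protHits `data.frame`s of hits with at least `e_value`,
#'   `domain`, and (for classification) `lineage` and a span
#'   (`span_start`, `span_end`); either may be `NULL` or empty.
#' @param thresholds an [EvidenceThresholds].
#' @return a list with `element_id`, `nt` and `prot` (filtered data frames).
#' @export
evaluateCandidateEvidence <- function(elementId, ntHits = NULL,
                                      protHits = NULL,
                                      thresholds = EvidenceThresholds()) {
  keepHits <- function(hits, eMax) {
    if (is.null(hits) || !nrow(hits)) return(hits[0, , drop = FALSE])
    if (any(hits$e_value < 0)) stop("negative E-value")
    hits[hits$e_value <= eMax, , drop = FALSE]
  }
  empty <- data.frame(domain = character(0), e_value = numeric(0))
  list(element_id = elementId,
       nt = if (is.null(ntHits)) empty else
         keepHits(ntHits, thresholds@ntEMax),
       prot = if (is.null(protHits)) empty else
         keepHits(protHits, thresholds@protEMax))
}

.hitSpan <- function(hits) {
  if (!is.null(hits$span_start) && !is.null(hits$span_end))
    abs(hits$span_end - hits$span_start) + 1L
  else rep(0L, nrow(hits))
}

# best hit = lowest E; ties by longer span, then input order
.bestHit <- function(hits) {
  spans <- .hitSpan(hits)
  ord <- order(hits$e_value, -spans, seq_len(nrow(hits)))
  hits[ord[1L], , drop = FALSE]
}

#' Classify an element to a retroviral genus or retrotransposon family
#'
#' Uses the filtered evidence bundle from [evaluateCandidateEvidence()],
#' where each retained hit carries the lineage of its best-matching
#' reference. Protein evidence takes precedence over nucleotide evidence,
#' and among protein domains reverse transcriptase outranks the rest: the
#' call is the lineage of the best (lowest-E) protein RT hit; failing that,
#' the best protein hit of any domain; failing that, the best nucleotide
#' hit; otherwise `unclassified`. Equal-E ties are broken by longer
#' alignment span, then input order (logged via a `tie` attribute).
#'
#' @param bundle list as returned by [evaluateCandidateEvidence()], whose
#'   `nt`/`prot` data frames carry a `lineage` column.
#' @return a one-row `data.frame`: `element_id`, `label`, `evidence_level`
#'   (`protein`, `nucleotide` or `none`), `best_domain`, `best_e`.
#' @export
classifyLineage <- function(bundle) {
  res <- function(label, level, domain = NA_character_, e = NA_real_)
    data.frame(element_id = bundle$element_id, label = label,
               evidence_level = level, best_domain = domain, best_e = e,
               stringsAsFactors = FALSE)
  prot <- bundle$prot
  if (!is.null(prot) && nrow(prot)) {
    rt <- prot[prot$domain == "RT", , drop = FALSE]
    pool <- if (nrow(rt)) rt else prot
    best <- .bestHit(pool)
    out <- res(best$lineage, "protein", best$domain, best$e_value)
    ties <- sum(pool$e_value == best$e_value)
    if (ties > 1L) attr(out, "tie") <- ties
    return(out)
  }
  nt <- bundle$nt
  if (!is.null(nt) && nrow(nt)) {
    best <- .bestHit(nt)
    return(res(best$lineage, "nucleotide", best$domain, best$e_value))
  }
  res("unclassified", "none")
}

#' Classify many elements at once
#'
#' @param hits `data.frame` of all hits with columns `element_id`, `domain`,
#'   `kind` (`nucleotide`/`protein`), `e_value`, `lineage` and optionally
#'   spans.
#' @param thresholds an [EvidenceThresholds].
#' @return `data.frame` of one [classifyLineage()] row per element.
#' @export
classifyElements <- function(hits, thresholds = EvidenceThresholds()) {
  ids <- unique(hits$element_id)
  do.call(rbind, lapply(ids, function(id) {
    h <- hits[hits$element_id == id, , drop = FALSE]
    bundle <- evaluateCandidateEvidence(
      id,
      ntHits = h[h$kind == "nucleotide", , drop = FALSE],
      protHits = h[h$kind == "protein", , drop = FALSE],
      thresholds = thresholds)
    classifyLineage(bundle)
  }))
}
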