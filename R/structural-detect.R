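# Reference structural detector for paired-LTR elements.
#
# Candidate generation is exact k-mer seeding: positions sharing a k-mer at
# an admissible spacing are clustered on near-constant diagonals into
# putative LTR-pair blocks, which are refined by local alignment of the two
# repeat copies. Acceptance then requires internal/terminal sequence
# evidence (TG..CA termini, TSD, PBS, PPT, poly-A) or a protein-domain hit.

.PURINES <- c("A", "G")

.seqToCodes <- function(dna) {
  s <- strsplit(as.character(dna), "")[[1L]]
  codes <- match(s, c("A", "C", "G", "T")) - 1L
  codes
}

# rolling k-mer hash; NA where the window contains an ambiguous base
.kmerHash <- function(codes, k) {
  n <- length(codes)
  m <- n - k + 1L
  if (m < 1L) return(integer(0))
  h <- integer(m)
  for (j in 0:(k - 1L)) {
    h <- h + codes[(1L + j):(m + j)] * as.integer(4^(k - 1L - j))
  }
  h
}

# seed pairs (p1, p2) sharing a k-mer with offset p2 - p1 in [dmin, dmax]
.seedPairs <- function(h, dmin, dmax) {
  ok <- which(!is.na(h))
  if (length(ok) < 2L)
    return(data.frame(p1 = integer(0), d = integer(0)))
  ord <- ok[order(h[ok], ok)]
  hv <- h[ord]
  runEnds <- c(which(diff(hv) != 0L), length(hv))
  runStarts <- c(1L, head(runEnds, -1L) + 1L)
  keep <- which(runEnds - runStarts >= 1L)
  p1 <- integer(0); d <- integer(0)
  for (r in keep) {
    p <- ord[runStarts[r]:runEnds[r]]        # ascending positions
    np <- length(p)
    jlo <- 1L
    for (i in seq_len(np - 1L)) {
      for (j in (i + 1L):np) {
        off <- p[j] - p[i]
        if (off > dmax) break
        if (off >= dmin) { p1 <- c(p1, p[i]); d <- c(d, off) }
      }
    }
  }
  data.frame(p1 = p1, d = d)
}

# cluster seed pairs into candidate blocks on near-constant diagonals
.seedBlocks <- function(seeds, k, maxLtrLen, diagTol = 15L,
                        seedGapTol = 600L, minSeeds = 2L) {
  if (!nrow(seeds)) return(list())
  seeds <- seeds[order(seeds$d, seeds$p1), ]
  dBreaks <- c(0L, which(diff(seeds$d) > diagTol), nrow(seeds))
  blocks <- list()
  for (b in seq_len(length(dBreaks) - 1L)) {
    blk <- seeds[(dBreaks[b] + 1L):dBreaks[b + 1L], ]
    blk <- blk[order(blk$p1), ]
    pBreaks <- c(0L, which(diff(blk$p1) > seedGapTol), nrow(blk))
    for (q in seq_len(length(pBreaks) - 1L)) {
      sub <- blk[(pBreaks[q] + 1L):pBreaks[q + 1L], ]
      if (nrow(sub) < minSeeds) next
      span <- max(sub$p1) + k - 1L - min(sub$p1) + 1L
      if (span > maxLtrLen + 200L) next
      blocks[[length(blocks) + 1L]] <-
        list(p1lo = min(sub$p1), p1hi = max(sub$p1) + k - 1L,
             d = as.integer(round(stats::median(sub$d))))
    }
  }
  blocks
}

.ltrSubstMat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2,
                                           baseOnly = TRUE)
}

# refine one block into LTR-pair coordinates by local alignment
.refineBlock <- function(block, dna, pad = 150L) {
  n <- length(dna)
  lwS <- max(1L, block$p1lo - pad)
  lwE <- min(n, block$p1hi + pad)
  rwS <- max(1L, lwS + block$d)
  rwE <- min(n, lwE + block$d)
  if (rwS >= rwE || lwS >= lwE) return(NULL)
  left <- subseq(dna, lwS, lwE)
  right <- subseq(dna, rwS, rwE)
  al <- pairwiseAlignment(left, right, type = "local",
                          substitutionMatrix = .ltrSubstMat(),
                          gapOpening = 6, gapExtension = 2)
  if (length(al) == 0L || Biostrings::score(al) <= 0) return(NULL)
  pr <- Biostrings::pattern(al); sr <- Biostrings::subject(al)
  ls <- lwS + start(pr) - 1L; le <- lwS + end(pr) - 1L
  rs <- rwS + start(sr) - 1L; re <- rwS + end(sr) - 1L
  alnLen <- nchar(al)
  data.frame(left_start = ls, left_end = le,
             right_start = rs, right_end = re,
             similarity = nmatch(al) / alnLen)
}

#' Find candidate LTR pairs in one chromosome sequence
#'
#' Scans a sequence for pairs of similar direct repeats satisfying the
#' detector's distance and similarity constraints: LTR lengths within
#' `[minLtrLen, maxLtrLen]`, pairwise identity at least `minLtrSimilarity`,
#' and a full element span within `[minElementSpan, maxElementSpan]`.
#' Candidates are seeded by exact `seedKmer`-mers shared at admissible
#' spacings and refined by local alignment. Direct repeats are preserved
#' under reverse complement, so scanning the forward sequence covers
#' elements inserted on either strand; coordinates are always reported on
#' the forward strand.
#'
#' @param sequence a [Biostrings::DNAString] (or single-sequence
#'   `DNAStringSet`).
#' @param params a [DetectorParams].
#' @return a `data.frame` with columns `left_start`, `left_end`,
#'   `right_start`, `right_end` (1-based, closed), `similarity` and
#'   `element_span`; zero rows when the sequence is shorter than
#'   `minElementSpan` or nothing qualifies.
#' @export
findLTRPairCandidates <- function(sequence, params = DetectorParams()) {
  if (is(sequence, "DNAStringSet")) sequence <- sequence[[1L]]
  dna <- as(sequence, "DNAString")
  empty <- data.frame(left_start = integer(0), left_end = integer(0),
                      right_start = integer(0), right_end = integer(0),
                      similarity = numeric(0), element_span = integer(0))
  if (length(dna) < params@minElementSpan) return(empty)
  codes <- .seqToCodes(dna)
  k <- params@seedKmer
  h <- .kmerHash(codes, k)
  dmin <- max(params@minElementSpan - params@maxLtrLen, params@minLtrLen)
  dmax <- params@maxElementSpan - params@minLtrLen
  seeds <- .seedPairs(h, dmin, dmax)
  blocks <- .seedBlocks(seeds, k, params@maxLtrLen)
  if (!length(blocks)) return(empty)
  cand <- do.call(rbind, lapply(blocks, .refineBlock, dna = dna))
  if (is.null(cand) || !nrow(cand)) return(empty)
  cand <- unique(cand)
  llen <- cand$left_end - cand$left_start + 1L
  rlen <- cand$right_end - cand$right_start + 1L
  span <- cand$right_end - cand$left_start + 1L
  keep <- llen >= params@minLtrLen & llen <= params@maxLtrLen &
    rlen >= params@minLtrLen & rlen <= params@maxLtrLen &
    cand$right_start > cand$left_end &
    span >= params@minElementSpan & span <= params@maxElementSpan &
    cand$similarity >= params@minLtrSimilarity
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand$element_span <- cand$right_end - cand$left_start + 1L
  rownames(cand) <- NULL
  cand[order(cand$left_start), , drop = FALSE]
}

.countMatches <- function(a, b) sum(strsplit(a, "")[[1L]] == strsplit(b, "")[[1L]])

#' Collect internal and terminal sequence evidence for an LTR-pair candidate
#'
#' Evidence flags follow classical retroelement anatomy:
#' \describe{
#'   \item{tg_ca}{both LTRs start `TG` and end `CA` (no mismatches).}
#'   \item{tsd}{an identical 4-6 bp target-site duplication immediately
#'     outside both LTRs.}
#'   \item{pbs}{a primer binding site: at least 16/18 complementarity to the
#'     3'-terminal 18-mer of any supplied tRNA, within 20 bp downstream of
#'     the left LTR.}
#'   \item{ppt}{a polypurine tract: an 11 bp window with at least 9 purines
#'     ending within 20 bp upstream of the right LTR.}
#'   \item{polya}{an `AATAAA` polyadenylation motif within either LTR.}
#' }
#'
#' @param candidate one row of [findLTRPairCandidates()] output (or any list
#'   with `left_start`, `left_end`, `right_start`, `right_end`).
#' @param sequence the chromosome [Biostrings::DNAString].
#' @param trnaSet optional [Biostrings::DNAStringSet] of tRNA sequences for
#'   the PBS scan (skipped, flag `FALSE`, when absent).
#' @return a list with logical flags `tg_ca`, `tsd`, `pbs`, `ppt`, `polya`,
#'   the matched `tsd_seq` (or `NA`), and `n_evidence`.
#' @export
collectInternalEvidence <- function(candidate, sequence, trnaSet = NULL) {
  if (is(sequence, "DNAStringSet")) sequence <- sequence[[1L]]
  dna <- as(sequence, "DNAString")
  ls <- candidate$left_start; le <- candidate$left_end
  rs <- candidate$right_start; re <- candidate$right_end
  n <- length(dna)
  if (ls < 1L || re > n || ls >= le || rs >= re || le >= rs)
    stop("candidate outside sequence bounds or malformed")
  ltr5 <- as.character(subseq(dna, ls, le))
  ltr3 <- as.character(subseq(dna, rs, re))

  tgca <- startsWith(ltr5, "TG") && endsWith(ltr5, "CA") &&
    startsWith(ltr3, "TG") && endsWith(ltr3, "CA")

  tsd <- FALSE; tsdSeq <- NA_character_
  for (len in 6:4) {
    if (ls - len < 1L || re + len > n) next
    up <- as.character(subseq(dna, ls - len, ls - 1L))
    dn <- as.character(subseq(dna, re + 1L, re + len))
    if (up == dn && !grepl("[^ACGT]", up)) { tsd <- TRUE; tsdSeq <- up; break }
  }

  pbs <- FALSE
  if (!is.null(trnaSet) && length(trnaSet)) {
    probes <- vapply(seq_along(trnaSet), function(i) {
      tr <- trnaSet[[i]]
      if (length(tr) < 18L) return(NA_character_)
      as.character(reverseComplement(subseq(tr, length(tr) - 17L, length(tr))))
    }, "")
    probes <- probes[!is.na(probes)]
    for (off in 0:20) {
      ws <- le + 1L + off
      if (ws + 17L > min(n, rs - 1L)) break
      win <- as.character(subseq(dna, ws, ws + 17L))
      if (any(vapply(probes, function(p) .countMatches(win, p) >= 16L, TRUE))) {
        pbs <- TRUE; break
      }
    }
  }

  ppt <- FALSE
  for (endPos in (rs - 1L):(rs - 20L)) {
    if (endPos - 10L < le + 1L || endPos < 11L) break
    win <- strsplit(as.character(subseq(dna, endPos - 10L, endPos)), "")[[1L]]
    if (sum(win %in% .PURINES) >= 9L) { ppt <- TRUE; break }
  }

  polya <- grepl("AATAAA", ltr5, fixed = TRUE) ||
    grepl("AATAAA", ltr3, fixed = TRUE)

  flags <- c(tg_ca = tgca, tsd = tsd, pbs = pbs, ppt = ppt, polya = polya)
  c(as.list(flags), list(tsd_seq = tsdSeq, n_evidence = sum(flags)))
}

#' Call structural elements across a genome
#'
#' Runs candidate detection and evidence collection per chromosome and
#' applies the acceptance rule: an element is accepted when it carries at
#' least `evidenceMin` structural evidence flags (TG..CA, TSD, PBS, PPT,
#' poly-A) or at least one protein/nucleotide domain hit passing the
#' evidence thresholds. Overlapping accepted candidates are resolved by
#' keeping the highest `similarity * (evidence + domain)` score (ties:
#' longer element, then leftmost), except that an element wholly inside
#' another's internal region is kept and flagged as nested.
#'
#' @param genome a named [Biostrings::DNAStringSet] or FASTA path.
#' @param params a [DetectorParams].
#' @param trnaSet optional tRNA `DNAStringSet` (or FASTA path) for PBS
#'   evidence.
#' @param domainHits optional `data.frame` of domain hits with genomic
#'   coordinates (`chrom`, `start`, `end`, `kind`, `e_value`); hits
#'   overlapping a candidate's internal region and passing `thresholds`
#'   count as domain support.
#' @param thresholds an [EvidenceThresholds] for `domainHits`.
#' @return a `GRanges` of candidates (span = full element) with metadata
#'   columns `element_id`, LTR sub-coordinates, `similarity`, the five
#'   evidence flags, `tsd_seq`, `n_evidence`, `n_domain`, `accepted` and
#'   `nested_parent`.
#' @export
callStructuralElements <- function(genome, params = DetectorParams(),
                                   trnaSet = NULL, domainHits = NULL,
                                   thresholds = EvidenceThresholds()) {
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  if (is.character(trnaSet)) trnaSet <- readDNAStringSet(trnaSet)
  stopifnot(is(genome, "DNAStringSet"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  rows <- list()
  for (chrom in names(genome)) {
    cand <- findLTRPairCandidates(genome[[chrom]], params)
    if (!nrow(cand)) next
    ev <- lapply(seq_len(nrow(cand)), function(i)
      collectInternalEvidence(cand[i, ], genome[[chrom]], trnaSet))
    cand$chrom <- chrom
    for (f in c("tg_ca", "tsd", "pbs", "ppt", "polya"))
      cand[[f]] <- vapply(ev, `[[`, TRUE, f)
    cand$tsd_seq <- vapply(ev, `[[`, "", "tsd_seq")
    cand$n_evidence <- vapply(ev, function(e) as.integer(e$n_evidence), 0L)
    rows[[length(rows) + 1L]] <- cand
  }
  if (!length(rows)) {
    gr <- GRanges()
    return(gr)
  }
  cand <- do.call(rbind, rows)

  # domain support: hits overlapping the internal region and passing E cuts
  cand$n_domain <- 0L
  if (!is.null(domainHits) && nrow(domainHits)) {
    pass <- ifelse(domainHits$kind == "protein",
                   domainHits$e_value <= thresholds@protEMax,
                   domainHits$e_value <= thresholds@ntEMax)
    dh <- domainHits[pass, , drop = FALSE]
    if (nrow(dh)) {
      dgr <- GRanges(dh$chrom, IRanges(dh$start, dh$end))
      internal <- GRanges(cand$chrom,
                          IRanges(cand$left_end + 1L, cand$right_start - 1L))
      cand$n_domain <- countOverlaps(internal, dgr)
    }
  }

  cand$accepted <- cand$n_evidence >= params@evidenceMin | cand$n_domain >= 1L

  # overlap resolution among accepted candidates
  cand$score <- cand$similarity * (cand$n_evidence + cand$n_domain)
  cand$nested_parent <- NA_character_
  accIdx <- which(cand$accepted)
  if (length(accIdx) > 1L) {
    a <- cand[accIdx, ]
    ord <- order(-a$score, -a$element_span, a$left_start)
    kept <- integer(0)
    drop <- logical(nrow(a))
    nest <- rep(NA_integer_, nrow(a))
    for (i in ord) {
      conflict <- FALSE
      for (j in kept) {
        if (a$chrom[i] != a$chrom[j]) next
        overl <- a$left_start[i] <= a$right_end[j] &&
          a$right_end[i] >= a$left_start[j]
        if (!overl) next
        iInJ <- a$left_start[i] > a$left_end[j] &&
          a$right_end[i] < a$right_start[j]
        jInI <- a$left_start[j] > a$left_end[i] &&
          a$right_end[j] < a$right_start[i]
        if (iInJ) { nest[i] <- j } else if (jInI) { nest[j] <- i }
        else { conflict <- TRUE; break }
      }
      if (conflict) drop[i] <- TRUE else kept <- c(kept, i)
    }
    cand$accepted[accIdx[drop]] <- FALSE
    ids <- sprintf("SIE_%s_%d", a$chrom, a$left_start)
    cand$nested_parent[accIdx[!is.na(nest)]] <- ids[nest[!is.na(nest)]]
  }

  gr <- GRanges(cand$chrom, IRanges(cand$left_start, cand$right_end),
                strand = "+")
  mcols(gr) <- DataFrame(
    element_id = sprintf("SIE_%s_%d", cand$chrom, cand$left_start),
    ltr5_start = cand$left_start, ltr5_end = cand$left_end,
    ltr3_start = cand$right_start, ltr3_end = cand$right_end,
    similarity = cand$similarity,
    tg_ca = cand$tg_ca, tsd = cand$tsd, pbs = cand$pbs, ppt = cand$ppt,
    polya = cand$polya, tsd_seq = cand$tsd_seq,
    n_evidence = cand$n_evidence, n_domain = cand$n_domain,
    accepted = cand$accepted, nested_parent = cand$nested_parent)
  sort(gr, ignore.strand = TRUE)
}
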