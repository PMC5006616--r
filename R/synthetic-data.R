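# Synthetic genomes with planted truth: intact elements (controlled LTR
# divergence, TSDs, PBS/PPT, domain placeholders), fragments, gene models,
# transcripts and a recombination map, so every pipeline stage can be
# validated without external data.

.BASES <- c("A", "C", "G", "T")

.randomBases <- function(n, gc = 0.42) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(.BASES, n, replace = TRUE, prob = p)
}

#' Random background sequence
#'
#' i.i.d. bases at a configurable GC fraction; composition beyond mononucleotide
#' frequency is deliberately not modelled.
#'
#' @param n length (bp).
#' @param gc GC fraction.
#' @return character string.
#' @export
randomSequence <- function(n, gc = 0.42) paste(.randomBases(n, gc),
                                               collapse = "")

#' Mutate a sequence to a target divergence
#'
#' Substitutions are drawn per site with probability `d`, uniformly over the
#' three alternative bases; optional indels (single-base, insertion or
#' deletion with equal probability) at rate `indelRate`.
#'
#' @param seq character sequence.
#' @param d per-site substitution probability in \[0, 1\].
#' @param indelRate per-site indel probability (default 0).
#' @return mutated character sequence.
#' @export
mutateSequence <- function(seq, d, indelRate = 0) {
  if (d < 0 || d > 1) stop("d must be in [0, 1]")
  s <- strsplit(seq, "")[[1L]]
  hit <- runif(length(s)) < d
  if (any(hit)) {
    s[hit] <- vapply(s[hit], function(b)
      sample(setdiff(.BASES, b), 1L), "")
  }
  if (indelRate > 0) {
    ind <- runif(length(s)) < indelRate
    if (any(ind)) {
      out <- character(0)
      for (i in seq_along(s)) {
        if (!ind[i]) { out <- c(out, s[i]); next }
        if (runif(1) < 0.5) out <- c(out, s[i], sample(.BASES, 1L))
        # else deletion: drop the base
      }
      s <- out
    }
  }
  paste(s, collapse = "")
}

# run code under a private RNG stream, restoring the caller's stream
.withLocalSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Synthetic domain library with lineage labels
#'
#' A small deterministic set of synthetic nucleotide "domain" sequences
#' (gag, RT, env) per lineage, used both to build planted elements and as
#' the labelled reference set for classification tests. Synthetic stand-in:
#' the sequences carry no biological homology.
#'
#' @param lineages lineage labels to include.
#' @param domainLen domain length (bp).
#' @return named list `lineage -> named character vector of domains`.
#' @export
syntheticDomainLibrary <- function(lineages = c("alpharetrovirus",
                                                "betaretrovirus",
                                                "gammaretrovirus",
                                                "Ty3/Gypsy"),
                                   domainLen = 500L) {
  .withLocalSeed(700919L, {
    out <- lapply(seq_along(lineages), function(i)
      setNames(vapply(1:3, function(j) randomSequence(domainLen, 0.45), ""),
               c("gag", "RT", "env")))
    names(out) <- lineages
    out
  })
}

# LTR template: TG ... AATAAA ... CA
.ltrTemplate <- function(len, gc = 0.42) {
  stopifnot(len >= 20L)
  core <- .randomBases(len - 10L, gc)
  paste(c("TG", core[1:floor(len / 2 - 5)], "AATAAA",
          core[(floor(len / 2 - 5) + 1L):(len - 10L)], "CA"),
        collapse = "")
}

# internal template: PBS (3 bp in), domains, PPT just before the 3' end
.internalTemplate <- function(len, trna, domains, gc = 0.42) {
  pbs <- as.character(reverseComplement(
    subseq(trna, length(trna) - 17L, length(trna))))
  ppt <- "AGGAGGGGAGG"                    # 11 bp, 11 purines
  dom <- paste(domains, collapse = paste(.randomBases(40L, gc),
                                         collapse = ""))
  fixed <- nchar(pbs) + 3L + nchar(ppt) + 2L + nchar(dom)
  fillLen <- len - fixed
  if (fillLen < 0L) stop("internal template length too short for contents")
  fill <- paste(.randomBases(fillLen, gc), collapse = "")
  body <- paste0(paste(.randomBases(3L, gc), collapse = ""), pbs, dom, fill)
  list(seq = paste0(body, ppt, paste(.randomBases(2L, gc), collapse = "")),
       domainOffset = 3L + nchar(pbs) + 1L,
       domainLen = nchar(dom))
}

#' Simulation configuration
#'
#' Defaults give a desk-scale genome: two chromosomes totalling 2 Mb,
#' 10 intact elements at divergences drawn from \[0.01, 0.12\] (young
#' insertions dominate real element populations), 50 fragments at
#' divergences up to 0.2, 40 genes, 500 kb recombination bins.
#'
#' @param chromLengths chromosome lengths (bp).
#' @param gc background GC fraction.
#' @param nSie number of planted intact elements.
#' @param divergence sampler (function of n) or vector of LTR-pair
#'   divergences.
#' @param ltrLenRange,internalLenRange LTR / internal length ranges (bp).
#' @param nFragments,fragmentLenRange planted fragment count and lengths.
#' @param nOtherRepeats planted LINE-like (conflicting-class) fragments.
#' @param nGenes gene model count.
#' @param exonCountRange exons per gene.
#' @param recombBin recombination map bin size (bp).
#' @param expressedFraction fraction of elements given a covering
#'   transcript.
#' @param seed RNG seed.
#' @return a list of class `ltrSimConfig`.
#' @export
simulationConfig <- function(chromLengths = c(simchr1 = 1200000L,
                                              simchr2 = 800000L),
                             gc = 0.42, nSie = 10L,
                             divergence = function(n) runif(n, 0.01, 0.12),
                             ltrLenRange = c(250L, 400L),
                             internalLenRange = c(3000L, 6000L),
                             nFragments = 50L,
                             fragmentLenRange = c(60L, 800L),
                             nOtherRepeats = 10L,
                             nGenes = 40L, exonCountRange = c(2L, 5L),
                             recombBin = 500000L,
                             expressedFraction = 0.3, seed = 17L) {
  cfg <- list(chromLengths = chromLengths, gc = gc, nSie = nSie,
              divergence = divergence, ltrLenRange = ltrLenRange,
              internalLenRange = internalLenRange,
              nFragments = nFragments, fragmentLenRange = fragmentLenRange,
              nOtherRepeats = nOtherRepeats, nGenes = nGenes,
              exonCountRange = exonCountRange, recombBin = recombBin,
              expressedFraction = expressedFraction, seed = seed)
  stopifnot(all(chromLengths > 0), nSie >= 0, nFragments >= 0, nGenes >= 0)
  class(cfg) <- "ltrSimConfig"
  cfg
}

.addOcc <- function(occ, ir) if (is.null(occ)) ir else c(occ, ir)

# non-overlapping placement with rejection sampling
.placeSpan <- function(occupied, chromLengths, len, margin = 20L,
                       tries = 400L) {
  for (t in seq_len(tries)) {
    ci <- sample.int(length(chromLengths), 1L,
                     prob = as.numeric(chromLengths))
    chrom <- names(chromLengths)[ci]
    maxStart <- chromLengths[[ci]] - len - margin
    if (maxStart <= margin + 1L) next
    s <- margin + 1L + floor(runif(1) * (maxStart - margin))
    cand <- IRanges(s - margin, s + len + margin)
    occ <- occupied[[chrom]]
    if (is.null(occ) || !length(occ) ||
        !any(overlapsAny(cand, occ))) {
      return(list(chrom = chrom, start = as.integer(s)))
    }
  }
  stop("infeasible planting density on chromosome ",
       paste(names(chromLengths), collapse = ","))
}

#' Simulate a genome with planted truth
#'
#' Generates multi-chromosome background sequence and plants intact
#' LTR elements (each LTR copy independently mutated at `d/2` so the pair
#' diverges by about `d`; a 4-6 bp TSD duplicated outside both LTRs; PBS,
#' PPT, poly-A and TG..CA built into the templates; lineage-tagged domain
#' placeholders inside), plus fragments derived from the element templates,
#' LINE-like conflicting repeats, gene models with exon/UTR structure,
#' covering transcripts for a subset of elements, a binned recombination
#' map, and a synthetic BLAST-style hit table for the planted fragments
#' (E-values from the declining heuristic `E = 10^-(identity * length / 5)`,
#' synthetic by construction: only ordering and threshold behaviour are
#' meaningful).
#'
#' @param config an [simulationConfig()] list.
#' @param outdir optional directory; when given, writes `genome.fa`,
#'   `trna.fa`, `genes.gff3`, `transcripts.gff`, `recomb.tsv`, `hits.tsv`,
#'   `repeats.out`, `truth.json` and `truth.gff3`.
#' @return a list: `genome` (DNAStringSet), `truth` (data.frame),
#'   `genes`, `exons`, `utr5`, `utr3` (GRanges), `transcripts` (named list
#'   of GRanges by tissue), `recomb` (GRanges), `hits` (data.frame),
#'   `otherRepeats` (GRanges), `trna` (DNAStringSet), `genomeIndex`.
#' @export
simulateGenome <- function(config = simulationConfig(), outdir = NULL) {
  stopifnot(inherits(config, "ltrSimConfig"))
  set.seed(config$seed)
  cl <- config$chromLengths
  chroms <- lapply(cl, function(n) .randomBases(n, config$gc))

  trna <- DNAStringSet(.withLocalSeed(761003L, {
    vapply(1:5, function(i) randomSequence(76L, 0.5), "")
  }))
  names(trna) <- paste0("tRNA", 1:5)
  domLib <- syntheticDomainLibrary()
  lineages <- names(domLib)

  occupied <- setNames(vector("list", length(cl)), names(cl))
  truth <- list()
  templates <- list()

  dval <- if (is.function(config$divergence))
    config$divergence(config$nSie) else
    rep_len(config$divergence, config$nSie)

  # --- intact elements ---
  for (i in seq_len(config$nSie)) {
    lin <- lineages[1L + (i - 1L) %% length(lineages)]
    ltrLen <- sample(config$ltrLenRange[1L]:config$ltrLenRange[2L], 1L)
    intLen <- sample(config$internalLenRange[1L]:config$internalLenRange[2L],
                     1L)
    ltr <- .ltrTemplate(ltrLen, config$gc)
    int <- .internalTemplate(intLen, trna[[1L]], domLib[[lin]], config$gc)
    d <- dval[i]
    ltr5 <- mutateSequence(ltr, d / 2)
    ltr3 <- mutateSequence(ltr, d / 2)
    body <- paste0(ltr5, int$seq, ltr3)
    tsdLen <- sample(4:6, 1L)
    tsd <- paste(.randomBases(tsdLen, config$gc), collapse = "")
    elem <- paste0(tsd, body, tsd)
    at <- .placeSpan(occupied, cl, nchar(elem))
    s <- strsplit(elem, "")[[1L]]
    pos <- at$start:(at$start + length(s) - 1L)
    chroms[[at$chrom]][pos] <- s
    occupied[[at$chrom]] <- .addOcc(occupied[[at$chrom]],
                                    IRanges(at$start,
                                            at$start + length(s) - 1L))
    eStart <- at$start + tsdLen            # element span minus TSDs
    eEnd <- at$start + nchar(elem) - tsdLen - 1L
    id <- sprintf("planted_sie_%02d", i)
    templates[[id]] <- paste0(ltr, int$seq, ltr)
    truth[[length(truth) + 1L]] <- data.frame(
      id = id, type = "SIE", chrom = at$chrom,
      start = eStart, end = eEnd, strand = "+",
      divergence = d, lineage = lin, tsd_seq = tsd,
      ltr5_start = eStart, ltr5_end = eStart + nchar(ltr5) - 1L,
      ltr3_start = eEnd - nchar(ltr3) + 1L, ltr3_end = eEnd,
      stringsAsFactors = FALSE)
  }

  # --- fragments of element templates ---
  hits <- list()
  if (config$nSie > 0L) for (i in seq_len(config$nFragments)) {
    src <- sample(names(templates), 1L)
    tmpl <- templates[[src]]
    fl <- sample(config$fragmentLenRange[1L]:config$fragmentLenRange[2L], 1L)
    fl <- min(fl, nchar(tmpl))
    fs <- sample.int(nchar(tmpl) - fl + 1L, 1L)
    d <- runif(1, 0.02, 0.2)
    frag <- mutateSequence(substr(tmpl, fs, fs + fl - 1L), d)
    at <- .placeSpan(occupied, cl, nchar(frag))
    s <- strsplit(frag, "")[[1L]]
    pos <- at$start:(at$start + length(s) - 1L)
    chroms[[at$chrom]][pos] <- s
    occupied[[at$chrom]] <- .addOcc(occupied[[at$chrom]],
                                    IRanges(at$start,
                                            at$start + length(s) - 1L))
    fid <- sprintf("planted_frag_%03d", i)
    truth[[length(truth) + 1L]] <- data.frame(
      id = fid, type = "fragment", chrom = at$chrom,
      start = at$start, end = at$start + length(s) - 1L, strand = "+",
      divergence = d, lineage = NA_character_, tsd_seq = NA_character_,
      ltr5_start = NA_integer_, ltr5_end = NA_integer_,
      ltr3_start = NA_integer_, ltr3_end = NA_integer_,
      stringsAsFactors = FALSE)
    ident <- 1 - d
    hits[[length(hits) + 1L]] <- data.frame(
      qseqid = src, sseqid = at$chrom, pident = ident,
      length = length(s),
      evalue = 10^-pmin(ident * length(s) / 5, 300),
      bitscore = 2 * length(s) * ident,
      sstart = at$start, send = at$start + length(s) - 1L,
      strand = "+", tool = "blastn", stringsAsFactors = FALSE)
  }

  # --- LINE-like conflicting repeats ---
  cr1 <- .withLocalSeed(810217L, randomSequence(2000L, 0.44))
  otherRows <- list()
  for (i in seq_len(config$nOtherRepeats)) {
    fl <- sample(150:900, 1L)
    fs <- sample.int(nchar(cr1) - fl + 1L, 1L)
    d <- runif(1, 0.05, 0.2)
    frag <- mutateSequence(substr(cr1, fs, fs + fl - 1L), d)
    at <- .placeSpan(occupied, cl, nchar(frag))
    s <- strsplit(frag, "")[[1L]]
    chroms[[at$chrom]][at$start:(at$start + length(s) - 1L)] <- s
    occupied[[at$chrom]] <- .addOcc(occupied[[at$chrom]],
                                    IRanges(at$start,
                                            at$start + length(s) - 1L))
    otherRows[[length(otherRows) + 1L]] <- data.frame(
      chrom = at$chrom, start = at$start,
      end = at$start + length(s) - 1L, divergence = d,
      stringsAsFactors = FALSE)
  }
  lv <- function(ch) factor(ch, levels = names(cl))
  otherRepeats <- if (length(otherRows)) {
    o <- do.call(rbind, otherRows)
    g <- GRanges(lv(o$chrom), IRanges(o$start, o$end), strand = "+")
    mcols(g)$repeat_name <- "CR1_syn"
    mcols(g)$repeat_class <- "LINE/CR1"
    mcols(g)$divergence <- o$divergence
    g
  } else GRanges()

  # --- gene models ---
  genes <- list(); exons <- list(); utr5 <- list(); utr3 <- list()
  for (i in seq_len(config$nGenes)) {
    glen <- sample(2000:10000, 1L)
    at <- .placeSpan(occupied, cl, glen, margin = 5L)
    gStart <- at$start; gEnd <- at$start + glen - 1L
    strand <- sample(c("+", "-"), 1L)
    nEx <- sample(config$exonCountRange[1L]:config$exonCountRange[2L], 1L)
    cuts <- sort(sample(seq(gStart + 50L, gEnd - 50L), 2L * nEx - 2L))
    bounds <- matrix(c(gStart, cuts, gEnd), ncol = 2L, byrow = TRUE)
    gid <- sprintf("gene%03d", i)
    genes[[i]] <- GRanges(lv(at$chrom), IRanges(gStart, gEnd),
                          strand = strand, gene_id = gid)
    exGr <- GRanges(lv(at$chrom), IRanges(bounds[, 1L], bounds[, 2L]),
                    strand = strand, gene_id = gid)
    exons[[i]] <- exGr
    first <- exGr[if (strand == "+") 1L else length(exGr)]
    last <- exGr[if (strand == "+") length(exGr) else 1L]
    u5 <- resize(first, width = max(1L, floor(width(first) / 4)),
                 fix = if (strand == "+") "start" else "end")
    u3 <- resize(last, width = max(1L, floor(width(last) / 4)),
                 fix = if (strand == "+") "end" else "start")
    mcols(u5)$gene_id <- gid; mcols(u3)$gene_id <- gid
    utr5[[i]] <- u5; utr3[[i]] <- u3
  }
  catG <- function(l) if (length(l)) do.call(c, l) else GRanges()
  genes <- catG(genes); exons <- catG(exons)
  utr5 <- catG(utr5); utr3 <- catG(utr3)

  # --- transcripts: cover internal regions of designated elements ---
  truthDf <- do.call(rbind, truth)
  if (is.null(truthDf))
    truthDf <- data.frame(id = character(0), type = character(0))
  sieRows <- truthDf[truthDf$type == "SIE", , drop = FALSE]
  nExpr <- ceiling(nrow(sieRows) * config$expressedFraction)
  exprIdx <- if (nrow(sieRows)) seq_len(nExpr) else integer(0)
  tissues <- c("embryo", "ovary")
  transcripts <- setNames(vector("list", length(tissues)), tissues)
  for (t in tissues) transcripts[[t]] <- GRanges()
  if (length(exprIdx)) {
    full <- sieRows[exprIdx, , drop = FALSE]
    txFull <- GRanges(lv(full$chrom),
                      IRanges(full$ltr5_end + 1L - 30L,
                              full$ltr3_start - 1L + 30L),
                      strand = full$strand)
    mcols(txFull)$transcript_id <- paste0("tx_full_", full$id)
    transcripts[["embryo"]] <- txFull
    half <- sieRows[seq_len(min(nrow(sieRows), nExpr + 2L)), , drop = FALSE]
    mid <- floor((half$ltr5_end + half$ltr3_start) / 2)
    txHalf <- GRanges(lv(half$chrom), IRanges(half$ltr5_end + 1L, mid),
                      strand = half$strand)
    mcols(txHalf)$transcript_id <- paste0("tx_part_", half$id)
    transcripts[["ovary"]] <- txHalf
  }

  # --- recombination map ---
  recomb <- list()
  for (ch in names(cl)) {
    starts <- seq(1L, cl[[ch]], by = config$recombBin)
    ends <- pmin(starts + config$recombBin - 1L, cl[[ch]])
    g <- GRanges(lv(ch), IRanges(starts, ends))
    mcols(g)$rate <- round(exp(runif(length(g), log(0.5), log(8))), 3)
    recomb[[ch]] <- g
  }
  recomb <- do.call(c, unname(recomb))

  genome <- DNAStringSet(vapply(chroms, paste, "", collapse = ""))
  names(genome) <- names(cl)
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(qseqid = character(0), sseqid = character(0),
               pident = numeric(0), length = integer(0),
               evalue = numeric(0), bitscore = numeric(0),
               sstart = integer(0), send = integer(0),
               strand = character(0), tool = character(0))

  out <- list(genome = genome, truth = truthDf, genes = genes,
              exons = exons, utr5 = utr5, utr3 = utr3,
              transcripts = transcripts, recomb = recomb, hits = hits,
              otherRepeats = otherRepeats, trna = trna,
              genomeIndex = GenomeIndex(cl), config = config)
  if (!is.null(outdir)) writeSimulation(out, outdir)
  out
}

#' Write a simulation to disk in standard formats
#'
#' @param sim the [simulateGenome()] result.
#' @param outdir output directory (created if needed).
#' @return invisibly the directory.
#' @export
writeSimulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outdir, f)
  writeXStringSet(sim$genome, fp("genome.fa"))
  writeXStringSet(sim$trna, fp("trna.fa"))
  g <- sim$genes
  if (length(g)) {
    feats <- c(`gene` = list(sim$genes), exon = list(sim$exons),
               five_prime_UTR = list(sim$utr5),
               three_prime_UTR = list(sim$utr3))
    all <- do.call(c, unname(feats))
    mcols(all)$type <- rep(names(feats), vapply(feats, length, 0L))
    export(all, fp("genes.gff3"), format = "gff3")
  }
  tx <- do.call(c, unname(lapply(names(sim$transcripts), function(t) {
    x <- sim$transcripts[[t]]
    if (length(x)) mcols(x)$tissue <- t
    x
  })))
  if (length(tx)) {
    mcols(tx)$type <- "transcript"
    export(tx, fp("transcripts.gff3"), format = "gff3")
  }
  rec <- data.frame(chrom = as.character(seqnames(sim$recomb)),
                    start = start(sim$recomb), end = end(sim$recomb),
                    rate = mcols(sim$recomb)$rate)
  write.table(rec, fp("recomb.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  h <- sim$hits
  blast6 <- data.frame(h$qseqid, h$sseqid, round(h$pident * 100, 2),
                       h$length, 0L, 0L, 1L, h$length, h$sstart, h$send,
                       signif(h$evalue, 3), round(h$bitscore, 1))
  write.table(blast6, fp("hits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeRepeatMaskerOut(sim$otherRepeats, fp("repeats.out"))
  write_json(sim$truth, fp("truth.json"), dataframe = "rows",
             na = "null", digits = NA)
  tr <- sim$truth[!is.na(sim$truth$start), , drop = FALSE]
  if (nrow(tr)) {
    tg <- GRanges(tr$chrom, IRanges(tr$start, tr$end), strand = tr$strand)
    mcols(tg)$ID <- tr$id
    mcols(tg)$type <- ifelse(tr$type == "SIE", "LTR_retrotransposon",
                             "repeat_fragment")
    export(tg, fp("truth.gff3"), format = "gff3")
  }
  invisible(outdir)
}

#' Write a minimal RepeatMasker-style .out file
#'
#' @param gr `GRanges` with `repeat_name`, `repeat_class`, `divergence`.
#' @param path output path.
#' @return invisibly the path.
#' @export
writeRepeatMaskerOut <- function(gr, path) {
  header <- c(
    paste("  SW   perc perc perc  query     position in query    ",
          "matching repeat"),
    paste("score   div. del. ins.  sequence  begin  end   (left) ",
          "repeat    class/family"),
    "")
  rows <- if (length(gr)) vapply(seq_along(gr), function(i) {
    sprintf(" 1000 %6.1f  0.0  0.0  %s %d %d (0) %s %s %s 1 %d (0) %d",
            mcols(gr)$divergence[i] * 100,
            as.character(seqnames(gr))[i], start(gr)[i], end(gr)[i],
            ifelse(as.character(strand(gr))[i] == "-", "C", "+"),
            mcols(gr)$repeat_name[i], mcols(gr)$repeat_class[i],
            width(gr)[i], i)
  }, "") else character(0)
  writeLines(c(header, rows), path)
  invisible(path)
}
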