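# Genomic distribution statistics: density and its correlates, cluster
# calling, the Monte-Carlo random-integration null, TU-distance profiles
# with enrichment tests, subfeature overlap and expression completeness.

.DIST_CATEGORIES <- c("TU", paste0("(", 0:9 * 10, ",", 1:10 * 10, "]"),
                      ">100kb", "ND")

#' Per-chromosome element density
#'
#' @param elements `GRanges` of elements.
#' @param genome a [GenomeIndex].
#' @return `data.frame` with `chrom`, `length_bp`, `n`, `density_per_mb`.
#' @export
chromosomeDensityTable <- function(elements, genome) {
  checkBounds(elements, genome)
  sl <- chromLengths(genome)
  n <- table(factor(as.character(seqnames(elements)), levels = names(sl)))
  data.frame(chrom = names(sl), length_bp = as.numeric(sl),
             n = as.integer(n),
             density_per_mb = as.integer(n) / (as.numeric(sl) / 1e6),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlates of chromosome element density
#'
#' Log10-transforms density, chromosome length, gene density and
#' recombination rate, computes all pairwise Pearson correlations, and fits
#' a Gaussian identity-link GLM of log-density on log-length and
#' log-recombination rate. Chromosomes named in `exclude` are dropped before
#' fitting and reported.
#'
#' @param density `data.frame` from [chromosomeDensityTable()].
#' @param geneDensity named vector of gene densities per chromosome
#'   (genes/Mb), or `NULL` to omit.
#' @param recombRate named vector of mean recombination rates (cM/Mb).
#' @param exclude chromosome names excluded from the fit.
#' @return a list with `correlations` (data.frame pairs, r, p), `glm`
#'   (fitted model), `coefficients` (coefficient table) and `excluded`.
#' @export
densityCorrelates <- function(density, geneDensity = NULL, recombRate,
                              exclude = character(0)) {
  d <- density[!(density$chrom %in% exclude), , drop = FALSE]
  d <- d[match(names(recombRate), d$chrom, nomatch = 0L), , drop = FALSE]
  rec <- recombRate[d$chrom]
  vars <- list(density = d$density_per_mb, length = d$length_bp,
               recomb = as.numeric(rec))
  if (!is.null(geneDensity)) vars$genes <- as.numeric(geneDensity[d$chrom])
  if (length(d$chrom) < 3L) stop("need at least 3 non-excluded chromosomes")
  for (v in names(vars)) {
    bad <- which(!(vars[[v]] > 0))
    if (length(bad))
      stop("non-positive ", v, " before log10 on chromosome ",
           d$chrom[bad[1L]])
  }
  lg <- lapply(vars, log10)
  prs <- utils::combn(names(lg), 2L)
  correlations <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
    ct <- cor.test(lg[[prs[1L, i]]], lg[[prs[2L, i]]], method = "pearson")
    data.frame(a = prs[1L, i], b = prs[2L, i],
               r = unname(ct$estimate), p = ct$p.value)
  }))
  fitData <- data.frame(logD = lg$density, logL = lg$length,
                        logR = lg$recomb)
  fit <- glm(logD ~ logL + logR, data = fitData, family = gaussian())
  list(correlations = correlations, glm = fit,
       coefficients = summary(fit)$coefficients, excluded = exclude)
}

# members of >= minCount runs spanning <= window, from sorted positions;
# the continuous-slide limit of a fixed-width window scan
.clusterMemberRuns <- function(x, window = 1e6, minCount = 5L) {
  n <- length(x)
  if (n < minCount) return(list())
  stopifnot(!is.unsorted(x))
  m <- n - minCount + 1L
  q <- which(x[seq_len(m) + minCount - 1L] - x[seq_len(m)] <= window)
  if (!length(q)) return(list())
  memberLo <- q; memberHi <- q + minCount - 1L
  # merge overlapping/adjacent qualifying runs into clusters
  runs <- list()
  curLo <- memberLo[1L]; curHi <- memberHi[1L]
  for (i in seq_along(q)[-1L]) {
    if (memberLo[i] <= curHi + 0L) curHi <- max(curHi, memberHi[i])
    else { runs[[length(runs) + 1L]] <- c(curLo, curHi); curLo <- memberLo[i]
           curHi <- memberHi[i] }
  }
  runs[[length(runs) + 1L]] <- c(curLo, curHi)
  runs
}

#' Call element density clusters
#'
#' A cluster is a maximal genomic span in which element midpoints reach the
#' density criterion of at least `minCount` elements per `window` bases
#' (default 5 per Mb): every run of `minCount` consecutive midpoints
#' spanning at most `window` seeds a cluster, and overlapping runs are
#' unioned. This is the continuous limit of a sliding fixed-width window.
#'
#' @param elements `GRanges` of elements (midpoints are clustered).
#' @param window window size in bp (default 1e6).
#' @param minCount minimum elements per window (default 5).
#' @return `GRanges` of clusters with metadata `n_members`,
#'   `density_per_mb` and `member_ids` (CharacterList of element ids when
#'   available, else indices).
#' @export
callClusters <- function(elements, window = 1e6, minCount = 5L) {
  ids <- mcols(elements)$element_id
  if (is.null(ids)) ids <- as.character(seq_along(elements))
  mid <- (start(elements) + end(elements)) / 2
  chrom <- as.character(seqnames(elements))
  out <- list()
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    sel <- sel[order(mid[sel])]
    runs <- .clusterMemberRuns(mid[sel], window, minCount)
    for (r in runs) {
      members <- sel[r[1L]:r[2L]]
      spanLo <- min(start(elements)[members])
      spanHi <- max(end(elements)[members])
      spanMb <- (spanHi - spanLo + 1) / 1e6
      g <- GRanges(ch, IRanges(spanLo, spanHi))
      mcols(g)$n_members <- length(members)
      mcols(g)$density_per_mb <- length(members) / max(spanMb, window / 1e6)
      mcols(g)$member_ids <- IRanges::CharacterList(list(ids[members]))
      out[[length(out) + 1L]] <- g
    }
  }
  if (!length(out)) {
    g <- GRanges()
    mcols(g)$n_members <- integer(0)
    return(g)
  }
  sort(do.call(c, out), ignore.strand = TRUE)
}

#' Fraction of elements inside called clusters
#'
#' @param elements `GRanges`.
#' @inheritParams callClusters
#' @return fraction in \[0, 1\].
#' @export
clusterFraction <- function(elements, window = 1e6, minCount = 5L) {
  cl <- callClusters(elements, window, minCount)
  if (!length(cl)) return(0)
  sum(mcols(cl)$n_members) / length(elements)
}

# draw n point integrations uniformly over assembled (non-gap) bases
.drawIntegrations <- function(n, genome) {
  reg <- assembledRegions(genome)
  w <- as.numeric(width(reg))
  idx <- sample.int(length(reg), n, replace = TRUE, prob = w)
  pos <- start(reg)[idx] + floor(runif(n) * w[idx])
  data.frame(chrom = as.character(seqnames(reg))[idx], pos = pos)
}

#' Monte-Carlo null of random point integrations
#'
#' Repeatedly places `n` point integrations uniformly over the assembled
#' (non-gap) bases of the genome — chromosome chosen proportional to
#' assembled length — and computes a distribution statistic per replicate:
#' either the fraction of points falling in density clusters
#' (`"cluster_fraction"`) or the TU-distance category profile
#' (`"distance_profile"`, requiring `tus`).
#'
#' @param n number of integrations per replicate.
#' @param genome a [GenomeIndex].
#' @param reps number of replicates.
#' @param seed RNG seed (the simulation is bit-reproducible given the seed).
#' @param statistic `"cluster_fraction"` or `"distance_profile"`.
#' @param tus merged TU-extent `GRanges` (for `"distance_profile"`).
#' @param window,minCount cluster rule parameters.
#' @return a list of class `ltrNullSummary`: `statistic`, `reps`, `n`,
#'   `seed`, and for cluster_fraction `values` (per-replicate fractions),
#'   `mean`, `sd`; for distance_profile `counts` (reps x category matrix),
#'   `mean_prop`, `sd_prop`, and `distances` (pooled per-point distances,
#'   `NA` = non-defined).
#' @export
simulateRandomIntegrations <- function(n, genome, reps = 1000L, seed = 1L,
                                       statistic = c("cluster_fraction",
                                                     "distance_profile"),
                                       tus = NULL, window = 1e6,
                                       minCount = 5L) {
  statistic <- match.arg(statistic)
  if (n < 1L) stop("n must be >= 1")
  if (reps < 1L) stop("reps must be >= 1")
  set.seed(seed)
  if (statistic == "cluster_fraction") {
    vals <- numeric(reps)
    for (r in seq_len(reps)) {
      pts <- .drawIntegrations(n, genome)
      tot <- 0L
      for (ch in unique(pts$chrom)) {
        x <- sort(pts$pos[pts$chrom == ch])
        runs <- .clusterMemberRuns(x, window, minCount)
        tot <- tot + sum(vapply(runs, function(r2) r2[2L] - r2[1L] + 1L, 0L))
      }
      vals[r] <- tot / n
    }
    out <- list(statistic = statistic, reps = reps, n = n, seed = seed,
                values = vals, mean = mean(vals), sd = sd(vals))
  } else {
    if (is.null(tus)) stop("distance_profile statistic needs tus")
    counts <- matrix(0L, nrow = reps, ncol = length(.DIST_CATEGORIES),
                     dimnames = list(NULL, .DIST_CATEGORIES))
    pooled <- list()
    for (r in seq_len(reps)) {
      pts <- .drawIntegrations(n, genome)
      gr <- GRanges(pts$chrom, IRanges(pts$pos, pts$pos))
      prof <- tuDistanceProfile(gr, tuExtent = tus)
      counts[r, ] <- prof$counts
      pooled[[r]] <- prof$distances
    }
    props <- counts / n
    out <- list(statistic = statistic, reps = reps, n = n, seed = seed,
                counts = counts, mean_prop = colMeans(props),
                sd_prop = apply(props, 2L, sd),
                distances = unlist(pooled))
  }
  class(out) <- "ltrNullSummary"
  out
}

#' @export
print.ltrNullSummary <- function(x, ...) {
  cat("Random-integration null:", x$statistic, "| n =", x$n,
      "| reps =", x$reps, "| seed =", x$seed, "\n")
  if (x$statistic == "cluster_fraction")
    cat(sprintf("  mean cluster fraction %.4f (sd %.4f)\n", x$mean, x$sd))
  else
    print(round(x$mean_prop, 4))
  invisible(x)
}

#' Build merged transcriptional-unit extents
#'
#' A TU covers a gene span (exons, introns, UTRs) plus `flank` bases up- and
#' downstream, clipped to the chromosome; overlapping extents are merged.
#'
#' @param genes `GRanges` of gene spans.
#' @param flank flank size in bp (default 5000).
#' @param genome optional [GenomeIndex] for clipping.
#' @return merged `GRanges` of TU extents.
#' @export
tuExtents <- function(genes, flank = 5000L, genome = NULL) {
  ext <- granges(genes)
  start(ext) <- pmax(1L, start(ext) - as.integer(flank))
  if (!is.null(genome)) {
    lim <- chromLengths(genome)[as.character(seqnames(ext))]
    end(ext) <- pmin(as.integer(lim), end(ext) + as.integer(flank))
  } else {
    end(ext) <- end(ext) + as.integer(flank)
  }
  reduce(ext, ignore.strand = TRUE)
}

#' Distance-to-TU category profile
#'
#' Elements overlapping any TU extent fall in category `TU`; the rest are
#' binned by shortest edge-to-edge distance into 10 kb bins up to 100 kb,
#' then `>100kb`; elements on chromosomes/contigs without any TU are `ND`
#' (non-defined).
#'
#' @param elements `GRanges`.
#' @param tus `GRanges` of gene spans (flanked and merged internally), or
#'   supply `tuExtent` directly.
#' @param flank flank in bp used when building extents from `tus`.
#' @param tuExtent pre-built merged TU extents.
#' @return a list of class `ltrDistanceProfile` with `counts` (named,
#'   summing to `total`), `total`, and `distances` (per-element bp, 0 for
#'   TU overlap, `NA` for ND).
#' @export
tuDistanceProfile <- function(elements, tus = NULL, flank = 5000L,
                              tuExtent = NULL) {
  if (is.null(tuExtent)) {
    if (is.null(tus)) stop("supply tus or tuExtent")
    tuExtent <- tuExtents(tus, flank)
  }
  d <- nearestFeatureDistance(elements, tuExtent)
  overlap <- overlapsAny(elements, tuExtent, ignore.strand = TRUE)
  cat <- character(length(elements))
  cat[is.na(d)] <- "ND"
  cat[overlap] <- "TU"
  rest <- !is.na(d) & !overlap
  bin <- pmin(floor((d[rest] - 1e-9) / 1e4), 10)
  bin[d[rest] <= 0] <- 0
  cat[rest] <- ifelse(bin >= 10, ">100kb",
                      paste0("(", bin * 10, ",", (bin + 1) * 10, "]"))
  counts <- table(factor(cat, levels = .DIST_CATEGORIES))
  stopifnot(sum(counts) == length(elements))
  out <- list(counts = setNames(as.integer(counts), .DIST_CATEGORIES),
              total = length(elements), distances = d)
  class(out) <- "ltrDistanceProfile"
  out
}

#' @export
print.ltrDistanceProfile <- function(x, ...) {
  cat("TU-distance profile over", x$total, "elements\n")
  print(x$counts)
  invisible(x)
}

#' Per-category enrichment tests against the random-integration null
#'
#' For every distance category, a two-sided exact binomial test of the
#' observed count against `n * (null mean proportion)`; overall, a
#' two-sample Kolmogorov-Smirnov test between the observed per-element
#' distances and the pooled null distances (non-defined elements excluded
#' from the KS sample).
#'
#' @param observed an `ltrDistanceProfile`.
#' @param null an `ltrNullSummary` with `statistic = "distance_profile"`.
#' @return a list with `categories` (data.frame: category, observed,
#'   expected_prop, p_binomial, direction) and `ks` (`htest`).
#' @export
categoryEnrichmentTests <- function(observed, null) {
  if (null$statistic != "distance_profile")
    stop("null must carry a distance_profile statistic")
  if (!identical(names(observed$counts), names(null$mean_prop)))
    stop("category mismatch between observed profile and null")
  n <- observed$total
  res <- do.call(rbind, lapply(names(observed$counts), function(cc) {
    p0 <- null$mean_prop[[cc]]
    obs <- observed$counts[[cc]]
    pb <- if (p0 <= 0) {
      if (obs == 0) 1 else 0
    } else if (p0 >= 1) {
      if (obs == n) 1 else 0
    } else binom.test(obs, n, p0, alternative = "two.sided")$p.value
    data.frame(category = cc, observed = obs, expected_prop = p0,
               p_binomial = pb,
               direction = ifelse(obs / n >= p0, "enriched", "depleted"),
               stringsAsFactors = FALSE)
  }))
  obsD <- observed$distances[!is.na(observed$distances)]
  nullD <- null$distances[!is.na(null$distances)]
  ks <- suppressWarnings(ks.test(obsD, nullD))
  list(categories = res, ks = ks)
}

#' Subfeature overlap profile of TU-overlapping elements
#'
#' Assigns each TU-overlapping element to exactly one subfeature by the
#' precedence exon > 5'UTR > 3'UTR > intron > flank, and reports observed
#' fractions next to the expectation under uniform point integration —
#' either from supplied null point positions or analytically from the
#' per-base share of each precedence class within the merged TU extents.
#'
#' @param elements `GRanges` of TU-overlapping elements.
#' @param subfeatures named list of `GRanges`: `exon`, `utr5`, `utr3`,
#'   `gene` (gene spans; introns are derived), and the TU extent is the
#'   flanked gene span.
#' @param flank flank bp (default 5000).
#' @param nullPoints optional `GRanges` of null integration points falling
#'   in TUs, used instead of the analytic expectation.
#' @return `data.frame` with `subfeature`, `observed_n`, `observed_frac`,
#'   `expected_frac`.
#' @export
subfeatureOverlapProfile <- function(elements, subfeatures, flank = 5000L,
                                     nullPoints = NULL) {
  ext <- tuExtents(subfeatures$gene, flank)
  exon <- reduce(granges(subfeatures$exon), ignore.strand = TRUE)
  utr5 <- if (!is.null(subfeatures$utr5))
    reduce(granges(subfeatures$utr5), ignore.strand = TRUE) else GRanges()
  utr3 <- if (!is.null(subfeatures$utr3))
    reduce(granges(subfeatures$utr3), ignore.strand = TRUE) else GRanges()
  geneSpan <- reduce(granges(subfeatures$gene), ignore.strand = TRUE)
  # precedence classes as disjoint base sets
  cls <- list(exon = exon,
              utr5 = GenomicRanges::setdiff(utr5, exon, ignore.strand = TRUE),
              utr3 = GenomicRanges::setdiff(
                utr3, GenomicRanges::union(exon, utr5, ignore.strand = TRUE),
                ignore.strand = TRUE))
  inner <- Reduce(function(a, b) GenomicRanges::union(a, b,
                                                      ignore.strand = TRUE),
                  cls)
  cls$intron <- GenomicRanges::setdiff(geneSpan, inner, ignore.strand = TRUE)
  cls$flank <- GenomicRanges::setdiff(
    ext, GenomicRanges::union(geneSpan, inner, ignore.strand = TRUE),
    ignore.strand = TRUE)
  assign1 <- function(gr) {
    res <- rep(NA_character_, length(gr))
    for (nm in c("exon", "utr5", "utr3", "intron", "flank")) {
      hit <- is.na(res) & overlapsAny(gr, cls[[nm]], ignore.strand = TRUE)
      res[hit] <- nm
    }
    res
  }
  obs <- assign1(elements)
  obs <- obs[!is.na(obs)]
  lev <- c("exon", "utr5", "utr3", "intron", "flank")
  obsN <- table(factor(obs, levels = lev))
  expected <- if (!is.null(nullPoints)) {
    np <- assign1(nullPoints)
    np <- np[!is.na(np)]
    as.numeric(table(factor(np, levels = lev))) / max(length(np), 1L)
  } else {
    bp <- vapply(cls[lev], function(g) sum(as.numeric(width(g))), 0)
    bp / sum(bp)
  }
  data.frame(subfeature = lev, observed_n = as.integer(obsN),
             observed_frac = as.integer(obsN) / max(length(obs), 1L),
             expected_frac = expected, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pearson chi-square test of representation in a 2x2 table
#'
#' @param tab 2x2 matrix of non-negative counts (e.g. feature in/out of
#'   clusters vs complement).
#' @return a list with `chisq`, `p` (df = 1, no continuity correction) and
#'   `low_expected` flag (some expected cell < 1).
#' @examples
#' chiSquareRepresentation(matrix(c(10, 20, 20, 10), 2))
#' @export
chiSquareRepresentation <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), p = ct$p.value,
       low_expected = any(ct$expected < 1))
}

#' Classify transcriptional support of structural elements
#'
#' For each element's internal region (between the LTRs), same-strand
#' transcripts from each tissue are examined: `complete` when some single
#' transcript covers the entire internal region, `partial` when any
#' same-strand transcript overlaps it, `none` otherwise. Unstranded
#' transcripts are excluded with a warning.
#'
#' @param elements `GRanges` of elements with metadata `ltr5_end` and
#'   `ltr3_start` (internal region = `ltr5_end+1 .. ltr3_start-1`) and
#'   stranded.
#' @param transcripts named list of `GRanges` (one per tissue), stranded.
#' @return `data.frame`: `element_id`, `status`, `tissues`
#'   (comma-separated tissues with any same-strand overlap).
#' @export
classifyExpressionSupport <- function(elements, transcripts) {
  ids <- mcols(elements)$element_id
  if (is.null(ids)) ids <- as.character(seq_along(elements))
  internal <- GRanges(seqnames(elements),
                      IRanges(mcols(elements)$ltr5_end + 1L,
                              mcols(elements)$ltr3_start - 1L),
                      strand = strand(elements))
  status <- rep("none", length(elements))
  tiss <- vector("list", length(elements))
  for (tissue in names(transcripts)) {
    tx <- transcripts[[tissue]]
    un <- as.character(strand(tx)) == "*"
    if (any(un)) {
      warning(sum(un), " unstranded transcript(s) excluded in tissue ",
              tissue)
      tx <- tx[!un]
    }
    pairs <- strandIntersect(internal, tx, mode = "same-orientation")
    if (!nrow(pairs)) next
    covers <- start(tx)[pairs$feature] <= start(internal)[pairs$element] &
      end(tx)[pairs$feature] >= end(internal)[pairs$element]
    for (i in unique(pairs$element)) {
      sel <- pairs$element == i
      tiss[[i]] <- c(tiss[[i]], tissue)
      if (any(covers[sel])) status[i] <- "complete"
      else if (status[i] == "none") status[i] <- "partial"
    }
  }
  data.frame(element_id = ids, status = status,
             tissues = vapply(tiss, function(t)
               paste(unique(t), collapse = ","), ""),
             stringsAsFactors = FALSE)
}

#' A chicken-genome-sized chromosome partition
#'
#' Builds a [GenomeIndex] whose chromosomes follow the macro/micro size
#' structure of the galGal4 chicken assembly (chromosomes 1-28, 32, W, Z
#' at their public lengths, with the remaining assembled sequence modelled
#' as 200 kb unplaced scaffolds), totalling exactly 1,046,932,099 assembled
#' bases. The scaffold decomposition is an approximation of the real
#' unplaced fraction; only the size structure matters for the
#' random-integration null.
#'
#' @return a [GenomeIndex].
#' @export
galGal4SizedPartition <- function() {
  lens <- c(chr1 = 195276750, chr2 = 148809762, chr3 = 110447801,
            chr4 = 90216835, chr5 = 59580361, chr6 = 34951654,
            chr7 = 36245040, chr8 = 28767244, chr9 = 23441680,
            chr10 = 19911089, chr11 = 19401079, chr12 = 19897011,
            chr13 = 17760035, chr14 = 15161805, chr15 = 12656803,
            chr16 = 535270, chr17 = 10454150, chr18 = 11219875,
            chr19 = 9983394, chr20 = 14302601, chr21 = 6802778,
            chr22 = 4081097, chr23 = 5723239, chr24 = 6323281,
            chr25 = 2191139, chr26 = 5329985, chr27 = 5209285,
            chr28 = 4742627, chr32 = 78254, chrW = 1248174,
            chrZ = 82363669)
  total <- 1046932099
  rem <- total - sum(lens)
  nsc <- floor(rem / 200000)
  sc <- rep(200000, nsc)
  lastBit <- rem - sum(sc)
  sc <- c(sc, if (lastBit > 0) lastBit)
  names(sc) <- sprintf("scaffold%04d", seq_along(sc))
  GenomeIndex(c(lens, sc))
}
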