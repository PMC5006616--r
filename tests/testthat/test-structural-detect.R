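# Structural LTR-pair detection against planted truth.

plantRepeatPair <- function(seqLen, ltrLen, gapLen, d = 0, seed = 5,
                            at = NULL) {
  set.seed(seed)
  bg <- strsplit(randomSequence(seqLen), "")[[1L]]
  ltr <- randomSequence(ltrLen)
  ltrB <- mutateSequence(ltr, d)
  if (is.null(at)) at <- floor(seqLen / 3)
  s1 <- at
  s2 <- at + ltrLen + gapLen
  bg[s1:(s1 + ltrLen - 1L)] <- strsplit(ltr, "")[[1L]]
  bg[s2:(s2 + ltrLen - 1L)] <- strsplit(ltrB, "")[[1L]]
  list(seq = Biostrings::DNAString(paste(bg, collapse = "")),
       left = c(s1, s1 + ltrLen - 1L), right = c(s2, s2 + ltrLen - 1L))
}

test_that("a planted perfect LTR pair is found with exact similarity", {
  p <- plantRepeatPair(100000L, 300L, 5000L, d = 0)
  cand <- findLTRPairCandidates(p$seq)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$similarity, 1.0)
  expect_lte(abs(cand$left_start - p$left[1]), 5)
  expect_lte(abs(cand$left_end - p$left[2]), 5)
  expect_lte(abs(cand$right_start - p$right[1]), 5)
  expect_lte(abs(cand$right_end - p$right[2]), 5)
})

test_that("similarity thresholding follows the 75 % constraint", {
  p20 <- plantRepeatPair(100000L, 300L, 5000L, d = 0.20, seed = 6)
  c20 <- findLTRPairCandidates(p20$seq)
  expect_equal(nrow(c20), 1L)
  expect_gte(c20$similarity, 0.75)
  expect_lt(abs(c20$similarity - 0.80), 0.05)

  p30 <- plantRepeatPair(100000L, 300L, 5000L, d = 0.30, seed = 7)
  expect_equal(nrow(findLTRPairCandidates(p30$seq)), 0L)
})

test_that("LTRs shorter than the minimum length are not called", {
  p <- plantRepeatPair(100000L, 60L, 5000L, d = 0, seed = 8)
  expect_equal(nrow(findLTRPairCandidates(p$seq)), 0L)
})

test_that("sequences shorter than the minimum span return empty, not error", {
  short <- Biostrings::DNAString(randomSequence(500L))
  expect_equal(nrow(findLTRPairCandidates(short)), 0L)
})

test_that("internal evidence flags are detected on planted features", {
  sim <- sharedSim()
  sie <- sim$truth[sim$truth$type == "SIE", ]
  low <- sie[sie$divergence <= 0.08, ][1, ]   # young: features intact
  cand <- data.frame(left_start = low$ltr5_start, left_end = low$ltr5_end,
                     right_start = low$ltr3_start, right_end = low$ltr3_end)
  ev <- collectInternalEvidence(cand, sim$genome[[low$chrom]], sim$trna)
  expect_true(ev$tsd)
  expect_equal(ev$tsd_seq, low$tsd_seq)
  expect_true(ev$pbs)
  expect_true(ev$ppt)
  expect_gte(ev$n_evidence, 2)
})

test_that("evidence flags are FALSE when features are absent", {
  set.seed(9)
  # strip AATAAA from LTRs by construction: all-C/T LTR content
  bg <- paste(rep("ACGT", 3000), collapse = "")
  ltr <- paste(rep("CT", 150), collapse = "")
  s <- paste0(substr(bg, 1, 2000), ltr,
              randomSequence(4000), ltr, substr(bg, 1, 2000))
  cand <- data.frame(left_start = 2001, left_end = 2300,
                     right_start = 6301, right_end = 6600)
  ev <- collectInternalEvidence(cand, Biostrings::DNAString(s))
  expect_false(ev$polya)
  expect_false(ev$tg_ca)
  expect_false(ev$pbs)    # no tRNA set supplied
})

test_that("bounds violations in evidence collection error", {
  s <- Biostrings::DNAString(randomSequence(1000L))
  cand <- data.frame(left_start = 900, left_end = 950,
                     right_start = 1100, right_end = 1200)
  expect_error(collectInternalEvidence(cand, s), "bounds")
})

test_that("planted elements are recovered genome-wide with tight boundaries", {
  sim <- sharedSim()
  det <- sharedDetection()
  acc <- det[mcols(det)$accepted]
  sie <- sim$truth[sim$truth$type == "SIE", ]
  truthGr <- GRanges(sie$chrom, IRanges(sie$start, sie$end))
  ov <- findOverlaps(truthGr, acc)
  recovered <- unique(queryHits(ov))
  expect_gte(length(recovered), ceiling(0.9 * nrow(sie)))
  i <- queryHits(ov); j <- subjectHits(ov)
  expect_lte(max(abs(start(truthGr)[i] - start(acc)[j])), 20)
  expect_lte(max(abs(end(truthGr)[i] - end(acc)[j])), 20)
})

test_that("no elements are accepted on unplanted random sequence", {
  set.seed(100)
  g <- Biostrings::DNAStringSet(c(nullchr = randomSequence(1000000L)))
  det <- callStructuralElements(g)
  expect_equal(sum(if (length(det)) mcols(det)$accepted else 0), 0)
})

test_that("candidates with similarity but zero evidence are rejected", {
  det <- sharedDetection()
  if (length(det)) {
    bare <- mcols(det)$n_evidence < DetectorParams()@evidenceMin &
      mcols(det)$n_domain == 0
    expect_true(all(!mcols(det)$accepted[bare]))
  }
  # and directly: a naked perfect repeat pair has no support
  p <- plantRepeatPair(60000L, 300L, 5000L, d = 0, seed = 12)
  g <- Biostrings::DNAStringSet(c(c1 = as.character(p$seq)))
  det2 <- callStructuralElements(g)
  if (length(det2)) expect_true(all(!mcols(det2)$accepted))
})

test_that("detection is invariant under reverse complement", {
  sim <- sharedSim()
  chrom <- "simchr2"
  fwd <- callStructuralElements(
    Biostrings::DNAStringSet(setNames(list(sim$genome[[chrom]]), chrom)))
  rcSeq <- Biostrings::reverseComplement(sim$genome[[chrom]])
  rev <- callStructuralElements(
    Biostrings::DNAStringSet(setNames(list(rcSeq), chrom)))
  L <- length(sim$genome[[chrom]])
  mirStart <- sort(L - end(rev) + 1)
  expect_equal(length(rev), length(fwd))
  expect_true(all(abs(sort(start(fwd)) - mirStart) <= 10))
})

test_that("accepted similarity agrees with an alignment-free recomputation", {
  sim <- sharedSim()
  det <- sharedDetection()
  acc <- det[mcols(det)$accepted]
  m <- mcols(acc)
  for (i in seq_along(acc)) {
    s <- sim$genome[[as.character(seqnames(acc))[i]]]
    a <- as.character(Biostrings::subseq(s, m$ltr5_start[i], m$ltr5_end[i]))
    b <- as.character(Biostrings::subseq(s, m$ltr3_start[i], m$ltr3_end[i]))
    # independent route: ungapped column identity, maximised over small
    # boundary shifts (the copies were planted without indels)
    av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
    ident <- max(vapply(-3:3, function(off) {
      ia <- seq_len(min(length(av), length(bv) - off))
      ia <- ia[ia >= 1 & ia + off >= 1 & ia + off <= length(bv)]
      mean(av[ia] == bv[ia + off])
    }, 0))
    expect_lte(abs(ident - m$similarity[i]), 0.02)
  }
})

test_that("no accepted element violates any detector bound", {
  det <- sharedDetection()
  p <- DetectorParams()
  acc <- det[mcols(det)$accepted]
  m <- mcols(acc)
  llen <- m$ltr5_end - m$ltr5_start + 1
  rlen <- m$ltr3_end - m$ltr3_start + 1
  span <- m$ltr3_end - m$ltr5_start + 1
  expect_true(all(llen >= p@minLtrLen & llen <= p@maxLtrLen))
  expect_true(all(rlen >= p@minLtrLen & rlen <= p@maxLtrLen))
  expect_true(all(span >= p@minElementSpan & span <= p@maxElementSpan))
  expect_true(all(m$similarity >= p@minLtrSimilarity))
  expect_true(all(m$ltr3_start > m$ltr5_end))
})
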