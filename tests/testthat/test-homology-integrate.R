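# Homology filtering, conflict removal, validation, DIRS rule, secondary
# expansion and final provenance accounting.

mkHits <- function(evalue, len, chrom = "chr1", start = 1000) {
  n <- length(evalue)
  data.frame(qseqid = paste0("q", seq_len(n)), sseqid = chrom,
             pident = 0.9, length = len, evalue = evalue,
             bitscore = 100, sstart = start + seq_len(n) * 5000,
             send = start + seq_len(n) * 5000 + len - 1,
             strand = "+", tool = "blastn")
}

test_that("hit filter applies inclusive E-value and length thresholds", {
  hits <- mkHits(evalue = c(1e-9, 1e-12, 1e-10, 1e-20),
                 len = c(500, 99, 100, 500))
  out <- filterHomologyHits(hits)
  # 1e-9 fails E; len 99 fails length; exact boundaries are retained
  expect_equal(length(out), 2L)
  expect_setequal(mcols(out)$label, c("q3", "q4"))
  expect_error(filterHomologyHits(mkHits(-1e-10, 200)), "negative")
})

test_that("RepeatMasker import partitions LTR from other classes", {
  gr <- GRanges(c("chr1", "chr1", "chr2"),
                IRanges(c(100, 5000, 300), c(600, 5700, 900)),
                strand = "+")
  mcols(gr)$repeat_name <- c("ERVL1", "CR1_X", "GGLTR")
  mcols(gr)$repeat_class <- c("LTR/ERVL", "LINE/CR1", "LTR/ERVK")
  mcols(gr)$divergence <- c(0.1, 0.2, 0.05)
  f <- tempfile(fileext = ".out")
  writeRepeatMaskerOut(gr, f)
  rm <- readRepeatMaskerOut(f)
  expect_equal(length(rm$ltr), 2L)
  expect_equal(length(rm$other), 1L)
  expect_equal(mcols(rm$other)$repeat_class, "LINE/CR1")
  expect_equal(start(rm$ltr), c(100, 300))

  empty <- tempfile(fileext = ".out")
  writeLines(character(0), empty)
  rme <- readRepeatMaskerOut(empty)
  expect_equal(length(rme$ltr) + length(rme$other), 0L)

  bad <- tempfile(fileext = ".out")
  writeLines("only three fields here", bad)
  expect_error(readRepeatMaskerOut(bad), "malformed")
  unlink(c(f, empty, bad))
})

test_that("conflict filter removes only heavily covered elements", {
  el <- GRanges("chr1", IRanges(c(1000, 9000, 20000), c(1999, 9999, 20999)))
  other <- GRanges("chr1", IRanges(c(1000, 9000), c(1599, 9299)))  # 60 %, 30 %
  mcols(other)$repeat_class <- c("LINE/CR1", "LINE/CR1")
  kept <- applyConflictFilter(el, other)
  expect_equal(start(kept), c(9000, 20000))
  log <- attr(kept, "removed")
  expect_equal(nrow(log), 1L)
  expect_equal(log$class, "LINE/CR1")
  expect_gte(log$covered, 0.5)
  # zero-overlap elements are never removed (property)
  noOv <- applyConflictFilter(el[3], other)
  expect_equal(length(noOv), 1L)
})

test_that("reciprocal validation uses the best hit against the threshold", {
  el <- GRanges("chr1", IRanges(c(100, 5000, 9000), c(400, 5400, 9400)))
  mcols(el)$element_id <- c("a", "b", "c")
  hits <- data.frame(element_id = c("a", "a", "c"),
                     evalue = c(1e-20, 1e-3, 1e-8),
                     bitscore = c(300, 50, 80), length = c(400, 100, 200))
  v <- reciprocalValidate(el, hits)
  expect_equal(mcols(v)$validated, c(TRUE, FALSE, FALSE))
})

test_that("the DIRS rule requires RT plus MT-or-YR at their thresholds", {
  expect_true(callDirs(data.frame(domain = c("RT", "YR"),
                                  e_value = c(1e-16, 1e-13))))
  expect_false(callDirs(data.frame(domain = "RT", e_value = 1e-16)))
  expect_false(callDirs(data.frame(domain = c("RT", "MT"),
                                   e_value = c(1e-14, 1e-13))))
  # boundary inclusivity: exactly at threshold passes
  expect_true(callDirs(data.frame(domain = c("RT", "MT"),
                                  e_value = c(1e-15, 1e-12))))
  expect_false(callDirs(NULL))
})

test_that("secondary expansion filters, absorbs and tags hits", {
  existing <- GRanges("chr1", IRanges(40000, 60000))
  hits <- data.frame(
    qseqid = c("SIE_1", "SIE_1", "SIE_2"),
    sseqid = "chr1", pident = 0.9,
    length = c(150, 150, 80),
    evalue = c(1e-12, 1e-12, 1e-12), bitscore = 100,
    sstart = c(1000, 45000, 70000),
    send = c(1149, 45149, 70079), strand = "+", tool = "blastn")
  out <- secondaryExpand(hits, existing)
  # disjoint 150 bp hit kept; inside-existing absorbed; 80 bp rejected
  expect_equal(length(out), 1L)
  expect_equal(start(out), 1000)
  expect_equal(mcols(out)$source, "secondary")
  expect_equal(mcols(out)$label, "SIE_1")
})

test_that("secondary expansion recovers planted fragments from hit tables", {
  sim <- sharedSim()
  frags <- sim$truth[sim$truth$type == "fragment", ]
  target <- frags[(frags$end - frags$start + 1) >= 100 &
                  frags$divergence <= 0.2, ]
  out <- secondaryExpand(sim$hits, existing = GRanges())
  fGr <- GRanges(target$chrom, IRanges(target$start, target$end))
  hitFrac <- mean(overlapsAny(fGr, out))
  expect_gte(hitFrac, 0.9)
})

test_that("finalize merges sources and accounts provenance exactly", {
  hom <- annotationSet(GRanges("chr1", IRanges(1, 10000)), "homology")
  str <- annotationSet(GRanges("chr1", IRanges(8001, 13000)), "structural")
  sec <- annotationSet(GRanges("chr1", IRanges(50000, 50999)), "secondary")
  fin <- finalizeAnnotation(hom, str, sec)
  expect_equal(fin$provenance$union, 14000)
  expect_equal(unname(fin$provenance$exclusive[["homology"]]), 8000)
  expect_equal(unname(fin$provenance$exclusive[["homology+structural"]]),
               2000)
  expect_equal(unname(fin$provenance$exclusive[["structural"]]), 3000)
  expect_equal(unname(fin$provenance$exclusive[["secondary"]]), 1000)
  # idempotence: finalizing the merged result again changes nothing
  fin2 <- finalizeAnnotation(fin$annotation, GRanges(), GRanges())
  expect_equal(granges(fin2$annotation), granges(fin$annotation))
})

test_that("unvalidated homology-only records without structural support drop", {
  hom <- annotationSet(GRanges("chr1", IRanges(c(1000, 50000),
                                               c(1999, 50999))), "homology")
  mcols(hom)$element_id <- c("h1", "h2")
  mcols(hom)$validated <- c(FALSE, FALSE)
  str <- GRanges("chr1", IRanges(1500, 2500))  # supports h1 only
  fin <- finalizeAnnotation(hom, str, GRanges())
  expect_equal(length(fin$dropped), 1L)
  expect_equal(start(fin$dropped), 50000)
  expect_false(any(overlapsAny(GRanges("chr1", IRanges(50000, 50999)),
                               fin$annotation)))
})

test_that("final union matches the per-base oracle on random sets", {
  for (seed in c(31, 32)) {
    set.seed(seed)
    sets <- list(homology = randomGRanges(20),
                 structural = randomGRanges(15),
                 secondary = randomGRanges(10))
    fin <- finalizeAnnotation(
      annotationSet(sets$homology, "homology"),
      annotationSet(sets$structural, "structural"),
      annotationSet(sets$secondary, "secondary"),
      params = FilterParams(mergeGap = 0L))
    bms <- bitmapCoverage(sets)
    expect_equal(sum(width(reduce(fin$annotation, ignore.strand = TRUE))),
                 bitmapUnionLength(bms))
    expect_equal(sum(fin$provenance$exclusive), fin$provenance$union)
  }
})

test_that("filtering then merging is invariant to input order", {
  set.seed(77)
  hits <- mkHits(evalue = 10^-runif(30, 5, 20),
                 len = sample(50:500, 30, replace = TRUE))
  perm <- sample(nrow(hits))
  a <- mergeAnnotations(filterHomologyHits(hits), 10)
  b <- mergeAnnotations(filterHomologyHits(hits[perm, ]), 10)
  expect_equal(granges(a), granges(b))
})
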