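# Density, clusters, the random-integration null, distance profiles,
# enrichment tests, subfeature overlap and expression classification.

test_that("chromosome density is count over megabases", {
  gi <- GenomeIndex(c(chr1 = 1e7, chr2 = 5e6))
  el <- GRanges("chr1", IRanges(seq(1e5, 1e6, length.out = 10), width = 100))
  d <- chromosomeDensityTable(el, gi)
  expect_equal(d$density_per_mb[d$chrom == "chr1"], 1.0)
  expect_equal(d$density_per_mb[d$chrom == "chr2"], 0.0)
  # arithmetic oracle on random placements
  set.seed(61)
  el2 <- GRanges(sample(c("chr1", "chr2"), 40, replace = TRUE),
                 IRanges(sample.int(4e6, 40), width = 50))
  d2 <- chromosomeDensityTable(el2, gi)
  for (i in seq_len(nrow(d2)))
    expect_equal(d2$density_per_mb[i],
                 sum(as.character(seqnames(el2)) == d2$chrom[i]) /
                   (d2$length_bp[i] / 1e6))
})

test_that("density correlates recover a planted log-linear model", {
  set.seed(62)
  n <- 30
  L <- 10^runif(n, 6.5, 8.3)
  R <- 10^runif(n, -0.3, 1)
  b <- 0.8; cc <- -0.5
  D <- 10^(0.2 + b * log10(L) + cc * log10(R) + rnorm(n, 0, 0.05))
  dens <- data.frame(chrom = paste0("c", 1:n), length_bp = L, n = 1,
                     density_per_mb = D)
  res <- densityCorrelates(dens, recombRate = setNames(R, dens$chrom))
  co <- res$coefficients
  expect_lt(abs(co["logL", "Estimate"] - b), 2 * co["logL", "Std. Error"])
  expect_lt(abs(co["logR", "Estimate"] - cc), 2 * co["logR", "Std. Error"])
  # exact proportionality gives r = 1 on the log scale
  densP <- data.frame(chrom = paste0("c", 1:n), length_bp = L, n = 1,
                      density_per_mb = 3 * L)
  resP <- densityCorrelates(densP, recombRate = setNames(R, densP$chrom))
  rDL <- resP$correlations[resP$correlations$a == "density" &
                           resP$correlations$b == "length", "r"]
  expect_equal(rDL, 1.0)
  # degenerate input errors
  densC <- data.frame(chrom = paste0("c", 1:n), length_bp = L, n = 1,
                      density_per_mb = 0)
  expect_error(densityCorrelates(densC,
                                 recombRate = setNames(R, densC$chrom)),
               "non-positive")
  expect_error(densityCorrelates(dens[1:2, ],
                                 recombRate = setNames(R[1:2],
                                                       dens$chrom[1:2])),
               "at least 3")
})

test_that("cluster calling follows the 5-per-Mb rule", {
  # 5 elements within 0.8 Mb -> one cluster of 5
  el5 <- GRanges("chr1", IRanges(seq(1e6, 1.8e6, length.out = 5),
                                 width = 100))
  cl <- callClusters(el5)
  expect_equal(length(cl), 1L)
  expect_equal(mcols(cl)$n_members, 5L)
  expect_gte(mcols(cl)$density_per_mb, 5)

  # 4 elements within 0.5 Mb -> no cluster
  el4 <- GRanges("chr1", IRanges(seq(1e6, 1.5e6, length.out = 4),
                                 width = 100))
  expect_equal(length(callClusters(el4)), 0L)

  # a chromosome-wide pile-up becomes one big cluster (all 56 members)
  set.seed(63)
  el56 <- GRanges("chrW", IRanges(sort(sample.int(9e5, 56)), width = 100))
  cl56 <- callClusters(el56)
  expect_equal(length(cl56), 1L)
  expect_equal(mcols(cl56)$n_members, 56L)
})

test_that("random integration nulls behave at the limits", {
  gi <- GenomeIndex(c(chr1 = 1e6))
  n1 <- simulateRandomIntegrations(1, gi, reps = 5, seed = 3)
  expect_equal(n1$mean, 0)
  # 5 points on a 1 Mb chromosome always lie within one window
  n5 <- simulateRandomIntegrations(5, gi, reps = 10, seed = 3)
  expect_equal(n5$values, rep(1, 10))
  # an unreachable member threshold gives zero
  big <- simulateRandomIntegrations(10, gi, reps = 5, seed = 3,
                                    minCount = 1000L)
  expect_equal(big$mean, 0)
  expect_error(simulateRandomIntegrations(0, gi), "n must be")
})

test_that("seeded nulls are bit-reproducible and obey Monte-Carlo scaling", {
  gi <- GenomeIndex(c(chr1 = 2e7, chr2 = 1e7))
  a <- simulateRandomIntegrations(60, gi, reps = 50, seed = 11)
  b <- simulateRandomIntegrations(60, gi, reps = 50, seed = 11)
  expect_identical(a$values, b$values)
  # s.e. of the null mean shrinks roughly as 1/sqrt(reps)
  m1 <- replicate(8, simulateRandomIntegrations(
    60, gi, reps = 50, seed = sample.int(1e6, 1))$mean)
  m2 <- replicate(8, simulateRandomIntegrations(
    60, gi, reps = 200, seed = sample.int(1e6, 1))$mean)
  expect_lt(sd(m2), sd(m1) * 1.05)
})

test_that("points are drawn from assembled bases only", {
  gaps <- GRanges("chr1", IRanges(1, 9e5))   # only 1e5 assembled at the end
  gi <- GenomeIndex(c(chr1 = 1e6), gaps = gaps)
  set.seed(5)
  null <- simulateRandomIntegrations(5, gi, reps = 3, seed = 5)
  expect_equal(genomeLength(gi), 1e5)
  reg <- assembledRegions(gi)
  expect_equal(start(reg), 900001)
})

test_that("TU distance profile bins elements as specified", {
  genes <- GRanges("chr1", IRanges(100000, 120000))
  els <- GRanges(
    c("chr1", "chr1", "chr1", "chr1", "contigX"),
    IRanges(c(96500,                    # 4 kb upstream: inside 5 kb flank
              220001,                   # 95 kb from the flanked TU end
              280000,                   # 155 kb away -> >100kb
              110000,                   # inside the gene
              5000), width = 100))
  prof <- tuDistanceProfile(els, tus = genes)
  expect_equal(prof$counts[["TU"]], 2L)
  expect_equal(prof$counts[["(90,100]"]], 1L)
  expect_equal(prof$counts[[">100kb"]], 1L)
  expect_equal(prof$counts[["ND"]], 1L)
  expect_equal(sum(prof$counts), length(els))   # conservation
})

test_that("profile counts always sum to the element count", {
  set.seed(66)
  genes <- randomGRanges(5, chroms = "chrA", maxPos = 3e5)
  for (i in 1:3) {
    els <- randomGRanges(30, chroms = c("chrA", "chrB"), maxPos = 4e5)
    prof <- tuDistanceProfile(els, tus = genes)
    expect_equal(sum(prof$counts), length(els))
  }
})

test_that("enrichment tests match closed forms and detect null equality", {
  gi <- GenomeIndex(c(chr1 = 3e6))
  genes <- GRanges("chr1", IRanges(c(5e5, 2e6), width = 2e5))
  tus <- tuExtents(genes)
  null <- simulateRandomIntegrations(40, gi, reps = 200, seed = 21,
                                     statistic = "distance_profile",
                                     tus = tus)
  set.seed(22)
  obsEls <- GRanges("chr1", IRanges(sample.int(2.9e6, 40), width = 50))
  prof <- tuDistanceProfile(obsEls, tuExtent = tus)
  res <- categoryEnrichmentTests(prof, null)
  expect_true(all(res$categories$p_binomial >= 0 &
                  res$categories$p_binomial <= 1))
  expect_equal(sum(res$categories$observed), prof$total)

  # closed-form binomial check: 0 of 10 at p = 0.5 -> p = 2 * 0.5^10
  pb <- binom.test(0, 10, 0.5, alternative = "two.sided")$p.value
  expect_equal(pb, 2 * 0.5^10)

  # identical observed and null distances -> KS D = 0
  d0 <- suppressWarnings(ks.test(null$distances, null$distances))
  expect_equal(unname(d0$statistic), 0)
})

test_that("binomial and chi-square match brute force exhaustively (n <= 12)", {
  for (n in c(5, 9, 12)) {
    for (k in 0:n) {
      expect_equal(binom.test(k, n, 0.3)$p.value, bruteBinomP(k, n, 0.3),
                   tolerance = 1e-9)
    }
  }
  # all 2x2 tables with total n <= 12
  for (a in 0:3) for (b in 0:3) for (cc in 0:3) for (d in 0:3) {
    tab <- matrix(c(a, b, cc, d), 2)
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      next
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    brute <- sum((tab - E)^2 / E)
    got <- chiSquareRepresentation(tab)
    expect_equal(got$chisq, brute, tolerance = 1e-12)
  }
})

test_that("chi-square representation reproduces hand-computed examples", {
  even <- chiSquareRepresentation(matrix(c(25, 25, 25, 25), 2))
  expect_equal(even$chisq, 0)
  expect_equal(even$p, 1)
  skew <- chiSquareRepresentation(matrix(c(10, 20, 20, 10), 2))
  expect_equal(skew$chisq, 20 / 3, tolerance = 1e-12)
  low <- chiSquareRepresentation(matrix(c(1, 0, 0, 1), 2))
  expect_true(low$low_expected)
})

test_that("KS statistic equals the brute-force ECDF sup-difference", {
  set.seed(67)
  for (i in 1:3) {
    x <- runif(200); y <- runif(150, 0.1, 1.1)
    got <- suppressWarnings(ks.test(x, y)$statistic)
    expect_equal(unname(got), bruteKS(x, y), tolerance = 1e-12)
  }
})

test_that("null TU proportion converges to the TU base fraction", {
  gi <- GenomeIndex(c(chr1 = 2e6, chr2 = 1e6))
  genes <- GRanges(c("chr1", "chr2"), IRanges(c(4e5, 2e5), width = 3e5))
  tus <- tuExtents(genes, genome = gi)
  q <- sum(as.numeric(width(tus))) / genomeLength(gi)
  null <- simulateRandomIntegrations(100, gi, reps = 400, seed = 31,
                                     statistic = "distance_profile",
                                     tus = tus)
  se <- sqrt(q * (1 - q) / 100) / sqrt(400)
  expect_lt(abs(null$mean_prop[["TU"]] - q), 4 * se + 0.002)
})

test_that("subfeature assignment follows precedence and base-share nulls", {
  gene <- GRanges("chr1", IRanges(100000, 120000), strand = "+")
  exon <- GRanges("chr1", IRanges(c(100000, 110000), c(101000, 111000)),
                  strand = "+")
  utr5 <- GRanges("chr1", IRanges(100000, 100300), strand = "+")
  sub <- list(gene = gene, exon = exon, utr5 = utr5)
  inIntron <- GRanges("chr1", IRanges(105000, 105100))
  spanning <- GRanges("chr1", IRanges(100900, 102000))  # exon+intron
  prof <- subfeatureOverlapProfile(c(inIntron, spanning), sub)
  expect_equal(prof$observed_n[prof$subfeature == "intron"], 1L)
  expect_equal(prof$observed_n[prof$subfeature == "exon"], 1L)
  # expected fractions equal per-base share of the flanked TU
  tuLen <- 20001 + 2 * 5000
  exonLen <- 2002
  expect_equal(prof$expected_frac[prof$subfeature == "exon"],
               exonLen / tuLen, tolerance = 1e-9)
  expect_equal(sum(prof$expected_frac), 1, tolerance = 1e-9)
})

test_that("expression support distinguishes complete, partial, none", {
  el <- GRanges("chr1", IRanges(1000, 9000), strand = "+")
  mcols(el)$element_id <- "e1"
  mcols(el)$ltr5_end <- 1300
  mcols(el)$ltr3_start <- 8700
  internalSpan <- c(1301, 8699)
  full <- GRanges("chr1", IRanges(1200, 8800), strand = "+")
  half <- GRanges("chr1", IRanges(1301, 5000), strand = "+")
  anti <- GRanges("chr1", IRanges(1301, 8699), strand = "-")
  expect_equal(classifyExpressionSupport(
    el, list(t1 = full))$status, "complete")
  expect_equal(classifyExpressionSupport(
    el, list(t1 = half))$status, "partial")
  expect_equal(classifyExpressionSupport(
    el, list(t1 = anti))$status, "none")
  expect_warning(classifyExpressionSupport(
    el, list(t1 = GRanges("chr1", IRanges(1301, 8699), strand = "*"))),
    "unstranded")
  both <- classifyExpressionSupport(el, list(em = full, ov = half))
  expect_equal(both$status, "complete")
  expect_equal(both$tissues, "em,ov")
})

test_that("simulated transcripts give the planted expression statuses", {
  sim <- sharedSim()
  sie <- sim$truth[sim$truth$type == "SIE", ]
  el <- GRanges(sie$chrom, IRanges(sie$start, sie$end), strand = sie$strand)
  mcols(el)$element_id <- sie$id
  mcols(el)$ltr5_end <- sie$ltr5_end
  mcols(el)$ltr3_start <- sie$ltr3_start
  calls <- classifyExpressionSupport(el, sim$transcripts)
  nExpr <- ceiling(nrow(sie) * sim$config$expressedFraction)
  expect_equal(sum(calls$status == "complete"), nExpr)
  expect_true(all(calls$status[seq_len(nExpr)] == "complete"))
})
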