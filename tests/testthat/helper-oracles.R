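# Independent brute-force oracles used by the property tests.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# O(n^2) transitive-closure interval merging on a data.frame
bruteMerge <- function(df, maxGap) {
  if (!nrow(df)) return(df)
  out <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    merged <- d[1, , drop = FALSE]
    for (i in seq_len(nrow(d))[-1]) {
      last <- nrow(merged)
      gap <- d$start[i] - merged$end[last] - 1
      if (gap <= maxGap) {
        merged$end[last] <- max(merged$end[last], d$end[i])
      } else {
        merged <- rbind(merged, d[i, , drop = FALSE])
      }
    }
    out[[ch]] <- merged
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# per-base bitmap coverage over small coordinate ranges
bitmapCoverage <- function(grList, maxPos = 100000L) {
  lapply(grList, function(gr) {
    bm <- new.env()
    for (i in seq_along(gr)) {
      ch <- as.character(seqnames(gr))[i]
      if (is.null(bm[[ch]])) bm[[ch]] <- logical(maxPos)
      bm[[ch]][start(gr)[i]:end(gr)[i]] <- TRUE
    }
    bm
  })
}

bitmapUnionLength <- function(bms) {
  chroms <- unique(unlist(lapply(bms, ls)))
  total <- 0
  for (ch in chroms) {
    u <- Reduce(`|`, lapply(bms, function(b)
      if (is.null(b[[ch]])) logical(length(bms[[1]][[ls(bms[[1]])[1]]]))
      else b[[ch]]))
    total <- total + sum(u)
  }
  total
}

# brute-force two-sample KS statistic: sup |ECDF1 - ECDF2|
bruteKS <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), 0)))
}

# two-sided exact binomial p by summation of no-more-likely outcomes
bruteBinomP <- function(k, n, p) {
  probs <- dbinom(0:n, n, p)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

randomGRanges <- function(n, chroms = c("chrA", "chrB"), maxPos = 5e4,
                          maxLen = 2e3) {
  s <- sample.int(maxPos - maxLen, n, replace = TRUE)
  w <- sample.int(maxLen, n, replace = TRUE)
  GRanges(sample(chroms, n, replace = TRUE), IRanges(s, s + w - 1L))
}
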