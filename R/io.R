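#' Read a BLAST tabular (outfmt 6 style) hit table
#'
#' Expected columns (no header):
#' `qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`, the default BLAST outfmt 6 layout. A trailing `sstrand`
#' column is honoured when present; otherwise strand is inferred from
#' `sstart > send` (minus-strand subject coordinates), as BLAST reports.
#'
#' @param path TSV file path.
#' @param tool tool tag recorded per hit (`"blastn"`, `"tblastx"`).
#' @return a `data.frame` with columns `qseqid`, `sseqid`, `pident`
#'   (fraction in \[0,1\]), `length`, `evalue`, `bitscore`, `sstart`,
#'   `send` (always `sstart <= send`), `strand`, `tool`.
#' @export
readBlastTab <- function(path, tool = "blastn") {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  if (ncol(x) < 12L)
    stop("expected >= 12 tab-separated columns, got ", ncol(x))
  names(x)[seq_along(cols)] <- cols
  strand <- if (ncol(x) >= 13L) {
    ifelse(x[[13L]] %in% c("minus", "-"), "-", "+")
  } else {
    ifelse(x$sstart > x$send, "-", "+")
  }
  lo <- pmin(x$sstart, x$send); hi <- pmax(x$sstart, x$send)
  data.frame(qseqid = x$qseqid, sseqid = x$sseqid,
             pident = x$pident / 100, length = as.integer(x$length),
             evalue = as.numeric(x$evalue), bitscore = as.numeric(x$bitscore),
             sstart = lo, send = hi, strand = strand, tool = tool,
             stringsAsFactors = FALSE)
}

#' Read a RepeatMasker .out annotation file
#'
#' Parses the fixed whitespace-separated RepeatMasker `.out` layout (three
#' header lines, then one row per hit) and partitions records into LTR-class
#' hits (repeat class/family beginning `LTR`) and all other classes; the
#' latter feed the conflict filter.
#'
#' @param path path to a RepeatMasker `.out` file.
#' @return a list with `ltr` and `other`, each a `GRanges` with metadata
#'   columns `repeat_name`, `repeat_class` and `divergence` (fraction).
#' @export
readRepeatMaskerOut <- function(path) {
  lines <- readLines(path)
  # drop header block and blank lines
  body <- lines[!grepl("^\\s*$", lines)]
  body <- body[!grepl("^\\s*(SW|score|bit)\\b", body)]
  if (!length(body)) {
    empty <- GRanges()
    mcols(empty)$repeat_name <- character(0)
    mcols(empty)$repeat_class <- character(0)
    mcols(empty)$divergence <- numeric(0)
    return(list(ltr = empty, other = empty))
  }
  fields <- strsplit(trimws(body), "\\s+")
  n <- vapply(fields, length, 0L)
  bad <- which(n < 14L)
  if (length(bad))
    stop("malformed RepeatMasker line ", which(lines == body[bad[1L]])[1L],
         ": fewer than 14 fields")
  f <- function(i) vapply(fields, `[[`, "", i)
  gr <- GRanges(f(5L),
                IRanges(as.integer(f(6L)), as.integer(f(7L))),
                strand = ifelse(f(9L) %in% c("C", "-"), "-", "+"))
  mcols(gr)$repeat_name <- f(10L)
  mcols(gr)$repeat_class <- f(11L)
  mcols(gr)$divergence <- as.numeric(f(2L)) / 100
  isLtr <- startsWith(mcols(gr)$repeat_class, "LTR")
  list(ltr = gr[isLtr], other = gr[!isLtr])
}

#' Read a HMMER tblout-style domain hit table
#'
#' Accepts a whitespace- or tab-separated table with one row per hit and the
#' columns `target element_id e_value domain kind frame span_start span_end`
#' (header optional, `#` comments ignored). `domain` names one of the
#' recognised retroelement domains (gag, pro, RT, RNaseH, IN, env, MT, YR,
#' other); `kind` is `nucleotide` or `protein`; `frame` (protein hits) is in
#' -3..+3 excluding 0.
#'
#' @param path file path.
#' @return a `data.frame` of domain hits suitable for
#'   [evaluateCandidateEvidence()] and [callDirs()].
#' @export
readDomainHits <- function(path) {
  x <- read.table(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  if (is.character(x[[3L]]) && any(is.na(suppressWarnings(as.numeric(x[[3L]])))))
    x <- x[-1L, , drop = FALSE]            # header row
  names(x)[1:8] <- c("target", "element_id", "e_value", "domain", "kind",
                     "frame", "span_start", "span_end")
  x$e_value <- as.numeric(x$e_value)
  x$frame <- suppressWarnings(as.integer(x$frame))
  x$span_start <- as.integer(x$span_start)
  x$span_end <- as.integer(x$span_end)
  validateDomainHits(x)
  x
}

validateDomainHits <- function(hits) {
  if (!nrow(hits)) return(invisible(TRUE))
  stopifnot(all(hits$e_value >= 0))
  stopifnot(all(hits$kind %in% c("nucleotide", "protein")))
  prot <- hits$kind == "protein"
  if (any(prot & (is.na(hits$frame) | hits$frame == 0L |
                  abs(hits$frame) > 3L)))
    stop("protein hits must carry a frame in -3..+3 excluding 0")
  invisible(TRUE)
}

#' Read a binned recombination map
#'
#' TSV with columns `chrom start end rate` (cM/Mb), 1-based closed
#' coordinates, header optional. Bins must not overlap.
#'
#' @param path file path.
#' @return a `GRanges` with metadata column `rate`.
#' @export
readRecombinationMap <- function(path) {
  x <- read.table(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  if (is.character(x[[2L]])) x <- x[-1L, , drop = FALSE]
  gr <- GRanges(x[[1L]], IRanges(as.integer(x[[2L]]), as.integer(x[[3L]])))
  mcols(gr)$rate <- as.numeric(x[[4L]])
  if (any(mcols(gr)$rate < 0)) stop("recombination rates must be >= 0")
  self <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(self)) stop("recombination map bins overlap")
  gr
}

#' Read a lineage map for a reference library
#'
#' Two-column TSV `ref_id lineage` mapping reference sequence identifiers to
#' retroviral genera or LTR retrotransposon family labels.
#'
#' @param path file path.
#' @return named character vector `ref_id -> lineage`.
#' @export
readLineageMap <- function(path) {
  x <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  setNames(as.character(x[[2L]]), as.character(x[[1L]]))
}
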