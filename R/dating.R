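# Molecular-clock insertion dating from LTR-LTR divergence.
#
# The two LTRs of an element are identical at insertion and accumulate
# substitutions independently afterwards, so for per-lineage substitution
# rate r (substitutions/site/year) and pairwise divergence d the insertion
# age is T = d / (2 r). The default rate is the Galliformes calibration
# under which d = 0.10 corresponds to 13.5 million years.

#' Default Galliformes per-lineage substitution rate (substitutions/site/yr)
#' @export
GALLIFORMES_RATE <- 3.7e-9

#' Pairwise LTR identity from a global alignment
#'
#' Globally aligns the two LTR sequences and reports the fraction of
#' matching columns. Terminal gap columns (alignment overhangs) are
#' excluded from the denominator; internal gap columns count as mismatches.
#'
#' @param ltr5,ltr3 the two LTR sequences ([Biostrings::DNAString],
#'   character, or `DNAStringSet` of length 1).
#' @return identity fraction in \[0, 1\].
#' @examples
#' ltrIdentity("ACGTACGTAC", "ACGTACGTAC")  # 1
#' @export
ltrIdentity <- function(ltr5, ltr3) {
  asDna <- function(x) {
    if (is(x, "DNAStringSet")) x <- x[[1L]]
    if (is.character(x)) x <- DNAString(x)
    as(x, "DNAString")
  }
  a <- asDna(ltr5); b <- asDna(ltr3)
  if (length(a) == 0L || length(b) == 0L) stop("empty LTR sequence")
  al <- pairwiseAlignment(a, b, type = "global",
                          substitutionMatrix = .ltrSubstMat(),
                          gapOpening = 6, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  gapP <- p == "-"; gapS <- s == "-"
  # strip terminal columns where either sequence has an end-gap run
  lead <- 0L
  while (lead < length(p) && (gapP[lead + 1L] || gapS[lead + 1L]))
    lead <- lead + 1L
  trail <- 0L
  n <- length(p)
  while (trail < n - lead && (gapP[n - trail] || gapS[n - trail]))
    trail <- trail + 1L
  keep <- seq.int(lead + 1L, n - trail)
  if (!length(keep)) return(0)
  sum(p[keep] == s[keep] & !gapP[keep]) / length(keep)
}

#' Date an insertion from LTR identity under the molecular clock
#'
#' @param identity LTR-LTR identity fraction in \[0, 1\] (vectorised).
#' @param rate per-lineage substitution rate in substitutions/site/year.
#' @param elementId optional ids carried into the result.
#' @param jukesCantor apply the Jukes-Cantor multiple-hit correction to the
#'   divergence before dating (default `FALSE`: the clock is linear in d).
#' @return `data.frame` with `element_id`, `identity`, `divergence` and
#'   `age_mya` (millions of years).
#' @examples
#' estimateInsertionAge(0.90)         # 13.5 MYA
#' estimateInsertionAge(0.80)$age_mya # 27.0 MYA
#' @export
estimateInsertionAge <- function(identity, rate = GALLIFORMES_RATE,
                                 elementId = NULL, jukesCantor = FALSE) {
  if (any(identity < 0 | identity > 1)) stop("identity must be in [0, 1]")
  if (rate <= 0) stop("substitution rate must be > 0")
  d <- 1 - identity
  if (jukesCantor) {
    if (any(d >= 0.75)) stop("Jukes-Cantor correction undefined for d >= 0.75")
    d <- -3 / 4 * log(1 - 4 * d / 3)
  }
  data.frame(
    element_id = if (is.null(elementId)) sprintf("el%d", seq_along(identity))
                 else elementId,
    identity = identity, divergence = d,
    age_mya = d / (2 * rate) / 1e6,
    stringsAsFactors = FALSE)
}

#' Age-category randomization test
#'
#' Randomly reassigns insertion ages across elements `reps` times and
#' averages the per-category proportions, where categories are LTR-identity
#' bands defined by `edges`. Reassigning over all elements leaves the age
#' multiset (hence the marginal proportions) unchanged — the informative use
#' is over a `subset` (e.g. elements inside clusters), whose null category
#' proportions then reflect random draws from the full age pool.
#'
#' @param identity numeric vector of per-element LTR identities.
#' @param edges identity breakpoints (ascending, within (0,1)); categories
#'   are `(-Inf, e1], (e1, e2], ..., (ek, 1]`.
#' @param reps number of reassignments (default 1000).
#' @param subset optional logical/integer index: the element subset whose
#'   category proportions are summarised under reassignment (default: all).
#' @param seed optional RNG seed for bit-reproducibility.
#' @return a list with `edges`, `observed` (category proportions of the
#'   subset), `null_mean`, `null_sd` and `reps`.
#' @export
ageRandomization <- function(identity, edges = c(0.7, 0.8, 0.9),
                             reps = 1000L, subset = NULL, seed = NULL) {
  stopifnot(length(identity) >= 1L, reps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(subset)) subset <- seq_along(identity)
  subset <- seq_along(identity)[subset]
  brk <- c(-Inf, edges, Inf)
  catOf <- function(x) cut(x, breaks = brk, labels = FALSE)
  nCat <- length(brk) - 1L
  prop <- function(x) tabulate(catOf(x), nCat) / length(x)
  observed <- prop(identity[subset])
  nullMat <- matrix(0, nrow = reps, ncol = nCat)
  for (r in seq_len(reps)) {
    perm <- sample(identity)
    nullMat[r, ] <- prop(perm[subset])
  }
  labels <- paste0("(", c("-Inf", edges), ",", c(edges, "1"), "]")
  list(edges = edges,
       observed = setNames(observed, labels),
       null_mean = setNames(colMeans(nullMat), labels),
       null_sd = setNames(apply(nullMat, 2L, sd), labels),
       reps = reps)
}

#' Correlation between GC deviance and insertion age
#'
#' Tests whether the absolute deviation of element GC content from the
#' genomic mean shrinks with element age: Pearson correlation between
#' `|gc - genomeGC|` and LTR identity (young elements have high identity),
#' with a two-sided p-value.
#'
#' @param gc per-element GC fractions.
#' @param genomeGC genome-wide mean GC fraction.
#' @param identity per-element LTR identity.
#' @return `htest` from [stats::cor.test()].
#' @export
gcDevianceAgeCorrelation <- function(gc, genomeGC, identity) {
  stopifnot(length(gc) == length(identity))
  if (length(gc) < 3L) stop("need at least 3 elements")
  dev <- abs(gc - genomeGC)
  if (sd(dev) == 0 || sd(identity) == 0)
    stop("zero variance: correlation undefined")
  cor.test(dev, identity, method = "pearson", alternative = "two.sided")
}
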