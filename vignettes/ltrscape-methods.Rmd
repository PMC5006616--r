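---
title: "ltrscape: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ltrscape: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrscape)
library(GenomicRanges)
```

## The annotation model

LTR retrotransposons (including endogenous retroviruses) are annotated from
three complementary evidence streams, and every interval in the final
annotation carries its provenance:

- **Homology** evidence comes in as BLAST-style tabular hits and
  RepeatMasker records. Hits are retained at `E <= 1e-10` and alignment
  length `>= 100` bp — both boundaries inclusive, matching how the DIRS
  domain rule treats its thresholds ("or better") — then merged whenever
  two intervals are fewer than 11 bp apart (an inter-interval gap of at
  most 10 intervening bases). Elements whose span is at least half covered
  by non-LTR repeat classes are removed: the dominant false-positive mode
  is a LINE element (in birds, CR1) matched through its reverse
  transcriptase domain. A reciprocal search against a user-supplied
  reference LTR library flags validated records; unvalidated homology-only
  records that also lack structural support are dropped at the final merge.
- **Structural** evidence is produced by the package's own detector
  (below).
- **Secondary** evidence re-queries the genome with the accepted
  structurally intact elements (SIEs) and keeps hits passing the primary
  E-value/length filters that are not already inside the annotation. The
  thresholds of this stage are deliberately the primary ones: the stage is
  a homology protocol with a different query set, and a separate threshold
  would add a free parameter with no constraint to set it.

Coordinates are 1-based and closed throughout, the native convention of
`GRanges`; BED input/output converts at the boundary via `rtracklayer`.
Merging is strand-agnostic — the unit of annotation is a genomic locus, and
fragment hits may legitimately be reported on either strand — while strand
is preserved as metadata and honoured where it matters (same-orientation
transcript intersection, where unstranded records are conservatively
excluded).

## The structural detector

The detector finds pairs of similar direct repeats under explicit
constraints, defaulting to LTR lengths of 80-2000 bp, pairwise LTR identity
of at least 0.75, and element spans of 1-25 kb (the span upper bound
accommodates long nested elements; mean intact-element length in real
genomes is near 8.5 kb). Candidate generation is exact k-mer seeding
(k = 12): genome positions sharing a 12-mer at an admissible spacing are
grouped on near-constant diagonals, and each group is refined by local
alignment (match +2, mismatch -2, gap open 6, gap extend 2) of the two
repeat copies; similarity is matches over alignment columns. At 75 %
identity about 3 % of 12-mers survive intact, so a 300 bp LTR still yields
several seeds, while a uniform-random genome yields essentially none at
admissible spacings — requiring two seeds per diagonal suppresses the
background at negligible cost in sensitivity. Direct repeats remain direct
repeats under reverse complement, so a forward scan covers insertions on
both strands and detection is mirror-invariant.

A candidate becomes an accepted element when it carries at least two of the
five structural evidence flags — `TG..CA` termini on both LTRs; an exact
4-6 bp target-site duplication immediately outside both LTRs; a primer
binding site with at least 16/18 complementarity to the 3'-terminal 18-mer
of a supplied tRNA within 20 bp downstream of the left LTR; an 11 bp
window with at least 9 purines (the polypurine tract) ending within 20 bp
upstream of the right LTR; an `AATAAA` motif within either LTR — or at
least one internal protein/nucleotide domain hit passing the evidence
thresholds (nucleotide `E <= 1e-5`, protein `E <= 1e-10`). A reproducible
rule deliberately replaces case-by-case manual review. Overlapping accepted
candidates are resolved by keeping the highest similarity-times-evidence
score, ties broken by longer element then leftmost position — except that
an element lying wholly inside another's internal region is kept and
flagged nested, since nested insertion is a real biological configuration
rather than a detection conflict.

PBS and PPT are motif scans against user-supplied tRNA sequences rather
than profile HMMs: the thresholds above are explicit, configurable and need
no external HMM toolchain; the TSD search is exact-match over 4-6 bp
because mismatch-tolerant TSD matching mostly admits noise at these
lengths.

## Lineage classification

Filtered evidence bundles (nucleotide hits at `E <= 1e-5`, protein at
`E <= 1e-10`) are classified with protein-over-nucleotide precedence, and
among protein domains reverse transcriptase outranks the rest — RT is the
most conserved and most diagnostic retroelement domain. "Best" means lowest
E-value, ties broken by longer alignment span then input order, with ties
logged. Reference lineage labels travel with the user's library (sidecar
TSV); the package ships no proprietary reference content.

## Insertion dating

The two LTRs are identical at insertion and each lineage accumulates
substitutions independently afterwards, so age is `T = d / (2r)` with `d`
the pairwise LTR divergence and `r` the per-lineage substitution rate. The
default `r = 3.7e-9` substitutions/site/year is the Galliformes
calibration under which `d = 0.10` corresponds to 13.5 MYA (and linearly,
`d = 0.20` to 27.0 MYA, the chicken-turkey split era). The clock is linear
in `d` by default — consistent with that calibration pairing — with an
optional Jukes-Cantor correction for users who prefer multiple-hit
adjustment at higher divergences. LTR identity is computed from a global
alignment; terminal gap columns are excluded from the denominator (they
reflect boundary uncertainty, not substitutions) and internal gap columns
count as mismatches. The age-category randomization permutes ages across
elements; over the full element set this provably reproduces the observed
marginals (a useful self-check), so the informative mode summarises a
subset — e.g. elements inside clusters — against permutations of the full
age pool.

## Distribution statistics

- **Density and correlates.** Element density per chromosome is count over
  megabases; density, chromosome length, gene density and recombination
  rate are log10-transformed before pairwise Pearson correlation and a
  Gaussian identity-link GLM of log-density on log-length and
  log-recombination, with named chromosomes excludable (assemblies often
  carry chromosomes whose residuals or gap content disqualify them).
- **Clusters.** The cluster criterion is at least 5 elements per Mb
  (against an even background of about 1 per Mb). The implementation takes
  the continuous limit of a sliding 1 Mb window: any run of 5 consecutive
  element midpoints spanning at most 1 Mb seeds a cluster and overlapping
  runs are unioned. This is deterministic, O(n log n), equivalent to an
  arbitrarily fine window step, and leaves window size and member count
  configurable.
- **The random-integration null.** Each replicate places n point
  integrations uniformly over assembled (non-gap) bases, chromosomes chosen
  proportional to assembled length; points, not intervals, because the
  quantity modelled is the integration event. The statistic per replicate
  is either the in-cluster fraction or the distance-category profile.
  Simulations are seeded and bit-reproducible.
- **Distance profiles and tests.** A transcriptional unit (TU) is a gene
  span plus 5 kb on each side, merged where overlapping. Elements
  overlapping a TU are category `TU`; the rest are binned by shortest
  edge-to-edge distance in 10 kb bins to 100 kb, then `>100kb`; elements on
  contigs without any gene annotation are `ND` (non-defined) — they cannot
  be assigned a distance at all. Per category, a two-sided exact binomial
  test compares the observed count to n times the null mean proportion
  (null-simulation means, not analytic coverage, so the expectation and the
  observation come from the same machinery); overall, a two-sample
  Kolmogorov-Smirnov test compares observed distances to pooled null
  distances. Sidedness is two-sided by choice: enrichment and depletion are
  both of interest.
- **Subfeature overlap.** TU-overlapping elements are assigned one
  subfeature by precedence exon > 5'UTR > 3'UTR > intron > flank; expected
  fractions come either from null integration points restricted to TUs or
  analytically from the per-base share of each precedence class.
- **Expression.** Per tissue, same-strand transcripts over an element's
  internal region (between the LTRs) give `complete` (a single transcript
  covers the whole internal region), `partial` (any same-strand overlap) or
  `none`; unstranded transcripts are excluded with a warning.

## The synthetic-data generator

`simulateGenome()` emulates the inputs of a real annotation run:
i.i.d. background sequence at configurable GC (0.42 by default); planted
intact elements whose two LTR copies are independently mutated at `d/2`
each, so the pair diverges by about `d` exactly as the dating model
assumes; TSDs duplicated outside both LTRs; PBS/PPT/poly-A/TG..CA built
into the templates; lineage-tagged synthetic domain sequences inside;
fragments of the element templates; LINE-like conflicting repeats; gene
models with exon/UTR structure; covering transcripts for a configurable
fraction of elements; and a binned recombination map. The default
desk-scale configuration — 2 Mb over two chromosomes, 10 intact elements at
divergences drawn from [0.01, 0.12] (young insertions dominate real
element populations), 50 fragments, 40 genes — is the condition under which
the recovery properties in the test suite are stated. Synthetic BLAST
E-values follow the declining heuristic `E = 10^-(identity x length / 5)`
and are synthetic by construction: only their ordering and threshold
behaviour are meaningful.

What the generator does **not** model bounds what passing tests show:
substitution is uniform (no transition bias, no rate heterogeneity), there
is no insertion-history realism (no bursts, no selection), background
composition is memoryless, and indels default to zero. Recovery rates on
this synthetic material therefore demonstrate algorithmic correctness —
boundary accuracy, threshold behaviour, provenance conservation — not
expected sensitivity on real genomes, where nested, truncated and anciently
diverged elements are harder.

## Numerical choices and degenerate inputs

Threshold comparisons are inclusive everywhere. Correlation and GLM inputs
must be strictly positive before log transform, and zero-variance inputs
raise errors rather than returning NaN. Chi-square tests use no continuity
correction (df = 1) and flag tables with any expected cell below 1. The
binomial test degenerates gracefully when the null proportion is 0 or 1.
Distance 0 (adjacent but non-overlapping) falls in the first distance bin.
Empty inputs return empty results for set operations and errors only where
a result would be meaningless (dating an empty sequence, a null of zero
integrations).

## Problem sizes

The test suite runs the detector on 2 Mb of simulated genome plus a 1 Mb
null sequence, and the genome-scale Monte-Carlo null at 1,000 replicates of
1,073 integrations over a 1.047 Gb partition — sizes chosen so the full
suite completes in a few minutes on a single core while every property is
exercised at meaningful scale. The chromosome partition used for the
genome-scale null reproduces the macro/micro size structure of the chicken
galGal4 assembly with the unplaced remainder modelled as 200 kb scaffolds;
only the size structure, not the identity of the scaffolds, matters to a
uniform integration null.

## Known limitations

The detector's boundary precision degrades with LTR divergence (local
alignment ends drift a few bases); recall falls to zero beyond the
similarity threshold by construction. Classification reflects the supplied
reference labels and does no phylogenetic inference. The dating confidence
range is whatever rate uncertainty the user propagates; the package does
not estimate the substitution rate. External detection programs are
supported only through their tabular/GFF outputs; the package does not
reimplement or execute them.
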