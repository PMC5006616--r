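# ltrscape

Annotation, insertion dating and genomic distribution analysis of LTR
retrotransposons and endogenous retroviruses (ERVs) in assembled genomes.

LTR retrotransposons are flanked by two long terminal repeats (LTRs) that
are identical at insertion and diverge afterwards. `ltrscape` exploits this
anatomy three ways:

1. **Annotation** combines three evidence streams, each carried as a
   provenance tag on every interval:
   - *homology*: BLAST-style hit tables and RepeatMasker output, filtered at
     `E <= 1e-10` and alignment length `>= 100` bp, merged when intervals
     are fewer than 11 bp apart, cleaned by a conflict filter (elements
     mostly covered by other repeat classes, e.g. CR1 LINEs matched through
     their reverse transcriptase, are removed) and a reciprocal search
     against a reference LTR library;
   - *structural*: a de novo detector that pairs direct repeats of
     80-2000 bp at `>= 75 %` identity spanning 1-25 kb (k-mer seeding plus
     local alignment), then demands internal/terminal evidence — `TG..CA`
     termini, a 4-6 bp target-site duplication (TSD), a primer binding site
     (PBS) complementary to a host tRNA 3' end, a polypurine tract (PPT), a
     polyadenylation motif — or a protein-domain hit;
   - *secondary*: a homology expansion using the structurally intact
     elements (SIEs) as queries, recovering related fragments that lack
     archetypal structure.
2. **Dating** uses the molecular clock `T = d / (2r)`: each LTR lineage
   accumulates substitutions independently after insertion, so pairwise LTR
   divergence `d` and a per-lineage substitution rate `r` give the
   insertion age. The default Galliformes rate `r = 3.7e-9`
   substitutions/site/year maps 10 % divergence to 13.5 million years.
3. **Distribution statistics**: per-chromosome density with log-scale
   Pearson correlations and a GLM on chromosome length and recombination
   rate; density clusters (>= 5 elements per Mb); a seeded Monte-Carlo null
   of uniform point integrations for cluster and distance-to-gene
   enrichment (exact binomial per category, Kolmogorov-Smirnov overall);
   subfeature overlap with exon > 5'UTR > 3'UTR > intron > flank
   precedence; and transcriptional completeness of elements from stranded
   transcript models.

A synthetic-genome simulator plants intact elements (controlled LTR
divergence, TSDs, PBS/PPT, lineage-tagged domains), fragments, gene models
and transcripts, and emits a truth table, so the whole pipeline is testable
end to end without downloads.

## Worked example

```r
library(ltrscape)
sim <- simulateGenome(simulationConfig(seed = 17))   # 2 Mb, 10 planted SIEs
el  <- callStructuralElements(sim$genome, trnaSet = sim$trna)
acc <- el[mcols(el)$accepted]
head(as.data.frame(acc)[, c("seqnames","start","end","similarity","n_evidence")], 3)
#>   seqnames  start    end similarity n_evidence
#> 1  simchr1   6671  11530  0.9661017          3
#> 2  simchr1 107006 112066  0.9652174          4
#> 3  simchr1 237299 241584  0.9365079          3

estimateInsertionAge(mcols(acc)$similarity,
                     elementId = mcols(acc)$element_id)[1:3, ]
#>           element_id  identity divergence  age_mya
#> 1   SIE_simchr1_6671 0.9661017 0.03389831 4.580852
#> 2 SIE_simchr1_107006 0.9652174 0.03478261 4.700353
#> 3 SIE_simchr1_237299 0.9365079 0.06349206 8.580009
```

All ten planted elements are recovered (boundaries within 20 bp of the
planted coordinates), their LTR identities reflect the planted divergences,
and the clock converts identity to age in millions of years: an element
whose LTRs are 96.6 % identical inserted roughly 4.6 MYA. The worked clock
example `estimateInsertionAge(0.90)` prints an age of 13.51 MYA.

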