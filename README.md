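# GenesetCompare

Structural comparison of transcript-level gene annotation sets
("genesets") and the impact of the chosen geneset on variant functional
annotation and on exon/intron expression summaries.

## Who this is for

Annotation and variant-interpretation groups who need to quantify how two
annotations of the same genome — typically a GENCODE-like set curated for
transcriptional completeness and a RefSeq-like set built around curated
accessions — differ, and what those differences do to downstream variant
effect calls.  Because the real reference inputs are version-pinned
external resources, the package also ships a deterministic synthetic-data
generator with complete ground-truth bookkeeping, so the whole pipeline is
testable end to end on a laptop.

## The core quantities

Transcript identity for comparison is structural, not accession-based.
For a transcript *t* with exons *e1..ek*:

* single-exon: key(t) = (chrom, strand, start(e1), end(e1))
* multi-exon: key(t) = the ordered **intron chain**
  ((end(e1)+1, start(e2)-1), ..., (end(e(k-1))+1, start(ek)-1)),
  which ignores terminal-exon outer coordinates and therefore treats
  transcripts differing only in UTR length as identical.

A **translation** is keyed by its CDS-exon coordinates exactly as
annotated.  The **non-redundant exon set** collapses exact duplicates and
terminal exons whose single splice junction is shared with a longer exon
(the longer exon is kept); internal exons that overlap but differ in at
least one junction all stay.  Comparing two genesets partitions each
feature kind into shared / unique-to-A / unique-to-B, with the
conservation identity |shared| + |unique_A| = #keys(A).

For variants, a minimal consequence caller assigns per-transcript terms
(exon or proximal splice region only: donor/acceptor = first/last 2
intronic bp, splice region = exonic bp 1–3 or intronic bp 3–8 from a
junction), selects one most-severe call per variant per geneset by the
usual severity ranking, and classifies each variant across the two
genesets as **concordant** (same call), **discordant** (different call) or
**unique** (annotated in only one geneset), stratified into the broad
classes LoF / CDS / splice / other.

## Worked example

Generate a paired study with planted structure (60 shared intron chains,
25 unique to A, 15 unique to B), compare, and check variant concordance:

```r
library(GenesetCompare)

sim <- simulateStudy(simParams(seed = 42, nGenes = 50, txPerGene = 2,
                               fracShared = 0.6, fracUniqueA = 0.25))
sim$A
#> Geneset object "A" (assembly: synthetic)
#>   49 genes; 85 transcripts (81 coding)
#>   biotypes: NMD=1, processed_transcript=2, protein_coding=80, retained_intron=2
#>   chromSizes for 1 chromosome(s)

compareTranscripts(sim$A, sim$B)
#> FeaturePartition (transcript): A vs B
#>   shared: 60; unique to A: 25; unique to B: 15

compareTranslations(sim$A, sim$B)
#> FeaturePartition (translation): A vs B
#>   shared: 48; unique to A: 33; unique to B: 27

annA <- annotateVariants(sim$variants, sim$A, sim$genome)
annB <- annotateVariants(sim$variants, sim$B, sim$genome)
sm <- concordanceSummary(classifyVariants(annA, annB))
sm$overall
#>       status   n   percent
#> 1 concordant 150 76.923077
#> 2 discordant   0  0.000000
#> 3   unique_A  15  7.692308
#> 4   unique_B  30 15.384615

sm$percent_nonconcordant
#>    class percent_nonconcordant
#> 1    LoF                     0
#> 2    CDS                     0
#> 3 splice                     0
#> 4  other                    60
```

The transcript partition recovers the planted 60/25/15 exactly.  The
variant table shows the designed mechanism: all non-concordance in this
run comes from UTR extensions and non-coding exons — broad class `other` —
while every CDS, splice and LoF call agrees between the genesets.

Real data enter through files: `readGeneset("annotation.gtf")`,
`readChromSizes()`, `annotateVariants("variants.vcf", gs, "genome.fa")`,
`readCoverageTrack("sample.bedGraph")`, or the one-shot orchestrator
`runFullComparison(runConfig(...))`, which writes TSV report tables and a
JSON summary.

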