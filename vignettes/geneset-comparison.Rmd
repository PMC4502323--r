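---
title: "Comparing gene annotation sets: models, conventions and design choices"
author: "GenesetCompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing gene annotation sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GenesetCompare)
```

# The problem

Two widely used transcript annotations of the same genome — one
GENCODE-like, curated for transcriptional completeness, one RefSeq-like,
curated around accessioned transcripts — disagree in ways that matter
downstream: they imply different numbers of alternatively spliced
transcripts per locus, different non-redundant exon complements and genomic
footprints, and, most consequentially, different functional annotations for
the same variants.  This package implements the comparison machinery as a
reusable pipeline: derive the standard annotation subsets, quantify
shared/unique transcripts, translations and exons, classify per-variant
annotation as concordant/discordant/unique under each geneset, and
summarise exon/intron expression from coverage tracks.  Because the real
reference inputs are version-pinned external resources, the package ships a
deterministic synthetic-data generator with complete ground-truth
bookkeeping; every stage is validated against that ground truth and against
independent brute-force oracles.

# Data model and conventions

A `Geneset` stores per-transcript exon and CDS ranges (`GRangesList`) plus
transcript metadata: a normalised transcript biotype (`protein_coding`,
`NMD`, `retained_intron`, `processed_transcript`, `other`), a RefSeq-style
accession class inferred from the id prefix (`NM`/`NR`/`XM`/`XR`/`none`),
tags (`basic`, `CDS_start_NF`, ...) and a locus biotype.  Coordinates are
1-based, closed intervals throughout (the native GRanges convention); GTF
input is therefore stored as-is and widths equal `end - start + 1`.

Two identity notions are deliberately decoupled.  Accession strings are
used only for IO and subset rules.  *Structural* equivalence drives every
comparison:

* **Transcript key** — the exon coordinates for a single-exon transcript;
  the ordered intron coordinates (intron chain) for a multi-exon
  transcript.  Intron chains ignore terminal-exon outer coordinates, so
  transcripts differing only in UTR length compare equal.  Single-exon
  transcripts get no such forgiveness: their key is the exact exon, since
  UTR compensation is only meaningful where introns pin down the structure.
* **Translation key** — the CDS-exon coordinates exactly as annotated.  No
  stop-codon extension is applied; the comparison is over the annotation,
  not a recomputed ORF.

# Subset rules

`selectProteinCodingLoci()` keeps `coding` loci; in the RefSeq-like
convention it additionally keeps `misc_RNA` loci where at least one
transcript has a CDS.  `applySubsetRule()` then derives: *comprehensive*
(everything), *basic* (full-length protein-coding: tagged `basic` or,
equivalently, `protein_coding` with a CDS and no `CDS_start_NF`/
`CDS_end_NF`; NMD/retained_intron/processed_transcript excluded), *nxr*
(NM/NR/XM/XR transcripts in genes with at least one curated NM/NR
transcript; genes with only predicted models are dropped), and *nr* (NM/NR
only).  Whether "basic" should also require an annotated stop codon is not
decidable from tags alone; the tag/structure-based definition above is
used.

# Non-redundant exons

An exon set is collapsed by three rules: exact duplicates merge; a terminal
exon (first or last in at least one transcript) whose single internal
splice junction is shared with a longer exon is dropped in favour of the
longer exon; internal exons that overlap but differ in at least one
junction are all kept.  An exon terminal in one transcript but internal in
another counts as internal (both its boundaries are junctions somewhere).
Exons of single-exon transcripts carry no junctions and are only
deduplicated.  Equal-length candidates cannot arise within one junction
group (same junction + same length = same coordinates), but a
lexicographic tie-break is implemented for determinism anyway.

For the cross-geneset exon partition the same terminal/longer-exon rule is
extended across the union of the two collapsed sets, so a terminal exon in
A matching a junction of a longer exon in B counts as shared.  Per-side
"distinct key" counts are defined as the number of union representatives
carrying members from that side, which keeps the conservation identity
`|shared| + |unique_X| = nKeys_X` exact even when several members collapse
onto one representative.

Genomic coverage reports both the summed member lengths per strand (the
headline number; some genome may be counted twice where exons share a donor
but not an acceptor) and the merged footprint (union of intervals).  The
percentage denominator is the total genome length from the chrom.sizes
file, for every row including the per-strand ones — coverage tracks how
much sequence is annotated, not a per-strand fraction.

# The consequence caller

A minimal, deterministic variant-consequence caller stands in for a full
effect predictor.  A variant receives terms against a transcript only when
it falls in an exon or the proximal splice region; everything deeper is
dropped ("does not map").  Window widths follow the common convention:
donor/acceptor are the first/last 2 intronic bp; splice region is exonic bp
1–3 from a junction or intronic bp 3–8.  CDS SNVs are translated on the
spliced, strand-oriented CDS with the standard genetic code
(stop gained/lost, start lost, synonymous, missense); CDS indels are
frameshift when the length change is not a multiple of 3, in-frame
otherwise.  Exonic non-CDS positions are utr5/utr3 relative to the CDS on
the coding strand; exonic positions of CDS-less transcripts are
noncoding_exon.  Transcripts tagged `CDS_start_NF` have no anchorable
reading frame, so CDS-overlapping variants get
`coding_sequence_ambiguous`; `CDS_end_NF` alone still anchors the frame at
the annotated start and is classified normally.  NMD status is read from
the biotype, never recomputed.  Indels are left-normalised against the
reference before overlap tests; multi-allelic records are split upstream.

One call per variant per geneset is selected by a fixed severity ranking
(most severe first): splice_acceptor, splice_donor, stop_gained,
frameshift, stop_lost, start_lost, inframe_indel, missense, splice_region,
synonymous, coding_sequence_ambiguous, utr5, utr3, noncoding_exon.  The
broad classes group these as LoF (stop gained/lost, start lost, frameshift,
essential splice sites), CDS (missense, synonymous, in-frame indel,
ambiguous coding), splice (splice region) and other (UTR, non-coding
exon).  The ranking is exposed via `consequenceTerms()` and is replaceable
through the `rank` argument of `mostSevere()`.

Concordance between two genesets compares, by default, the selected
most-severe call per variant (`granularity = "term"`); comparing the full
per-transcript term set (`"termset"`) or only broad classes (`"broad"`) are
options, since both flavours of the question are legitimate.  A record
whose two sides fall in different broad classes is stratified by the more
severe side, so a LoF-vs-other discordance counts as LoF — the
conservative choice for reporting non-concordance among LoF calls.

# Expression summaries

Exon and intron complements are kept per-transcript redundant (an exon in
three transcripts is counted three times), introns included; feature
identity is exact coordinates.  `intervalDensity()` averages a per-base
bedGraph track over the feature span (absent positions read as zero);
`featureExpression()` summarises across samples by maximum, median and
mean.  The median of an even number of samples is the mean of the two
middle values (the R convention).  ECDFs are right-continuous; the
fraction at threshold 0 is the silent-feature proportion (the "y
intercept").

# The synthetic generator

`simParams()`/`simulateStudy()` define the study conditions.  Defaults: one
chromosome of 1 Mb, 100 non-overlapping strand-alternating genes of six
150 bp exon slots (250 bp introns), two planted transcript chains per gene,
70% of chains shared between the two genesets, 20% unique to A, the rest
unique to B; 30% of shared chains get UTR-only terminal extensions on the
B side and 20% an in-frame CDS-start shift (same chain, different
translation); ten unique chains per side carry a novel exon with a novel
splice junction; 10% of A-only chains are truncated (`CDS_start_NF`) and
20% carry non-coding biotypes (retained_intron, processed_transcript,
NMD).  Variants are planted at positions whose category is known by
construction (synonymous/missense/stop-gain codons written into the
genome, essential donor sites, 5'UTR positions, B-only UTR extensions,
A-only retained-intron exons, deep introns, intergenic gaps).  Expression
uses 18 samples (mirroring a multi-cell-line RNA-seq design) with
per-gene, per-sample gamma densities (shape 2, rate 0.5), a 0.25
zero-inflation fraction, and introns at 0.1 times the exonic density.

Realism boundaries, stated plainly: genes do not overlap, exon sizes are
regular, splice sites are written as canonical GT/AG but never used by the
comparison logic, anchored CDSs are guaranteed ORFs (ATG, in-frame
terminal stop, no internal stop; the generator writes exonic sequence
without T except at planted codons to make this exact), and expression is
planted per gene rather than per feature — overlapping features share
genomic bases, so independent per-feature densities are not realisable in
a per-base track.  Consequently zero-inflation operates at the gene level
and recovery of the silent fraction is assessed with a gene-level binomial
bound.  Passing tests demonstrate the pipeline's correctness on data with
known structure; they do not certify behaviour on the messier real genome
(overlapping loci, non-canonical splicing, incomplete assemblies).

The generator's GTF output includes the stop codon inside the CDS features
so that stop-loss consequences are observable under the verbatim-CDS
convention; real GENCODE GTFs exclude the stop from CDS, in which case
stop_lost is simply never called.

# Numerical and degenerate-input choices

Ties in terminal-exon collapsing break lexicographically by
(chromosome, start, end).  Per-locus means are taken over loci with at
least one multi-exon transcript; a geneset with none reports zeros with a
`degenerate` flag.  `intervalDensity()` rejects zero-length intervals;
`expressionEcdf()` rejects empty or negative input; `mostSevere()` rejects
an empty term list.  Validation problems in a `Geneset` are returned as
data by `validateGeneset()` rather than raised, except structural
impossibilities at parse time (malformed GTF lines, exons without
transcript ids, CDS outside exons), which raise errors naming the line or
transcript.  All randomness in the generator derives from the single seed
(per-stage offsets keep the streams independent); two runs under one seed
write byte-identical files.

# Problem sizes

The shipped test suite and the acceptance script run the generator at 8–100
genes, 2–3 chains per gene, up to 18 samples and a few hundred planted
variants — sizes chosen so the full pipeline completes in seconds to a few
minutes while every planted relation is still individually checkable.  The
oracle-equivalence checks use 20 random fixtures of up to ~500 exons
against O(n^2) brute-force reimplementations, and the consequence caller is
checked against an independent string-slicing classifier for every possible
SNV over a three-exon toy gene on both strands.

# Known limitations

GFF3 input is not supported (GTF only); assembly patches, alternative
haplotypes and coordinate projection between assemblies are out of scope —
all inputs must share one assembly.  RefSeq transcripts mapping to multiple
genomic locations are assumed to have one placement per transcript id.
Upstream/downstream gene-flank and regulatory-region consequences are not
called, and deleteriousness scores are not computed.  Dominant-transcript
analysis and transcript-level quantification are outside the package's
remit.
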