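# Toy-object builders used across the suite.

# Build a Geneset from a compact per-transcript description:
# list(id=, gene=, chrom=, strand=, exons=matrix(2 cols), cds=matrix|NULL,
#      biotype=, tags=, locus=)
makeGeneset <- function(txs, name = "toy", chromSizes = NULL) {
  ex <- GenomicRanges::GRangesList(lapply(txs, function(t)
    GenomicRanges::GRanges(t$chrom,
                           IRanges::IRanges(t$exons[, 1], t$exons[, 2]),
                           strand = t$strand)))
  names(ex) <- vapply(txs, `[[`, "", "id")
  cd <- GenomicRanges::GRangesList(lapply(txs, function(t)
    if (is.null(t$cds)) GenomicRanges::GRanges()
    else GenomicRanges::GRanges(t$chrom,
                                IRanges::IRanges(t$cds[, 1], t$cds[, 2]),
                                strand = t$strand)))
  names(cd) <- names(ex)
  td <- S4Vectors::DataFrame(
    tx_id = names(ex),
    gene_id = vapply(txs, function(t)
      if (is.null(t$gene)) t$id else t$gene, ""),
    biotype = vapply(txs, function(t)
      if (is.null(t$biotype)) "protein_coding" else t$biotype, ""),
    accession_class = GenesetCompare:::.accessionClass(names(ex)),
    tags = IRanges::CharacterList(lapply(txs, function(t)
      if (is.null(t$tags)) character(0) else t$tags)),
    locus_biotype = vapply(txs, function(t)
      if (is.null(t$locus)) "coding" else t$locus, ""))
  Geneset(name, ex, cd, td, chromSizes = chromSizes)
}

tx <- function(id, exons, cds = NULL, strand = "+", chrom = "chr1",
               gene = NULL, biotype = "protein_coding", tags = NULL,
               locus = "coding") {
  list(id = id, gene = gene, chrom = chrom, strand = strand,
       exons = matrix(exons, ncol = 2, byrow = TRUE),
       cds = if (is.null(cds)) NULL else matrix(cds, ncol = 2, byrow = TRUE),
       biotype = biotype, tags = tags, locus = locus)
}

# random ACGT chromosome as a plain string
randomChrom <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# one simulated study shared across test files (computed once)
.simCache <- new.env(parent = emptyenv())
sharedSim <- function() {
  if (is.null(.simCache$sim))
    .simCache$sim <- simulateStudy(simParams(seed = 11, nGenes = 30,
                                             txPerGene = 3, nSamples = 6))
  .simCache$sim
}

# its per-geneset variant annotations (computed once)
sharedAnn <- function() {
  if (is.null(.simCache$ann)) {
    sim <- sharedSim()
    .simCache$ann <- list(
      A = annotateVariants(sim$variants, sim$A, sim$genome),
      B = annotateVariants(sim$variants, sim$B, sim$genome))
  }
  .simCache$ann
}
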