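# Synthetic-data generator: determinism, validity and planted structure.

test_that("genome generation is deterministic with realistic base composition", {
  p <- simParams(seed = 9, nChroms = 2, chromLength = 1e5)
  g1 <- simulateGenome(p)
  g2 <- simulateGenome(p)
  expect_identical(g1$seq, g2$seq)
  expect_equal(unname(g1$sizes), c(1e5L, 1e5L))
  expect_named(g1$sizes, c("chr1", "chr2"))
  expect_false(grepl("[^ACGT]", g1$seq[[1]]))
  # 6-sigma binomial band around 0.5 for uniform bases at n = 1e5
  gc <- mean(strsplit(g1$seq[[1]], "")[[1]] %in% c("G", "C"))
  expect_gt(gc, 0.45); expect_lt(gc, 0.55)
  g3 <- simulateGenome(simParams(seed = 10, nChroms = 2,
                                 chromLength = 1e5))
  expect_false(identical(g1$seq, g3$seq))
})

test_that("the full study is byte-identical under one seed", {
  p <- simParams(seed = 5, nGenes = 12, txPerGene = 2, nSamples = 3,
                 variantCounts = c(cds_synonymous = 5, splice_donor = 3,
                                   utr5 = 3, deep_intron = 3,
                                   intergenic = 2))
  d1 <- file.path(tempdir(), "simrun1"); d2 <- file.path(tempdir(), "simrun2")
  s1 <- simulateStudy(p, d1)
  s2 <- simulateStudy(p, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$truth$expected, s2$truth$expected)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("generated annotation is valid and VCF reference alleles match", {
  sim <- sharedSim()
  expect_length(validateGeneset(sim$A), 0L)
  expect_length(validateGeneset(sim$B), 0L)
  v <- sim$variants
  for (i in seq_len(nrow(v))) {
    obs <- as.character(Biostrings::subseq(sim$genome[[v$chrom[i]]],
                                           v$pos[i],
                                           v$pos[i] + nchar(v$ref[i]) - 1L))
    expect_identical(obs, v$ref[i])
  }
})

test_that("planted CDSs are translatable open reading frames", {
  sim <- sharedSim()
  td <- transcriptTable(sim$A)
  anchored <- which(lengths(cdsRanges(sim$A)) > 0 &
                    !vapply(td$tags, function(t) "CDS_start_NF" %in% t, NA))
  for (i in anchored[seq_len(min(25, length(anchored)))]) {
    cds <- BiocGenerics::sort(cdsRanges(sim$A)[[i]])
    strand <- as.character(BiocGenerics::strand(cds))[1]
    chrom <- as.character(GenomeInfoDb::seqnames(cds))[1]
    pieces <- vapply(seq_along(cds), function(j)
      as.character(Biostrings::subseq(sim$genome[[chrom]],
                                      BiocGenerics::start(cds)[j],
                                      BiocGenerics::end(cds)[j])), "")
    s <- paste(pieces, collapse = "")
    if (strand == "-")
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    expect_equal(nchar(s) %% 3, 0)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_equal(substr(s, 1, 3), "ATG")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)))
  }
})

test_that("an identity pair yields no unique features", {
  p <- simParams(seed = 3, nGenes = 10, txPerGene = 2, fracShared = 1,
                 fracUniqueA = 0, fracUtrOnly = 0, fracCdsShift = 0,
                 nUniqueExonsPerSide = 0,
                 variantCounts = c(cds_synonymous = 2))
  genome <- simulateGenome(p)
  pair <- simulateGenesetPair(p, genome)
  pt <- compareTranscripts(pair$A, pair$B)
  nChains <- length(unique(pair$truth$transcripts$chain_key))
  expect_equal(unname(partitionCounts(pt)), c(nChains, 0L, 0L))
  pe <- compareExons(pair$A, pair$B)
  expect_equal(unname(partitionCounts(pe)[c("unique_A", "unique_B")]),
               c(0L, 0L))
})

test_that("infeasible parameters raise generation errors", {
  p <- simParams(seed = 1, nGenes = 1000, chromLength = 1e5)
  expect_error(simulateGenesetPair(p, simulateGenome(p)), "do not fit")
  # noncoding_exon variants need retained-intron transcripts
  p2 <- simParams(seed = 1, nGenes = 8, txPerGene = 2, fracNoncoding = 0,
                  fracUniqueA = 0.2,
                  variantCounts = c(noncoding_exon = 5))
  pair <- simulateGenesetPair(p2, simulateGenome(p2))
  expect_error(simulateVariants(p2, pair), "noncoding_exon")
})

test_that("written artefacts are readable by the package's own IO", {
  d <- file.path(tempdir(), "simio")
  sim <- simulateStudy(simParams(seed = 21, nGenes = 8, txPerGene = 2,
                                 nSamples = 2,
                                 variantCounts = c(cds_synonymous = 3,
                                                   utr5 = 2,
                                                   deep_intron = 2)), d)
  A2 <- readGeneset(sim$files$gtfA, name = "A",
                    chromSizes = readChromSizes(sim$files$sizes))
  expect_length(validateGeneset(A2), 0L)
  expect_identical(sort(transcriptTable(A2)$tx_id),
                   sort(transcriptTable(sim$A)$tx_id))
  pt <- compareTranscripts(A2, sim$A)
  expect_length(partitionKeys(pt, "uniqueA"), 0L)
  expect_length(partitionKeys(pt, "uniqueB"), 0L)
  v <- readVariants(sim$files$vcf)
  expect_equal(nrow(v), nrow(sim$variants))
  tr <- readCoverageTrack(sim$files$tracks[1])
  expect_true(all(tr$score >= 0))
  unlink(d, recursive = TRUE)
})
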