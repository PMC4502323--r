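# Minimal consequence caller: severity ranking, broad classes, window
# logic, codon effects and dataset-level behaviour.

# deterministic toy chromosome with a 3-exon coding transcript
toyGene <- function(strand = "+") {
  seq <- randomChrom(800, seed = 42)
  exS <- c(101L, 321L, 541L); exE <- c(220L, 440L, 660L)
  cdS <- c(131L, 321L, 541L); cdE <- c(220L, 440L, 600L)  # 90+120+60 = 270
  list(seq = seq, exS = exS, exE = exE, cdS = cdS, cdE = cdE,
       strand = strand,
       exons = GenomicRanges::GRanges("chr1", IRanges::IRanges(exS, exE),
                                      strand = strand),
       cds = GenomicRanges::GRanges("chr1", IRanges::IRanges(cdS, cdE),
                                    strand = strand),
       genome = Biostrings::DNAStringSet(c(chr1 = seq)))
}

test_that("severity ranking selects the most severe call", {
  expect_equal(mostSevere(c("synonymous", "missense")), "missense")
  expect_equal(mostSevere("utr3"), "utr3")
  expect_equal(mostSevere(c("splice_region", "stop_gained")), "stop_gained")
  expect_error(mostSevere(character(0)), "non-empty")
  expect_error(mostSevere("nonsense_term"), "unknown")
})

test_that("every term maps to exactly one broad class", {
  terms <- consequenceTerms()
  cls <- broadClass(terms)
  expect_false(anyNA(cls))
  expect_setequal(unique(cls), c("LoF", "CDS", "splice", "other"))
  expect_equal(broadClass("stop_gained"), "LoF")
  expect_equal(broadClass("synonymous"), "CDS")
  expect_equal(broadClass("utr5"), "other")
  expect_equal(broadClass("splice_region"), "splice")
  expect_error(broadClass("bogus"), "unknown")
})

test_that("codon-level SNV effects follow the genetic code", {
  g <- toyGene()
  # plant a known codon at the start of the CDS: ATG GCA ... TCA(stop-able)
  seq <- g$seq
  substr(seq, 131, 139) <- "ATGGCAAAA"
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  cl <- function(pos, ref, alt)
    annotateVariantTranscript("chr1", pos, ref, alt, g$exons, g$cds, "+",
                              character(0), genome)
  # third base of AAA codon: AAA -> AAG is Lys -> Lys
  expect_equal(cl(139, "A", "G"), "synonymous")
  # AAA -> ACA missense
  expect_equal(cl(138, "A", "C"), "missense")
  # GCA -> GTA missense (middle codon)
  expect_equal(cl(135, "C", "T"), "missense")
  # start codon ATG -> ATA
  expect_equal(cl(133, "G", "A"), "start_lost")
  # create in-frame TAA: AAA (codon 3) -> TAA via first base
  expect_equal(cl(137, "A", "T"), "stop_gained")
})

test_that("indels in CDS are frameshift or in-frame by length change", {
  g <- toyGene()
  cl <- function(pos, ref, alt)
    annotateVariantTranscript("chr1", pos, ref, alt, g$exons, g$cds, "+",
                              character(0), g$genome)
  ref2 <- substr(g$seq, 150, 151)
  expect_equal(cl(150, ref2, substr(ref2, 1, 1)), "frameshift")
  ref4 <- substr(g$seq, 150, 153)
  expect_equal(cl(150, ref4, substr(ref4, 1, 1)), "inframe_indel")
  # insertion of 3 bases
  expect_equal(cl(150, substr(g$seq, 150, 150),
                  paste0(substr(g$seq, 150, 150), "CCC")), "inframe_indel")
})

test_that("splice windows have the documented widths", {
  g <- toyGene()
  cl <- function(pos) {
    alt <- setdiff(c("A", "C", "G", "T"),
                   substr(g$seq, pos, pos))[1]
    annotateVariantTranscript("chr1", pos, substr(g$seq, pos, pos), alt,
                              g$exons, g$cds, "+", character(0), g$genome)
  }
  # intron 1 runs 221..320 on the plus strand
  expect_equal(cl(221), "splice_donor")
  expect_equal(cl(222), "splice_donor")
  expect_equal(cl(223), "splice_region")
  expect_equal(cl(228), "splice_region")
  expect_length(cl(229), 0L)          # deep intron
  expect_length(cl(280), 0L)
  expect_length(cl(312), 0L)          # 9 bp from the acceptor
  expect_equal(cl(313), "splice_region")
  expect_equal(cl(318), "splice_region")
  expect_equal(cl(319), "splice_acceptor")
  expect_equal(cl(320), "splice_acceptor")
  # exonic 1-3 bp from the junction: coding term plus splice_region
  expect_true("splice_region" %in% cl(220))
  expect_true("splice_region" %in% cl(218))
  expect_false("splice_region" %in% cl(217))
})

test_that("UTR and non-coding assignments respect the coding strand", {
  g <- toyGene()
  cl <- function(pos, strand, cds = g$cds, tags = character(0)) {
    exons <- g$exons; BiocGenerics::strand(exons) <- strand
    if (length(cds)) BiocGenerics::strand(cds) <- strand
    alt <- setdiff(c("A", "C", "G", "T"), substr(g$seq, pos, pos))[1]
    annotateVariantTranscript("chr1", pos, substr(g$seq, pos, pos), alt,
                              exons, cds, strand, tags, g$genome)
  }
  expect_equal(cl(110, "+"), "utr5")
  expect_equal(cl(640, "+"), "utr3")
  expect_equal(cl(110, "-"), "utr3")
  expect_equal(cl(640, "-"), "utr5")
  # no CDS at all: non-coding exon
  noCds <- GenomicRanges::GRanges()
  expect_equal(cl(400, "+", cds = noCds), "noncoding_exon")
  # unanchored reading frame
  expect_equal(cl(400, "+", tags = "CDS_start_NF"),
               "coding_sequence_ambiguous")
})

test_that("dataset annotation omits non-mapping variants and flags mismatches", {
  sim <- sharedSim()
  tr <- sim$truth$variants
  ann <- sharedAnn()$A
  md <- S4Vectors::metadata(ann)
  # intergenic and deep-intron plants never map; utr-extension plants map
  # only to B
  nAbsentA <- sum(is.na(tr$expected_term_A))
  expect_equal(md$n_omitted, nAbsentA)
  expect_equal(nrow(md$mismatches), 0L)

  # a wrong reference allele is reported and the variant skipped
  v <- sim$variants[1, , drop = FALSE]
  trueRef <- v$ref
  v$ref <- setdiff(c("A", "C", "G", "T"), c(trueRef, v$alt))[1]
  ann2 <- annotateVariants(v, sim$A, sim$genome)
  expect_equal(nrow(ann2), 0L)
  expect_equal(nrow(S4Vectors::metadata(ann2)$mismatches), 1L)

  # contigs absent from the geneset are counted
  v2 <- data.frame(chrom = "chrZ", pos = 100L, ref = "A", alt = "C")
  ann3 <- annotateVariants(v2, sim$A, sim$genome)
  expect_equal(S4Vectors::metadata(ann3)$n_no_contig, 1L)
})

test_that("annotation is deterministic", {
  sim <- sharedSim()
  v <- sim$variants[1:40, ]
  a1 <- annotateVariants(v, sim$A, sim$genome)
  a2 <- annotateVariants(v, sim$A, sim$genome)
  expect_identical(as.data.frame(a1[, setdiff(colnames(a1),
                                              c("terms", "txIds"))]),
                   as.data.frame(a2[, setdiff(colnames(a2),
                                              c("terms", "txIds"))]))
  expect_identical(as.list(a1$terms), as.list(a2$terms))
})

test_that("reverse-complementing the locus preserves the term multiset", {
  g <- toyGene()
  L <- nchar(g$seq)
  rcSeq <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(g$seq)))
  flip <- function(x) L - x + 1L
  exons2 <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(rev(flip(g$exE)), rev(flip(g$exS))),
    strand = "-")
  cds2 <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(rev(flip(g$cdE)), rev(flip(g$cdS))),
    strand = "-")
  genome2 <- Biostrings::DNAStringSet(c(chr1 = rcSeq))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (pos in seq(95, 670, by = 7)) {
    ref <- substr(g$seq, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      t1 <- annotateVariantTranscript("chr1", pos, ref, alt, g$exons,
                                      g$cds, "+", character(0), g$genome)
      t2 <- annotateVariantTranscript("chr1", flip(pos), comp[[ref]],
                                      comp[[alt]], exons2, cds2, "-",
                                      character(0), genome2)
      expect_identical(sort(t1), sort(t2))
    }
  }
})
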