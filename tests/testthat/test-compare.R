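# Equivalence keys, non-redundant exon sets, partitions, coverage and
# per-locus statistics.

test_that("transcript keys use exon coords (single-exon) or intron chains", {
  gs <- makeGeneset(list(
    tx("S1", c(100, 200)),                       # single exon
    tx("M1", c(100, 200, 301, 400), cds = c(150, 200)),
    tx("M2", c(50, 200, 301, 450), cds = c(150, 200)),   # UTR-length diffs
    tx("M3", c(100, 200, 311, 400), cds = c(150, 200))), # shifted acceptor
    chromSizes = c(chr1 = 1000L))
  k <- transcriptKeys(gs)
  expect_match(k[["S1"]], "SE")
  expect_identical(k[["M1"]], k[["M2"]])
  expect_false(identical(k[["M1"]], k[["M3"]]))
})

test_that("translation keys use CDS coords verbatim and skip non-coding", {
  gs <- makeGeneset(list(
    tx("P1", c(100, 400), biotype = "processed_transcript"),
    tx("C1", c(100, 200, 301, 400), cds = c(150, 200, 301, 350)),
    tx("C2", c(50, 200, 301, 450), cds = c(150, 200, 301, 350)),
    tx("C3", c(100, 200, 301, 400), cds = c(150, 200, 301, 353))))
  k <- translationKeys(gs)
  expect_true(is.na(k[["P1"]]))
  expect_identical(k[["C1"]], k[["C2"]])
  expect_false(identical(k[["C1"]], k[["C3"]]))
})

test_that("unique exon set applies the terminal and internal junction rules", {
  # two terminal first exons sharing the donor at 200: longer retained
  gs <- makeGeneset(list(
    tx("T1", c(100, 200, 301, 400), cds = c(150, 200)),
    tx("T2", c(50, 200, 301, 400), cds = c(150, 200))))
  ue <- uniqueExonSet(gs)
  df <- data.frame(start = BiocGenerics::start(ue),
                   end = BiocGenerics::end(ue))
  expect_true(any(df$start == 50 & df$end == 200))
  expect_false(any(df$start == 100 & df$end == 200))

  # internal exons overlapping with different junctions: both retained
  gs2 <- makeGeneset(list(
    tx("T1", c(1, 50, 100, 200, 301, 400), cds = c(120, 200)),
    tx("T2", c(1, 50, 100, 210, 301, 400), cds = c(120, 200))))
  ue2 <- uniqueExonSet(gs2)
  ends <- BiocGenerics::end(ue2)[BiocGenerics::start(ue2) == 100]
  expect_setequal(ends, c(200L, 210L))
})

test_that("unique exon set matches the brute-force oracle on planted fixtures", {
  for (seed in 1:6) {
    txl <- randomTxList(nTx = 15, seed = seed)
    gs <- makeGeneset(lapply(seq_along(txl), function(i)
      tx(sprintf("T%02d", i),
         as.vector(t(cbind(txl[[i]]$starts, txl[[i]]$ends))),
         tags = "CDS_start_NF")))
    ue <- uniqueExonSet(gs)
    got <- sort(paste("chr1", "+", BiocGenerics::start(ue),
                      BiocGenerics::end(ue), sep = "|"))
    oracle <- bruteForceUniqueExons(txl)
    expect_identical(got, sort(oracle$key[oracle$kept]))
  }
})

test_that("partitions are identity-stable, disjoint-aware and symmetric", {
  sim <- sharedSim()
  A <- sim$A
  pAA <- compareTranscripts(A, A)
  expect_length(partitionKeys(pAA, "uniqueA"), 0L)
  expect_length(partitionKeys(pAA, "uniqueB"), 0L)

  # disjoint chromosomes share nothing
  g1 <- makeGeneset(list(tx("T1", c(100, 200, 301, 400), cds = c(150, 200))))
  g2 <- makeGeneset(list(tx("T2", c(100, 200, 301, 400), cds = c(150, 200),
                            chrom = "chr2")))
  expect_length(partitionKeys(compareTranscripts(g1, g2), "shared"), 0L)

  # symmetry with sides swapped
  pAB <- compareTranscripts(sim$A, sim$B)
  pBA <- compareTranscripts(sim$B, sim$A)
  expect_identical(partitionKeys(pAB, "shared"), partitionKeys(pBA, "shared"))
  expect_identical(partitionKeys(pAB, "uniqueA"),
                   partitionKeys(pBA, "uniqueB"))
  pe <- compareExons(sim$A, sim$B)
  pe2 <- compareExons(sim$B, sim$A)
  expect_identical(partitionKeys(pe, "uniqueA"), partitionKeys(pe2, "uniqueB"))
  expect_identical(partitionKeys(pe, "shared"), partitionKeys(pe2, "shared"))
})

test_that("conservation: shared + unique equals the side's distinct keys", {
  sim <- sharedSim()
  for (p in list(compareTranscripts(sim$A, sim$B),
                 compareTranslations(sim$A, sim$B))) {
    cnt <- partitionCounts(p)
    kA <- switch(p@kind,
                 transcript = transcriptKeys(sim$A),
                 translation = translationKeys(sim$A))
    kA <- kA[!is.na(kA)]
    expect_equal(unname(cnt["shared"] + cnt["unique_A"]),
                 length(unique(kA)))
  }
})

test_that("filtering a geneset leaves nothing unique to the subset side", {
  sim <- sharedSim()
  bas <- applySubsetRule(sim$A, "basic")
  for (p in list(compareTranscripts(sim$A, bas),
                 compareTranslations(sim$A, bas),
                 compareExons(sim$A, bas)))
    expect_length(partitionKeys(p, "uniqueB"), 0L)
})

test_that("UTR-only perturbation changes no transcript or translation keys", {
  sim <- sharedSim()
  A <- sim$A
  ex <- exonRanges(A)
  perturbed <- lapply(seq_along(ex), function(i) {
    e <- ex[[i]]
    if (length(e) > 1L) {
      BiocGenerics::start(e)[1] <- BiocGenerics::start(e)[1] - 7L
      BiocGenerics::end(e)[length(e)] <- BiocGenerics::end(e)[length(e)] + 5L
    }
    e
  })
  pex <- GenomicRanges::GRangesList(perturbed)
  names(pex) <- names(ex)
  A2 <- Geneset("A2", pex, cdsRanges(A), transcriptTable(A),
                chromSizes = chromSizes(A))
  pt <- compareTranscripts(A, A2)
  expect_length(partitionKeys(pt, "uniqueA"), 0L)
  expect_length(partitionKeys(pt, "uniqueB"), 0L)
  pl <- compareTranslations(A, A2)
  expect_length(partitionKeys(pl, "uniqueA"), 0L)
  expect_length(partitionKeys(pl, "uniqueB"), 0L)
})

test_that("coverage sums member lengths and merges overlaps per strand", {
  gs <- makeGeneset(list(
    tx("T1", c(101, 200), tags = "CDS_start_NF"),
    tx("T2", c(151, 250), tags = "CDS_start_NF")))
  ue <- uniqueExonSet(gs)
  cov <- genomicCoverage(ue, c(chr1 = 1000L))
  plus <- cov[cov$strand == "+", ]
  expect_equal(plus$summed_bp, 200)
  expect_equal(plus$merged_bp, 150)
  expect_equal(plus$percent_summed, 100 * 200 / 1000)

  empty <- makeGeneset(list(tx("T1", c(101, 200), tags = "CDS_start_NF")))
  ue0 <- uniqueExonSet(keepTranscripts(empty, character(0)))
  cov0 <- genomicCoverage(ue0, c(chr1 = 1000L))
  expect_true(all(cov0$summed_bp == 0) && all(cov0$percent_summed == 0))

  expect_error(genomicCoverage(ue, c(chr2 = 500L)), "absent from sizes")
})

test_that("merged coverage equals a per-base bitmap oracle", {
  set.seed(3)
  n <- 100
  st <- sample(1:5000, n); en <- st + sample(20:300, n, replace = TRUE)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st, en),
                               strand = "+")
  gr$key <- paste0("k", seq_len(n))
  cov <- genomicCoverage(gr, c(chr1 = 10000L))
  expect_equal(cov$merged_bp[cov$strand == "combined"],
               bitmapCoverage(st, en, rep("chr1", n), 10000L))
})

test_that("per-locus statistics average over multi-exon loci", {
  gs <- makeGeneset(list(
    tx("T1", c(100, 200, 301, 400), cds = c(150, 200), gene = "G1"),
    tx("T2", c(100, 200, 311, 400), cds = c(150, 200), gene = "G1"),
    tx("T3", c(100, 200, 321, 400), cds = c(150, 200, 321, 350),
       gene = "G1")))
  st <- perLocusStats(gs)
  expect_equal(st$mean_transcripts, 3)
  expect_equal(st$mean_translations, 2)
  expect_false(st$degenerate)

  single <- makeGeneset(list(tx("T1", c(100, 200), cds = c(120, 200))))
  st0 <- perLocusStats(single)
  expect_true(st0$degenerate)
  expect_equal(st0$mean_transcripts, 0)
})

test_that("planted per-locus counts are recovered from generator bookkeeping", {
  sim <- sharedSim()
  tt <- sim$truth$transcripts
  st <- perLocusStats(sim$A)
  # every gene is multi-exon by construction; expected mean = planted
  # distinct chains per gene on side A
  perGene <- tapply(tt$type %in% c("shared", "A"), tt$gene, sum)
  expect_equal(st$n_multiexon_loci, sum(perGene > 0))
  expect_equal(st$mean_transcripts, mean(perGene[perGene > 0]))
})
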