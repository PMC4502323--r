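# Annotation parsing, validation and IO round trips.

writeGtf <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}

test_that("GTF coordinates are read 1-based closed and widths match", {
  f <- writeGtf(c(
    'chr1\tsrc\tgene\t101\t400\t.\t+\t.\tgene_id "G1"; gene_type "protein_coding";',
    'chr1\tsrc\ttranscript\t101\t400\t.\t+\t.\tgene_id "G1"; transcript_id "T1"; transcript_type "protein_coding";',
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tsrc\tCDS\t131\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1";'))
  gs <- readGeneset(f, name = "x")
  e <- exonRanges(gs)[["T1"]]
  expect_equal(BiocGenerics::start(e), c(101L, 301L))
  expect_equal(BiocGenerics::end(e), c(200L, 400L))
  # internal width equals GTF end - start + 1
  expect_equal(BiocGenerics::width(e), c(200L - 101L + 1L, 400L - 301L + 1L))
  expect_equal(BiocGenerics::start(cdsRanges(gs)[["T1"]]), 131L)
  expect_equal(transcriptTable(gs)$locus_biotype, "coding")
})

test_that("empty GTF yields an empty geneset", {
  gs <- readGeneset(writeGtf(character(0)), name = "empty")
  expect_s4_class(gs, "Geneset")
  expect_equal(length(gs), 0L)
})

test_that("structural GTF problems raise errors naming the location", {
  f <- writeGtf(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "G1";'))
  expect_error(readGeneset(f), "line 2")
  f2 <- writeGtf('chr1\tsrc\texon\t101\t200\t.\t+')
  expect_error(readGeneset(f2), "line 1")
  f3 <- writeGtf(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tsrc\tCDS\t501\t600\t.\t+\t.\tgene_id "G1"; transcript_id "T1";'))
  expect_error(readGeneset(f3), "T1")
})

test_that("repeated and comma-joined tag attributes are both collected", {
  f <- writeGtf(c(
    'chr1\tsrc\ttranscript\t101\t400\t.\t+\t.\tgene_id "G1"; transcript_id "T1"; tag "basic"; tag "CDS_end_NF";',
    'chr1\tsrc\texon\t101\t400\t.\t+\t.\tgene_id "G1"; transcript_id "T1"; tag "mRNA_end_NF";',
    'chr1\tsrc\ttranscript\t501\t900\t.\t+\t.\tgene_id "G1"; transcript_id "T2"; tag "basic,CDS_start_NF";',
    'chr1\tsrc\texon\t501\t900\t.\t+\t.\tgene_id "G1"; transcript_id "T2";'))
  gs <- readGeneset(f)
  td <- transcriptTable(gs)
  expect_setequal(td$tags[[match("T1", td$tx_id)]],
                  c("basic", "CDS_end_NF", "mRNA_end_NF"))
  expect_setequal(td$tags[[match("T2", td$tx_id)]],
                  c("basic", "CDS_start_NF"))
})

test_that("biotype synonyms are normalised and accession classes inferred", {
  f <- writeGtf(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "NM_001"; gene_biotype "protein_coding"; transcript_biotype "nonsense_mediated_decay";',
    'chr1\tsrc\texon\t501\t600\t.\t+\t.\tgene_id "G2"; transcript_id "XR_9"; gene_biotype "transcribed_pseudogene"; transcript_biotype "weird";'))
  td <- transcriptTable(readGeneset(f))
  expect_equal(td$biotype[match("NM_001", td$tx_id)], "NMD")
  expect_equal(td$accession_class[match(c("NM_001", "XR_9"), td$tx_id)],
               c("NM", "XR"))
  expect_equal(td$locus_biotype[match("XR_9", td$tx_id)], "pseudogene")
  expect_equal(td$biotype[match("XR_9", td$tx_id)], "other")
})

test_that("geneset GTF round trip preserves structure and metadata", {
  gs <- makeGeneset(list(
    tx("T1", c(101, 200, 301, 400), cds = c(131, 200, 301, 340),
       gene = "G1", tags = c("basic")),
    tx("NR_07", c(1001, 1200), gene = "G2", biotype = "processed_transcript",
       strand = "-", locus = "misc_RNA")))
  f <- tempfile(fileext = ".gtf")
  writeGeneset(gs, f)
  gs2 <- readGeneset(f, name = genesetName(gs))
  expect_equal(as.list(exonRanges(gs2)), as.list(exonRanges(gs)))
  expect_equal(as.list(cdsRanges(gs2)), as.list(cdsRanges(gs)))
  td <- transcriptTable(gs); td2 <- transcriptTable(gs2)
  ord <- match(td$tx_id, td2$tx_id)
  expect_equal(td2$biotype[ord], td$biotype)
  expect_equal(td2$locus_biotype[ord], td$locus_biotype)
  expect_equal(td2$accession_class[ord], td$accession_class)
  expect_equal(lapply(td2$tags[ord], sort), lapply(td$tags, sort))
})

test_that("chromosome sizes files parse and reject bad input", {
  f <- tempfile(); writeLines("chr1\t1000", f)
  expect_equal(readChromSizes(f), c(chr1 = 1000L))
  writeLines(c("chr1 1000", "chr1 2000"), f)
  expect_error(readChromSizes(f), "duplicate")
  writeLines("chr1\tabc", f)
  expect_error(readChromSizes(f), "non-integer")
  writeLines(character(0), f)
  expect_equal(length(readChromSizes(f)), 0L)
})

test_that("validateGeneset reports violations as data", {
  good <- makeGeneset(list(tx("T1", c(101, 200, 301, 400),
                              cds = c(131, 200))),
                      chromSizes = c(chr1 = 1000L))
  expect_equal(validateGeneset(good), character(0))

  overlapping <- makeGeneset(list(tx("T1", c(101, 200, 150, 400),
                                     biotype = "other")))
  v <- validateGeneset(overlapping)
  expect_length(v, 1L)
  expect_match(v, "T1")
  expect_match(v, "overlap")

  beyond <- makeGeneset(list(tx("T1", c(101, 200), biotype = "other")),
                        chromSizes = c(chr1 = 150L))
  expect_match(validateGeneset(beyond), "beyond chromosome length")

  codingNoCds <- makeGeneset(list(tx("T1", c(101, 200))))
  expect_match(validateGeneset(codingNoCds), "without CDS")
  truncated <- makeGeneset(list(tx("T1", c(101, 200),
                                   tags = "CDS_start_NF")))
  expect_equal(validateGeneset(truncated), character(0))
})
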