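#' Parameters for the synthetic study generator
#'
#' Defines the shape of a fully synthetic annotation-comparison study:
#' paired genesets with controlled fractions of shared intron chains,
#' UTR-only differences, in-frame CDS shifts, unique exons with novel splice
#' junctions, truncated (start-not-found) transcripts and non-coding
#' transcript biotypes; variants stratified across CDS, splice, UTR,
#' non-coding-exon, deep-intron and intergenic positions; and per-sample
#' coverage tracks with a zero-inflated gamma expression model.  The seed
#' fully determines every output.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param nChroms,chromLength Genome shape (chromosomes of equal length).
#' @param nGenes Number of gene loci (non-overlapping, strand-alternating).
#' @param txPerGene Planned transcript chains per gene (2..11).
#' @param fracShared Fraction of chains planted with identical intron chains
#'   in both genesets.
#' @param fracUniqueA Fraction of chains unique to geneset A (the remainder
#'   after shared is unique to B).
#' @param fracUtrOnly Of shared chains, fraction whose B copy differs only
#'   in terminal-exon outer coordinates (longer UTRs).
#' @param fracCdsShift Of shared chains, fraction whose B copy uses an
#'   in-frame shifted CDS start (same intron chain, different translation).
#' @param nUniqueExonsPerSide Number of unique chains per side that carry a
#'   novel exon with at least one novel splice junction.
#' @param fracTruncated Of A-only chains, fraction tagged
#'   \code{CDS_start_NF}/\code{mRNA_start_NF} with an unanchored CDS.
#' @param fracNoncoding Of A-only chains, fraction given non-coding biotypes
#'   (cycling retained_intron, processed_transcript, NMD).
#' @param variantCounts Named integer vector of planted variant counts per
#'   category: \code{cds_synonymous}, \code{cds_missense},
#'   \code{cds_stopgain}, \code{splice_donor}, \code{utr5},
#'   \code{utr_extension}, \code{noncoding_exon}, \code{deep_intron},
#'   \code{intergenic}.
#' @param expression List: \code{shape}, \code{rate} (gamma density model,
#'   reads/bp), \code{zeroFraction} (probability a gene is silent in all
#'   samples), \code{intronFactor} (intron density relative to exons),
#'   \code{noiseSd} (sd of additive Gaussian noise per coverage block; 0
#'   disables noise).
#' @param nSamples Number of coverage tracks (samples).
#' @return List of class \code{SimParams}.
#' @export
simParams <- function(seed = 1L, nChroms = 1L, chromLength = 1e6,
                      nGenes = 100L, txPerGene = 2L,
                      fracShared = 0.7, fracUniqueA = 0.2,
                      fracUtrOnly = 0.3, fracCdsShift = 0.2,
                      nUniqueExonsPerSide = 10L,
                      fracTruncated = 0.1, fracNoncoding = 0.2,
                      variantCounts = c(cds_synonymous = 40,
                                        cds_missense = 40,
                                        cds_stopgain = 20,
                                        splice_donor = 20, utr5 = 30,
                                        utr_extension = 30,
                                        noncoding_exon = 15,
                                        deep_intron = 20, intergenic = 10),
                      expression = list(shape = 2, rate = 0.5,
                                        zeroFraction = 0.25,
                                        intronFactor = 0.1, noiseSd = 0),
                      nSamples = 18L) {
  p <- list(seed = as.integer(seed), nChroms = as.integer(nChroms),
            chromLength = as.integer(chromLength),
            nGenes = as.integer(nGenes), txPerGene = as.integer(txPerGene),
            fracShared = fracShared, fracUniqueA = fracUniqueA,
            fracUtrOnly = fracUtrOnly, fracCdsShift = fracCdsShift,
            nUniqueExonsPerSide = as.integer(nUniqueExonsPerSide),
            fracTruncated = fracTruncated, fracNoncoding = fracNoncoding,
            variantCounts = variantCounts, expression = expression,
            nSamples = as.integer(nSamples))
  stopifnot(p$txPerGene >= 1L, p$txPerGene <= 11L,
            p$fracShared >= 0, p$fracUniqueA >= 0,
            p$fracShared + p$fracUniqueA <= 1,
            all(unlist(p[c("fracUtrOnly", "fracCdsShift", "fracTruncated",
                           "fracNoncoding")]) >= 0),
            p$expression$zeroFraction >= 0, p$expression$zeroFraction <= 1,
            p$nSamples >= 1L)
  class(p) <- "SimParams"
  p
}

## gene anatomy constants: 6 exon slots of 150 bp, 250 bp introns, 3 kb gene
## pitch, 30 bp maximum terminal UTR extension, 30 bp 5'UTR / 27 bp 3'UTR
.SLOT_N <- 6L; .EXON_W <- 150L; .PITCH <- 400L; .GENE_PITCH <- 3000L
.FIRST_ORIGIN <- 301L
.UTR5 <- 30L; .UTR3 <- 27L; .UTR_EXT <- 30L

## subsets of internal slots, largest chains first; every chain keeps the
## outermost slots so that all transcripts share the terminal exon slots
.chainSubsets <- function() {
  inner <- list(c(2L, 3L, 4L, 5L), c(2L, 3L, 4L), c(2L, 3L, 5L),
                c(2L, 4L, 5L), c(3L, 4L, 5L), c(2L, 3L), c(2L, 4L),
                c(2L, 5L), c(3L, 4L), c(3L, 5L), c(4L, 5L))
  lapply(inner, function(x) c(1L, x, .SLOT_N))
}

## transcript-space -> genomic mapping over an exon chain (generator-side
## arithmetic, independent of the analysis modules)
.txToGenomic <- function(st, en, strand, a, b) {
  w <- en - st + 1L
  if (strand == "-") { st <- rev(st); en <- rev(en); w <- rev(w) }
  cum <- cumsum(w)
  lo <- c(0L, cum[-length(cum)])
  out <- NULL
  for (i in seq_along(w)) {
    qa <- max(a, lo[i] + 1L); qb <- min(b, cum[i])
    if (qa > qb) next
    if (strand == "+") {
      gs <- st[i] + (qa - lo[i] - 1L); ge <- st[i] + (qb - lo[i] - 1L)
    } else {
      ge <- en[i] - (qa - lo[i] - 1L); gs <- en[i] - (qb - lo[i] - 1L)
    }
    out <- rbind(out, c(gs, ge))
  }
  out[order(out[, 1]), , drop = FALSE]
}

## single transcript-space position -> genomic position
.txPos <- function(st, en, strand, q) {
  m <- .txToGenomic(st, en, strand, q, q)
  m[1, 1]
}

.rc <- function(s) chartr("ACGT", "TGCA",
                          paste(rev(strsplit(s, "")[[1]]), collapse = ""))

## write a transcript-oriented sequence into the genome string
.writeTxSeq <- function(seqs, chrom, strand, gpos, txt) {
  n <- nchar(txt)
  if (strand == "+") {
    substr(seqs[[chrom]], gpos, gpos + n - 1L) <- txt
  } else {
    substr(seqs[[chrom]], gpos - n + 1L, gpos) <- .rc(txt)
  }
  seqs
}

#' Generate a synthetic genome
#'
#' Uniform-random ACGT sequence (no ambiguity codes), reproducible from the
#' seed.
#'
#' @param p \code{SimParams}.
#' @return List with \code{seq} (named character vector, one string per
#'   chromosome) and \code{sizes} (named integer lengths).
#' @export
simulateGenome <- function(p) {
  set.seed(p$seed)
  chroms <- paste0("chr", seq_len(p$nChroms))
  seqs <- vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), p$chromLength, replace = TRUE),
          collapse = ""), "")
  list(seq = seqs, sizes = setNames(rep(p$chromLength, p$nChroms), chroms))
}

## key builders shared with the analysis modules' string format; the
## coordinates fed in come from generator arithmetic only
.icKey <- function(chrom, strand, intronStarts, intronEnds) {
  paste0(chrom, "|", strand, "|IC|",
         paste(intronStarts, intronEnds, sep = "-", collapse = ","))
}
.cdsKey <- function(chrom, strand, m) {
  paste0(chrom, "|", strand, "|CDS|",
         paste(m[, 1], m[, 2], sep = "-", collapse = ","))
}
.exKey <- function(chrom, strand, start, end) {
  paste(chrom, strand, start, end, sep = "|")
}

#' Generate a paired annotation with ground truth
#'
#' Builds two genesets over the synthetic genome with planted relations:
#' shared intron chains (optionally UTR-extended or CDS-shifted on the B
#' side), chains unique to one side (optionally carrying a novel exon,
#' truncation tags, or non-coding biotypes on the A side), canonical GT/AG
#' dinucleotides under every standard intron, and valid ORFs (ATG start,
#' in-frame terminal stop, no internal stop) for every anchored CDS.  The
#' returned ground truth enumerates every planted relation.
#'
#' @param p \code{SimParams}.
#' @param genome Output of [simulateGenome()].
#' @return List: \code{A}, \code{B} (\code{Geneset}s), \code{genomeSeq}
#'   (genome with gene sequences written in), \code{truth}.
#' @export
simulateGenesetPair <- function(p, genome) {
  set.seed(p$seed + 1L)
  perChrom <- (p$chromLength - 2L * .FIRST_ORIGIN) %/% .GENE_PITCH
  if (p$nGenes > perChrom * p$nChroms)
    stop("generation error: ", p$nGenes, " genes do not fit a genome of ",
         p$nChroms, " x ", p$chromLength, " bp")
  chroms <- names(genome$sizes)
  seqs <- genome$seq

  ## --- gene scaffold ---------------------------------------------------
  gidx <- seq_len(p$nGenes)
  geneChrom <- chroms[((gidx - 1L) %/% perChrom) + 1L]
  geneOff <- ((gidx - 1L) %% perChrom)
  origin <- .FIRST_ORIGIN + geneOff * .GENE_PITCH
  geneStrand <- ifelse(gidx %% 2L == 1L, "+", "-")
  slotStart <- outer(origin, (seq_len(.SLOT_N) - 1L) * .PITCH, `+`)
  slotEnd <- slotStart + .EXON_W - 1L

  ## --- chain plans ------------------------------------------------------
  total <- p$nGenes * p$txPerGene
  nShared <- round(p$fracShared * total)
  nA <- round(p$fracUniqueA * total)
  nB <- total - nShared - nA
  type <- sample(c(rep("shared", nShared), rep("A", nA), rep("B", nB)))
  gene <- rep(gidx, p$txPerGene)
  ordinal <- rep(seq_len(p$txPerGene), each = p$nGenes)

  flavor <- rep("plain", total)
  sh <- which(type == "shared")
  nUtr <- round(p$fracUtrOnly * length(sh))
  nCds <- round(p$fracCdsShift * length(sh))
  flavor[sh[seq_len(nUtr)]] <- "utr"
  flavor[sh[nUtr + seq_len(min(nCds, length(sh) - nUtr))]] <- "cdsshift"
  ai <- which(type == "A")
  nTr <- round(p$fracTruncated * length(ai))
  nNc <- round(p$fracNoncoding * length(ai))
  flavor[ai[seq_len(nTr)]] <- "trunc"
  ncFlavors <- c("retained_intron", "processed_transcript", "NMD")
  ncIdx <- ai[nTr + seq_len(min(nNc, length(ai) - nTr))]
  flavor[ncIdx] <- rep(ncFlavors, length.out = length(ncIdx))
  rest <- ai[flavor[ai] == "plain"]
  flavor[rest[seq_len(min(p$nUniqueExonsPerSide, length(rest)))]] <- "novel"
  bi <- which(type == "B")
  flavor[bi[seq_len(min(p$nUniqueExonsPerSide, length(bi)))]] <- "novel"
  # at most one retained-intron chain per gene (their structure is gene-wide)
  for (g in gidx) {
    ri <- which(gene == g & flavor == "retained_intron")
    if (length(ri) > 1L)
      flavor[ri[-1]] <- "processed_transcript"
  }

  subsets <- .chainSubsets()

  ## --- per-chain structure ---------------------------------------------
  chain <- vector("list", total)
  for (i in seq_len(total)) {
    g <- gene[i]
    slots <- subsets[[ordinal[i]]]
    st <- slotStart[g, slots]; en <- slotEnd[g, slots]
    shift <- 0L
    if (flavor[i] == "novel") {
      shift <- 6L + 3L * ((ordinal[i] - 1L) %% 8L)
      en[2L] <- en[2L] - shift    # novel donor junction on the 2nd exon
    }
    retained <- FALSE
    if (flavor[i] == "retained_intron") {
      slots <- seq_len(.SLOT_N)
      st <- slotStart[g, slots]; en <- slotEnd[g, slots]
      st <- c(st[1L], st[2L], st[4L:.SLOT_N])
      en <- c(en[1L], en[3L], en[4L:.SLOT_N])   # slots 2+3 merged
      retained <- TRUE
    }
    chain[[i]] <- list(idx = i, gene = g, type = type[i],
                       flavor = flavor[i], slots = slots,
                       st = st, en = en, shift = shift,
                       retained = retained,
                       chrom = geneChrom[g], strand = geneStrand[g])
  }

  ## --- sequence writing -------------------------------------------------
  for (g in gidx) {
    a <- origin[g] - .UTR_EXT - 5L
    b <- origin[g] + (.SLOT_N - 1L) * .PITCH + .EXON_W + .UTR_EXT + 5L
    substr(seqs[[geneChrom[g]]], a, b) <-
      paste(sample(c("A", "C", "G"), b - a + 1L, replace = TRUE),
            collapse = "")
    # canonical splice dinucleotides under every standard intron
    for (j in seq_len(.SLOT_N - 1L)) {
      is <- slotEnd[g, j] + 1L; ie <- slotStart[g, j + 1L] - 1L
      if (geneStrand[g] == "+") {
        substr(seqs[[geneChrom[g]]], is, is + 1L) <- "GT"
        substr(seqs[[geneChrom[g]]], ie - 1L, ie) <- "AG"
      } else {
        substr(seqs[[geneChrom[g]]], is, is + 1L) <- "CT"
        substr(seqs[[geneChrom[g]]], ie - 1L, ie) <- "AC"
      }
    }
  }

  ## anchors in transcript space (0-based offsets within the first exon)
  anchorOf <- function(fl, side)
    if (fl == "trunc") 0L else if (fl == "cdsshift" && side == "B") 42L
    else 30L

  # write ATG at every used anchor and the gene-common terminal stop
  for (g in gidx) {
    ch <- geneChrom[g]; strd <- geneStrand[g]
    stAll <- slotStart[g, ]; enAll <- slotEnd[g, ]
    usedAnchors <- integer(0)
    hasCoding <- FALSE
    for (cc in chain[seq_len(total)]) {
      if (cc$gene != g) next
      fl <- cc$flavor
      coding <- !fl %in% c("retained_intron", "processed_transcript")
      if (!coding) next
      hasCoding <- TRUE
      if (fl != "trunc") {
        usedAnchors <- union(usedAnchors, 30L)
        if (fl == "cdsshift") usedAnchors <- union(usedAnchors, 42L)
      }
    }
    for (anc in usedAnchors) {
      gp <- .txPos(stAll, enAll, strd, anc + 1L)
      seqs <- .writeTxSeq(seqs, ch, strd, gp, "ATG")
    }
    if (hasCoding) {
      # terminal stop: last 27 bases of every chain are 3'UTR; the stop
      # codon sits at a fixed genomic spot in the outermost slot
      if (strd == "+") {
        sp <- slotEnd[g, .SLOT_N] - .UTR3 - 2L
        substr(seqs[[ch]], sp, sp + 2L) <- "TAA"
      } else {
        # stop codon occupies genomic [start+27, start+29] of the outermost
        # slot; its transcript-first base is the genomically highest one
        sp <- slotStart[g, 1L] + .UTR3 + 2L
        seqs <- .writeTxSeq(seqs, ch, strd, sp, "TAA")
      }
    }
  }

  ## --- assemble genesets and ground truth -------------------------------
  mkIntrons <- function(st, en) {
    k <- length(st)
    list(s = en[-k] + 1L, e = st[-1] - 1L)
  }

  rowsA <- list(); rowsB <- list()
  truthTx <- list()
  exUsage <- list()  # per-side exon coordinate usage for expected partition
  addExons <- function(side, cc, st, en) {
    k <- length(st)
    for (j in seq_len(k)) {
      key <- .exKey(cc$chrom, cc$strand, st[j], en[j])
      ent <- exUsage[[key]]
      if (is.null(ent))
        ent <- list(chrom = cc$chrom, strand = cc$strand, start = st[j],
                    end = en[j], A = FALSE, B = FALSE,
                    startJ = FALSE, endJ = FALSE)
      ent[[side]] <- TRUE
      if (j > 1L) ent$startJ <- TRUE
      if (j < k) ent$endJ <- TRUE
      exUsage[[key]] <<- ent
    }
  }

  txCounter <- 0L
  for (i in seq_len(total)) {
    cc <- chain[[i]]
    fl <- cc$flavor
    g <- cc$gene
    icv <- mkIntrons(cc$st, cc$en)
    chainKey <- .icKey(cc$chrom, cc$strand, icv$s, icv$e)
    coding <- !fl %in% c("retained_intron", "processed_transcript")
    L <- sum(cc$en - cc$st + 1L)

    cdsOf <- function(anchor, st, en)
      .txToGenomic(st, en, cc$strand, anchor + 1L, L - .UTR3)

    sides <- switch(cc$type, shared = c("A", "B"), A = "A", B = "B")
    keyA <- keyB <- NA_character_
    txA <- txB <- NA_character_
    for (side in sides) {
      txCounter <- txCounter + 1L
      st <- cc$st; en <- cc$en
      if (side == "B" && fl == "utr") {
        st[1L] <- st[1L] - .UTR_EXT
        en[length(en)] <- en[length(en)] + .UTR_EXT
      }
      anchor <- anchorOf(fl, side)
      cdsM <- if (coding) cdsOf(anchor, cc$st, cc$en) else NULL
      biotype <- if (fl %in% ncFlavors && fl != "NMD") fl
                 else if (fl == "NMD") "NMD" else "protein_coding"
      tags <- character(0)
      if (fl == "trunc") tags <- c("CDS_start_NF", "mRNA_start_NF")
      if (biotype == "protein_coding" && fl != "trunc")
        tags <- c(tags, "basic")
      if (side == "A") {
        txId <- sprintf("TXA%05d", i)
        geneId <- sprintf("GA%04d", g)
      } else {
        pre <- if (fl == "novel" && cc$type == "B") "XM" else "NM"
        txId <- sprintf("%s_%06d", pre, i)
        geneId <- sprintf("GB%04d", g)
      }
      gr <- GenomicRanges::GRanges(cc$chrom, IRanges::IRanges(st, en),
                                   strand = cc$strand)
      cdsGr <- if (!is.null(cdsM))
        GenomicRanges::GRanges(cc$chrom,
                               IRanges::IRanges(cdsM[, 1], cdsM[, 2]),
                               strand = cc$strand)
        else GenomicRanges::GRanges()
      row <- list(tx_id = txId, gene_id = geneId, biotype = biotype,
                  tags = tags, exons = gr, cds = cdsGr)
      if (side == "A") { rowsA[[length(rowsA) + 1L]] <- row; txA <- txId }
      else { rowsB[[length(rowsB) + 1L]] <- row; txB <- txId }
      key <- if (!is.null(cdsM)) .cdsKey(cc$chrom, cc$strand, cdsM)
             else NA_character_
      if (side == "A") keyA <- key else keyB <- key
      addExons(side, cc, st, en)
    }
    truthTx[[i]] <- data.frame(
      chain = i, gene = g, type = cc$type, flavor = fl,
      chain_key = chainKey, cds_key_A = keyA, cds_key_B = keyB,
      tx_A = txA, tx_B = txB, stringsAsFactors = FALSE)
  }
  truthTx <- do.call(rbind, truthTx)

  buildGeneset <- function(rows, name) {
    if (!length(rows)) {
      return(Geneset(name,
                     GenomicRanges::GRangesList(
                       setNames(list(), character(0))),
                     chromSizes = genome$sizes, assembly = "synthetic"))
    }
    ex <- GenomicRanges::GRangesList(lapply(rows, `[[`, "exons"))
    names(ex) <- vapply(rows, `[[`, "", "tx_id")
    cd <- GenomicRanges::GRangesList(lapply(rows, `[[`, "cds"))
    names(cd) <- names(ex)
    td <- S4Vectors::DataFrame(
      tx_id = names(ex),
      gene_id = vapply(rows, `[[`, "", "gene_id"),
      biotype = vapply(rows, `[[`, "", "biotype"),
      accession_class = .accessionClass(names(ex)),
      tags = IRanges::CharacterList(lapply(rows, `[[`, "tags")),
      locus_biotype = "coding")
    Geneset(name, ex, cd, td, assembly = "synthetic",
            chromSizes = genome$sizes)
  }
  A <- buildGeneset(rowsA, "A")
  B <- buildGeneset(rowsB, "B")

  ## expected partitions -------------------------------------------------
  expTx <- list(
    shared = sort(unique(truthTx$chain_key[truthTx$type == "shared"])),
    uniqueA = sort(unique(truthTx$chain_key[truthTx$type == "A"])),
    uniqueB = sort(unique(truthTx$chain_key[truthTx$type == "B"])))
  ka <- truthTx$cds_key_A; kb <- truthTx$cds_key_B
  expTr <- list(
    shared = sort(unique(ka[!is.na(ka) & !is.na(kb) & ka == kb])),
    uniqueA = sort(unique(c(ka[!is.na(ka) & is.na(kb)],
                            ka[!is.na(ka) & !is.na(kb) & ka != kb]))),
    uniqueB = sort(unique(c(kb[!is.na(kb) & is.na(ka)],
                            kb[!is.na(kb) & !is.na(ka) & ka != kb]))))

  # exon partition from usage records: exact matches are shared; terminal
  # exons differing only in outer coordinates collapse onto the longest
  ue <- exUsage
  keys <- names(ue)
  # group pure-terminal exons by their single junction and collapse
  junctionOf <- function(e) {
    if (e$startJ && !e$endJ) paste(e$chrom, e$strand, "S", e$start)
    else if (e$endJ && !e$startJ) paste(e$chrom, e$strand, "E", e$end)
    else NA_character_
  }
  jk <- vapply(ue, junctionOf, "")
  keep <- rep(TRUE, length(ue))
  sideA <- vapply(ue, `[[`, NA, "A")
  sideB <- vapply(ue, `[[`, NA, "B")
  wdt <- vapply(ue, function(e) e$end - e$start + 1L, 0L)
  for (grp in split(seq_along(ue), jk)) {
    if (length(grp) < 2L) next
    best <- grp[which.max(wdt[grp])]
    drop <- setdiff(grp, best)
    keep[drop] <- FALSE
    sideA[best] <- any(sideA[grp]); sideB[best] <- any(sideB[grp])
  }
  expEx <- list(
    shared = sort(keys[keep & sideA & sideB]),
    uniqueA = sort(keys[keep & sideA & !sideB]),
    uniqueB = sort(keys[keep & !sideA & sideB]))

  geneTable <- data.frame(
    gene = gidx, chrom = geneChrom, strand = geneStrand, origin = origin,
    span_start = origin - .UTR_EXT,
    span_end = origin + (.SLOT_N - 1L) * .PITCH + .EXON_W + .UTR_EXT,
    stringsAsFactors = FALSE)

  truth <- list(
    transcripts = truthTx,
    expected = list(transcripts = expTx, translations = expTr,
                    exons = expEx),
    genes = geneTable,
    slotStart = slotStart, slotEnd = slotEnd)

  list(A = A, B = B, genomeSeq = seqs, truth = truth)
}

## ---- variants ---------------------------------------------------------------

## per-gene chain info needed for eligibility decisions
.geneChainInfo <- function(truthTx) {
  genes <- sort(unique(truthTx$gene))
  info <- lapply(genes, function(g) {
    tt <- truthTx[truthTx$gene == g, , drop = FALSE]
    sideA <- any(tt$type %in% c("shared", "A"))
    sideB <- any(tt$type %in% c("shared", "B"))
    codingA <- any(tt$type %in% c("shared", "A") &
                   !tt$flavor %in% c("retained_intron",
                                     "processed_transcript", "trunc"))
    codingB <- any(tt$type %in% c("shared", "B") &
                   !tt$flavor %in% c("retained_intron",
                                     "processed_transcript"))
    list(gene = g, sideA = sideA, sideB = sideB,
         bothSides = sideA && sideB,
         codingBoth = codingA && codingB,
         hasTrunc = any(tt$flavor == "trunc"),
         hasRetained = any(tt$flavor == "retained_intron"),
         hasUtrMod = any(tt$flavor == "utr"))
  })
  names(info) <- as.character(genes)
  info
}

#' Generate planted variants
#'
#' Places variants at positions whose consequence category is known by
#' construction on each side: synonymous/missense/stop-gain sites inside
#' planted codons, essential splice-donor sites, 5'UTR positions, positions
#' inside B-side UTR extensions (annotated only in B), positions inside
#' A-only retained-intron exons (annotated only in A), deep-intron and
#' intergenic positions (annotated in neither).  Reference alleles are read
#' from the (already written) genome; the planted codons are written here.
#'
#' @param p \code{SimParams}.
#' @param pair Output of [simulateGenesetPair()].
#' @return List: \code{variants} (data.frame \code{id}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}), \code{genomeSeq} (genome with
#'   planted codons written), \code{truth} (data.frame with per-variant
#'   category, expected per-side most-severe term and broad class, expected
#'   concordance status).
#' @export
simulateVariants <- function(p, pair) {
  set.seed(p$seed + 2L)
  seqs <- pair$genomeSeq
  truthTx <- pair$truth$transcripts
  genes <- pair$truth$genes
  slotStart <- pair$truth$slotStart; slotEnd <- pair$truth$slotEnd
  info <- .geneChainInfo(truthTx)

  nextCodon <- setNames(rep(0L, nrow(genes)), as.character(genes$gene))
  nextUtr <- nextCodon
  usedDonorAlt <- setNames(rep(0L, nrow(genes)), as.character(genes$gene))

  vrows <- list(); trows <- list()
  vid <- 0L
  emit <- function(chrom, pos, ref, alt, category, termA, termB, status) {
    vid <<- vid + 1L
    vrows[[vid]] <<- data.frame(id = sprintf("var%04d", vid), chrom = chrom,
                                pos = pos, ref = ref, alt = alt,
                                stringsAsFactors = FALSE)
    trows[[vid]] <<- data.frame(
      id = sprintf("var%04d", vid), category = category,
      expected_term_A = termA, expected_term_B = termB,
      expected_broad_A = if (is.na(termA)) NA_character_
                         else broadClass(termA),
      expected_broad_B = if (is.na(termB)) NA_character_
                         else broadClass(termB),
      expected_status = status, stringsAsFactors = FALSE)
  }

  firstExonMap <- function(g, q) {
    # transcript-space offset q (0-based) within the first transcript exon
    st <- slotStart[g, ]; en <- slotEnd[g, ]
    strd <- genes$strand[g]
    if (strd == "+") st[1L] + q else en[.SLOT_N] - q
  }
  gbase <- function(chrom, pos) substr(seqs[[chrom]], pos, pos)

  plantCodon <- function(g, codon, vOffInCodon, altTx, category,
                         termA, termB, status) {
    # allocate an unused in-frame codon in the first transcript exon CDS
    ci <- nextCodon[[as.character(g)]]
    off <- 60L + 3L * ci
    # keep clear of the exonic splice-region zone (last 3 exon bases)
    if (off + 2L > .EXON_W - 4L) return(FALSE)
    nextCodon[[as.character(g)]] <<- ci + 1L
    chrom <- genes$chrom[g]; strd <- genes$strand[g]
    gp <- firstExonMap(g, off)
    seqs <<- .writeTxSeq(seqs, chrom, strd, gp, codon)
    # variant at base vOffInCodon (1..3) of the codon, transcript strand
    qv <- off + vOffInCodon - 1L
    gpv <- firstExonMap(g, qv)
    refTx <- substr(codon, vOffInCodon, vOffInCodon)
    refG <- if (strd == "+") refTx else chartr("ACGT", "TGCA", refTx)
    altG <- if (strd == "+") altTx else chartr("ACGT", "TGCA", altTx)
    emit(chrom, gpv, refG, altG, category, termA, termB, status)
    TRUE
  }

  vc <- p$variantCounts
  want <- function(nm) if (nm %in% names(vc)) as.integer(vc[[nm]]) else 0L
  elig <- function(pred) {
    ok <- vapply(info, pred, NA)
    as.integer(names(info))[ok]
  }

  ## CDS categories: need anchored coding transcripts on both sides and no
  ## truncated transcript (whose unanchored CDS would add ambiguity terms
  ## that still rank below coding terms, so truncation is actually fine for
  ## cds categories; it matters for utr5 where ambiguity outranks UTR)
  cdsGenes <- elig(function(x) x$codingBoth)
  planCds <- function(category, codon, base, altTx, term) {
    n <- want(category)
    if (!n) return()
    if (!length(cdsGenes))
      stop("generation error: no eligible gene for category ", category)
    k <- 0L; gcycle <- rep(cdsGenes, length.out = 10L * n)
    for (g in gcycle) {
      if (k >= n) break
      if (plantCodon(g, codon, base, altTx, category, term, term,
                     "concordant")) k <- k + 1L
    }
    if (k < n) stop("generation error: could not place all ", category,
                    " variants")
  }
  planCds("cds_synonymous", "CCA", 3L, "G", "synonymous")
  planCds("cds_missense", "CCA", 1L, "G", "missense")
  planCds("cds_stopgain", "TCA", 2L, "A", "stop_gained")

  ## splice donor: 2nd intronic base of the intron after the first
  ## transcript exon; shared by every chain of the gene on both sides
  n <- want("splice_donor")
  if (n) {
    dGenes <- elig(function(x) x$bothSides)
    if (!length(dGenes))
      stop("generation error: no eligible gene for category splice_donor")
    k <- 0L
    for (g in rep(dGenes, length.out = max(n, length(dGenes)) * 3L)) {
      if (k >= n) break
      used <- usedDonorAlt[[as.character(g)]]
      if (used >= 3L) next
      chrom <- genes$chrom[g]; strd <- genes$strand[g]
      pos <- if (strd == "+") slotEnd[g, 1L] + 2L
             else slotStart[g, .SLOT_N] - 2L
      ref <- gbase(chrom, pos)
      alts <- setdiff(c("A", "C", "G", "T"), ref)
      emit(chrom, pos, ref, alts[used + 1L], "splice_donor",
           "splice_donor", "splice_donor", "concordant")
      usedDonorAlt[[as.character(g)]] <- used + 1L
      k <- k + 1L
    }
    if (k < n) stop("generation error: could not place all splice_donor ",
                    "variants")
  }

  ## utr5: transcript offset < 24 in the first exon (before every anchor);
  ## genes with truncated transcripts are avoided because their unanchored
  ## CDS covers the 5'UTR and outranks it
  n <- want("utr5")
  if (n) {
    uGenes <- elig(function(x) x$codingBoth && !x$hasTrunc)
    if (!length(uGenes))
      stop("generation error: no eligible gene for category utr5")
    k <- 0L
    for (g in rep(uGenes, length.out = 10L * n)) {
      if (k >= n) break
      ui <- nextUtr[[as.character(g)]]
      off <- 8L + 3L * ui
      if (off > 23L) next
      nextUtr[[as.character(g)]] <- ui + 1L
      chrom <- genes$chrom[g]; strd <- genes$strand[g]
      pos <- firstExonMap(g, off)
      ref <- gbase(chrom, pos)
      alt <- setdiff(c("A", "C", "G"), ref)[1L]
      emit(chrom, pos, ref, alt, "utr5", "utr5", "utr5", "concordant")
      k <- k + 1L
    }
    if (k < n) stop("generation error: could not place all utr5 variants")
  }

  ## utr_extension: inside the B-side 30 bp terminal extension; annotated
  ## only in B (utr5 or utr3 depending on which transcript end the genomic
  ## left extension is)
  n <- want("utr_extension")
  if (n) {
    eGenes <- elig(function(x) x$hasUtrMod)
    if (!length(eGenes))
      stop("generation error: no eligible gene for category utr_extension")
    k <- 0L; usedOff <- setNames(rep(0L, length(eGenes)),
                                 as.character(eGenes))
    for (g in rep(eGenes, length.out = 10L * n)) {
      if (k >= n) break
      uo <- usedOff[[as.character(g)]]
      if (uo >= 10L) next
      usedOff[[as.character(g)]] <- uo + 1L
      chrom <- genes$chrom[g]; strd <- genes$strand[g]
      pos <- slotStart[g, 1L] - .UTR_EXT + 5L + 2L * uo
      ref <- gbase(chrom, pos)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
      term <- if (strd == "+") "utr5" else "utr3"
      emit(chrom, pos, ref, alt, "utr_extension", NA_character_, term,
           "unique_B")
      k <- k + 1L
    }
    if (k < n) stop("generation error: could not place all utr_extension ",
                    "variants")
  }

  ## noncoding_exon: centre of the retained intron (slots 2-3) of an A-side
  ## retained_intron transcript; deep intron for everything else
  n <- want("noncoding_exon")
  if (n) {
    rGenes <- elig(function(x) x$hasRetained)
    if (!length(rGenes))
      stop("generation error: no eligible gene for category noncoding_exon")
    k <- 0L; usedOff <- setNames(rep(0L, length(rGenes)),
                                 as.character(rGenes))
    for (g in rep(rGenes, length.out = 10L * n)) {
      if (k >= n) break
      uo <- usedOff[[as.character(g)]]
      if (uo >= 20L) next
      usedOff[[as.character(g)]] <- uo + 1L
      chrom <- genes$chrom[g]
      mid <- (slotEnd[g, 2L] + slotStart[g, 3L]) %/% 2L
      pos <- mid - 10L + 2L * uo
      ref <- gbase(chrom, pos)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
      emit(chrom, pos, ref, alt, "noncoding_exon", "noncoding_exon",
           NA_character_, "unique_A")
      k <- k + 1L
    }
    if (k < n) stop("generation error: could not place all noncoding_exon ",
                    "variants")
  }

  ## deep_intron: centre of the first intron (>8 bp from every junction in
  ## every chain); annotated in neither geneset
  n <- want("deep_intron")
  if (n) {
    dGenes <- as.integer(names(info))
    k <- 0L; usedOff <- setNames(rep(0L, length(dGenes)),
                                 as.character(dGenes))
    for (g in rep(dGenes, length.out = 10L * n)) {
      if (k >= n) break
      uo <- usedOff[[as.character(g)]]
      if (uo >= 20L) next
      usedOff[[as.character(g)]] <- uo + 1L
      chrom <- genes$chrom[g]
      mid <- (slotEnd[g, 1L] + slotStart[g, 2L]) %/% 2L
      pos <- mid - 10L + uo
      ref <- gbase(chrom, pos)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
      emit(chrom, pos, ref, alt, "deep_intron", NA_character_,
           NA_character_, "absent")
      k <- k + 1L
    }
  }

  ## intergenic: in the gap after the gene span
  n <- want("intergenic")
  if (n) {
    gsel <- rep(seq_len(nrow(genes)), length.out = n)
    for (j in seq_len(n)) {
      g <- gsel[j]
      chrom <- genes$chrom[g]
      pos <- genes$origin[g] + 2600L + j
      ref <- gbase(chrom, pos)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
      emit(chrom, pos, ref, alt, "intergenic", NA_character_,
           NA_character_, "absent")
    }
  }

  variants <- do.call(rbind, vrows)
  truth <- do.call(rbind, trows)
  o <- order(variants$chrom, variants$pos, variants$alt)
  list(variants = variants[o, , drop = FALSE],
       genomeSeq = seqs,
       truth = truth[o, , drop = FALSE])
}

## ---- expression tracks ------------------------------------------------------

#' Generate per-sample coverage tracks
#'
#' Plants a per-gene, per-sample expression density (gamma distributed);
#' silent genes (zero-inflation) get zero coverage everywhere.  Expressed
#' genes receive their density over the union of all exonic bases (both
#' genesets) and \code{intronFactor} times it over the remaining intronic
#' span; optional Gaussian block noise can be added.
#'
#' @param p \code{SimParams}.
#' @param pair Output of [simulateGenesetPair()].
#' @return List: \code{tracks} (list of \code{GRanges} with \code{score},
#'   one per sample), \code{truth} (list with \code{silent} logical per
#'   gene, \code{density} genes x samples matrix, gene spans).
#' @export
simulateTracks <- function(p, pair) {
  set.seed(p$seed + 3L)
  genes <- pair$truth$genes
  nG <- nrow(genes)
  silent <- stats::runif(nG) < p$expression$zeroFraction
  dens <- matrix(stats::rgamma(nG * p$nSamples, shape = p$expression$shape,
                               rate = p$expression$rate),
                 nrow = nG)
  dens[silent, ] <- 0

  # per-gene exonic union across both genesets
  allEx <- c(unlist(pair$A@exons, use.names = FALSE),
             unlist(pair$B@exons, use.names = FALSE))
  spans <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$span_start, genes$span_end))
  exByGene <- lapply(seq_len(nG), function(g) {
    sel <- allEx[S4Vectors::queryHits(
      GenomicRanges::findOverlaps(allEx, spans[g]))]
    GenomicRanges::reduce(sel, ignore.strand = TRUE)
  })
  intrByGene <- lapply(seq_len(nG), function(g) {
    if (!length(exByGene[[g]])) return(GenomicRanges::GRanges())
    span <- range(exByGene[[g]])
    GenomicRanges::setdiff(span, exByGene[[g]], ignore.strand = TRUE)
  })

  tracks <- lapply(seq_len(p$nSamples), function(s) {
    blocks <- list()
    for (g in seq_len(nG)) {
      if (silent[g] || !length(exByGene[[g]])) next
      d <- dens[g, s]
      ex <- exByGene[[g]]; ex$score <- d
      blocks[[length(blocks) + 1L]] <- ex
      ir <- intrByGene[[g]]
      if (length(ir)) {
        ir$score <- d * p$expression$intronFactor
        blocks[[length(blocks) + 1L]] <- ir
      }
    }
    if (!length(blocks)) {
      empty <- GenomicRanges::GRanges()
      empty$score <- numeric(0)
      return(empty)
    }
    tr <- do.call(c, blocks)
    if (p$expression$noiseSd > 0)
      tr$score <- pmax(0, tr$score +
                         stats::rnorm(length(tr), 0, p$expression$noiseSd))
    BiocGenerics::sort(tr, ignore.strand = TRUE)
  })
  list(tracks = tracks,
       truth = list(silent = silent, density = dens,
                    spans = data.frame(gene = genes$gene,
                                       chrom = genes$chrom,
                                       start = genes$span_start,
                                       end = genes$span_end)))
}

## ---- orchestration ----------------------------------------------------------

#' Generate a complete synthetic study
#'
#' Runs genome, geneset-pair, variant and track generation under one seed
#' and optionally writes every artefact (FASTA, chrom.sizes, two GTFs, VCF,
#' one bedGraph per sample, ground-truth JSON) to a directory.
#'
#' @param p \code{SimParams}.
#' @param outDir Optional output directory (created if needed).
#' @return List: \code{params}, \code{genome} (\code{DNAStringSet}),
#'   \code{chromSizes}, \code{A}, \code{B}, \code{variants},
#'   \code{tracks}, \code{truth}, and (when written) \code{files}.
#' @export
simulateStudy <- function(p = simParams(), outDir = NULL) {
  genome <- simulateGenome(p)
  pair <- simulateGenesetPair(p, genome)
  vars <- simulateVariants(p, pair)
  pair$genomeSeq <- vars$genomeSeq
  trks <- simulateTracks(p, pair)
  dna <- Biostrings::DNAStringSet(pair$genomeSeq)
  sim <- list(params = p, genome = dna, chromSizes = genome$sizes,
              A = pair$A, B = pair$B, variants = vars$variants,
              tracks = trks$tracks,
              truth = c(pair$truth, list(variants = vars$truth,
                                         expression = trks$truth)))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    f <- list(
      fasta = file.path(outDir, "genome.fa"),
      sizes = file.path(outDir, "genome.chrom.sizes"),
      gtfA = file.path(outDir, "genesetA.gtf"),
      gtfB = file.path(outDir, "genesetB.gtf"),
      vcf = file.path(outDir, "variants.vcf"),
      truth = file.path(outDir, "ground_truth.json"))
    Biostrings::writeXStringSet(dna, f$fasta)
    writeChromSizes(genome$sizes, f$sizes)
    writeGeneset(pair$A, f$gtfA)
    writeGeneset(pair$B, f$gtfB)
    v <- sim$variants
    vr <- VariantAnnotation::VRanges(
      seqnames = v$chrom,
      ranges = IRanges::IRanges(v$pos, width = nchar(v$ref)),
      ref = v$ref, alt = v$alt,
      sampleNames = S4Vectors::Rle(factor("sim", levels = "sim"),
                                   nrow(v)))
    names(vr) <- v$id
    VariantAnnotation::writeVcf(vr, f$vcf)
    f$tracks <- vapply(seq_along(sim$tracks), function(s) {
      path <- file.path(outDir, sprintf("track_%02d.bedGraph", s))
      writeCoverageTrack(sim$tracks[[s]], path)
      path
    }, "")
    jsonlite::write_json(list(
      seed = p$seed,
      expected = sim$truth$expected,
      variant_truth = sim$truth$variants,
      silent_genes = which(sim$truth$expression$silent),
      n_genes = nrow(sim$truth$genes)),
      f$truth, auto_unbox = TRUE, digits = NA)
    sim$files <- f
  }
  sim
}
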