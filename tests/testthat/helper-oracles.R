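# Independent brute-force oracles.  These deliberately use naive loops and
# string slicing, not the package's data structures, so that agreement with
# the implementation is informative.

# --- O(n^2) non-redundant exon set ------------------------------------------
# txList: list of list(chrom, strand, starts, ends) per transcript.
# Returns a data.frame of retained distinct exons with side bookkeeping.
bruteForceUniqueExons <- function(txList) {
  occ <- list()
  for (t in txList) {
    k <- length(t$starts)
    for (j in seq_len(k)) {
      occ[[length(occ) + 1L]] <- list(
        chrom = t$chrom, strand = t$strand,
        start = t$starts[j], end = t$ends[j],
        leftJ = j > 1L, rightJ = j < k,
        side = if (is.null(t$side)) "A" else t$side)
    }
  }
  # distinct exons, junction flags OR-ed over occurrences
  rec <- list()
  for (o in occ) {
    key <- paste(o$chrom, o$strand, o$start, o$end, sep = "|")
    if (is.null(rec[[key]]))
      rec[[key]] <- list(chrom = o$chrom, strand = o$strand,
                         start = o$start, end = o$end,
                         leftJ = FALSE, rightJ = FALSE,
                         sides = character(0))
    rec[[key]]$leftJ <- rec[[key]]$leftJ || o$leftJ
    rec[[key]]$rightJ <- rec[[key]]$rightJ || o$rightJ
    rec[[key]]$sides <- union(rec[[key]]$sides, o$side)
  }
  keys <- names(rec)
  keep <- rep(TRUE, length(rec))
  repOf <- seq_along(rec)
  for (i in seq_along(rec)) {
    a <- rec[[i]]
    oneJ <- xor(a$leftJ, a$rightJ)
    if (!oneJ) next
    best <- NA_integer_; bestW <- a$end - a$start
    for (j in seq_along(rec)) {
      if (i == j) next
      b <- rec[[j]]
      if (b$chrom != a$chrom || b$strand != a$strand) next
      sharesJ <-
        (a$leftJ && b$leftJ && a$start == b$start) ||
        (a$rightJ && b$rightJ && a$end == b$end)
      if (!sharesJ) next
      if ((b$end - b$start) > (a$end - a$start)) {
        keep[i] <- FALSE
        if ((b$end - b$start) > bestW) { best <- j; bestW <- b$end - b$start }
      }
    }
    if (!keep[i]) repOf[i] <- best
  }
  # resolve chains
  repeat {
    nxt <- repOf[repOf]
    if (identical(nxt, repOf)) break
    repOf <- nxt
  }
  sidesOf <- lapply(seq_along(rec), function(i)
    sort(unique(unlist(lapply(which(repOf == i), function(j)
      rec[[j]]$sides)))))
  data.frame(
    key = keys,
    kept = keep,
    sides = I(sidesOf),
    stringsAsFactors = FALSE)
}

# --- per-base bitmap coverage -----------------------------------------------
bitmapCoverage <- function(starts, ends, chroms, maxLen) {
  total <- 0L
  for (ch in unique(chroms)) {
    bm <- logical(maxLen)
    for (i in which(chroms == ch)) bm[starts[i]:ends[i]] <- TRUE
    total <- total + sum(bm)
  }
  total
}

# --- per-base density loop ---------------------------------------------------
loopDensity <- function(trackDf, chrom, start, end) {
  tot <- 0
  for (p in start:end) {
    hit <- which(trackDf$chrom == chrom & trackDf$start <= p &
                 trackDf$end >= p)
    if (length(hit)) tot <- tot + sum(trackDf$score[hit])
  }
  tot / (end - start + 1)
}

# --- string-slicing SNV consequence classifier --------------------------------
# Independent re-derivation used to cross-check annotateVariantTranscript()
# for every possible SNV on a toy transcript.
oracleSnv <- function(pos, alt, exS, exE, cdS, cdE, strand, tags, chromSeq) {
  comp <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]
  k <- length(exS)
  terms <- character(0)
  exIdx <- 0L
  for (j in seq_len(k))
    if (pos >= exS[j] && pos <= exE[j]) exIdx <- j
  if (exIdx > 0L) {
    if (exIdx > 1L && pos <= exS[exIdx] + 2L) terms <- c(terms, "splice_region")
    if (exIdx < k && pos >= exE[exIdx] - 2L) terms <- c(terms, "splice_region")
    if (length(cdS)) {
      inCds <- FALSE
      for (j in seq_along(cdS))
        if (pos >= cdS[j] && pos <= cdE[j]) inCds <- TRUE
      if (inCds) {
        if ("CDS_start_NF" %in% tags) {
          terms <- c(terms, "coding_sequence_ambiguous")
        } else {
          gpos <- integer(0); bases <- character(0)
          for (j in seq_along(cdS)) {
            gpos <- c(gpos, cdS[j]:cdE[j])
            bases <- c(bases, strsplit(substr(chromSeq, cdS[j], cdE[j]),
                                       "")[[1]])
          }
          if (strand == "-") {
            gpos <- rev(gpos)
            bases <- vapply(rev(bases), comp, "")
          }
          q <- which(gpos == pos)
          altB <- if (strand == "-") comp(alt) else alt
          ci <- (q - 1L) %/% 3L
          if ((ci + 1L) * 3L > length(bases)) {
            terms <- c(terms, "coding_sequence_ambiguous")
          } else {
            refCodon <- paste(bases[(ci * 3L + 1L):(ci * 3L + 3L)],
                              collapse = "")
            mut <- bases
            mut[q] <- altB
            altCodon <- paste(mut[(ci * 3L + 1L):(ci * 3L + 3L)],
                              collapse = "")
            aaR <- Biostrings::GENETIC_CODE[[refCodon]]
            aaA <- Biostrings::GENETIC_CODE[[altCodon]]
            terms <- c(terms,
              if (aaR != "*" && aaA == "*") "stop_gained"
              else if (aaR == "*" && aaA != "*") "stop_lost"
              else if (ci == 0L && refCodon == "ATG" && altCodon != "ATG")
                "start_lost"
              else if (aaR == aaA) "synonymous" else "missense")
          }
        }
      } else {
        lo <- min(cdS); hi <- max(cdE)
        terms <- c(terms,
          if (pos < lo) { if (strand == "+") "utr5" else "utr3" }
          else if (pos > hi) { if (strand == "+") "utr3" else "utr5" }
          else "coding_sequence_ambiguous")
      }
    } else {
      terms <- c(terms, "noncoding_exon")
    }
  } else {
    for (j in seq_len(k - 1L)) {
      is <- exE[j] + 1L; ie <- exS[j + 1L] - 1L
      if (pos < is || pos > ie) next
      dl <- pos - is + 1L; dr <- ie - pos + 1L
      dDonor <- if (strand == "+") dl else dr
      dAcc <- if (strand == "+") dr else dl
      if (dDonor <= 2L) terms <- c(terms, "splice_donor")
      if (dAcc <= 2L) terms <- c(terms, "splice_acceptor")
      if (dl >= 3L && dl <= 8L) terms <- c(terms, "splice_region")
      if (dr >= 3L && dr <= 8L) terms <- c(terms, "splice_region")
    }
  }
  sort(unique(terms))
}

# random multi-transcript exon fixtures for oracle-equivalence runs
randomTxList <- function(nTx, seed, side = "A", chrom = "chr1",
                         strand = "+") {
  set.seed(seed)
  lapply(seq_len(nTx), function(i) {
    k <- sample(1:6, 1)
    # random sorted boundaries with positive exon and intron widths
    cuts <- sort(sample(seq(1, 5000, by = 10), 2 * k))
    starts <- cuts[seq(1, 2 * k, by = 2)]
    ends <- cuts[seq(2, 2 * k, by = 2)]
    # occasionally reuse boundaries of an earlier transcript pattern
    list(chrom = chrom, strand = strand, starts = starts, ends = ends,
         side = side)
  })
}
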