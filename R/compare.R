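#' @importFrom BiocGenerics start end strand width
NULL

## ---- equivalence keys ------------------------------------------------------

#' Structural equivalence keys for transcripts and translations
#'
#' Transcript identity for comparison is structural, not accession-based:
#' a single-exon transcript is keyed by its exon coordinates; a multi-exon
#' transcript by its ordered intron coordinates (the "intron chain"), which
#' deliberately ignores terminal-exon outer coordinates so that transcripts
#' differing only in UTR length compare as equal.  A translation is keyed by
#' its CDS-exon coordinates exactly as annotated.
#'
#' @param gs A \code{Geneset}.
#' @return \code{transcriptKeys}: character vector of keys named by
#'   transcript id.  \code{translationKeys}: the same, with \code{NA} for
#'   transcripts without CDS.
#' @export
transcriptKeys <- function(gs) {
  ex <- gs@exons
  keys <- vapply(seq_along(ex), function(i) {
    e <- ex[[i]]
    chr <- as.character(GenomeInfoDb::seqnames(e))[1]
    str <- as.character(BiocGenerics::strand(e))[1]
    if (length(e) == 1L) {
      paste0(chr, "|", str, "|SE|", BiocGenerics::start(e), "-",
             BiocGenerics::end(e))
    } else {
      is <- BiocGenerics::end(e)[-length(e)] + 1L
      ie <- BiocGenerics::start(e)[-1] - 1L
      paste0(chr, "|", str, "|IC|", paste(is, ie, sep = "-", collapse = ","))
    }
  }, "")
  setNames(keys, gs@txData$tx_id)
}

#' @rdname transcriptKeys
#' @export
translationKeys <- function(gs) {
  cd <- gs@cds
  keys <- vapply(seq_along(cd), function(i) {
    cc <- cd[[i]]
    if (!length(cc)) return(NA_character_)
    cc <- BiocGenerics::sort(cc)
    chr <- as.character(GenomeInfoDb::seqnames(cc))[1]
    str <- as.character(BiocGenerics::strand(cc))[1]
    paste0(chr, "|", str, "|CDS|",
           paste(BiocGenerics::start(cc), BiocGenerics::end(cc),
                 sep = "-", collapse = ","))
  }, "")
  setNames(keys, gs@txData$tx_id)
}

## ---- non-redundant exon sets ----------------------------------------------

## One row per per-transcript exon occurrence.
.exonOccurrences <- function(gs) {
  ex <- gs@exons
  n <- lengths(ex)
  if (!sum(n))
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      tx = character(0), leftJunct = logical(0),
                      rightJunct = logical(0), terminal = logical(0),
                      hasCds = logical(0)))
  flat <- unlist(ex, use.names = FALSE)
  tx <- rep(gs@txData$tx_id, n)
  idx <- unlist(lapply(n, seq_len))
  ntx <- rep(n, n)
  hasCds <- rep(lengths(gs@cds) > 0, n)
  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(flat)),
    strand = as.character(BiocGenerics::strand(flat)),
    start = BiocGenerics::start(flat), end = BiocGenerics::end(flat),
    tx = tx,
    leftJunct = idx > 1L,            # exon start abuts an intron
    rightJunct = idx < ntx,          # exon end abuts an intron
    terminal = idx == 1L | idx == ntx,
    hasCds = hasCds,
    stringsAsFactors = FALSE)
}

## Aggregate occurrences into distinct exon records.
.exonRecords <- function(occ) {
  if (!nrow(occ))
    return(data.frame(key = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), width = integer(0),
                      startJunct = logical(0), endJunct = logical(0),
                      terminal = logical(0), hasCds = logical(0),
                      txIds = I(list())))
  key <- paste(occ$chrom, occ$strand, occ$start, occ$end, sep = "|")
  sp <- split(seq_len(nrow(occ)), key)
  first <- vapply(sp, `[`, 1L, 1L)
  data.frame(
    key = names(sp),
    chrom = occ$chrom[first], strand = occ$strand[first],
    start = occ$start[first], end = occ$end[first],
    width = occ$end[first] - occ$start[first] + 1L,
    startJunct = vapply(sp, function(i) any(occ$leftJunct[i]), NA),
    endJunct = vapply(sp, function(i) any(occ$rightJunct[i]), NA),
    terminal = vapply(sp, function(i) any(occ$terminal[i]), NA),
    hasCds = vapply(sp, function(i) any(occ$hasCds[i]), NA),
    txIds = I(lapply(sp, function(i) sort(unique(occ$tx[i])))),
    stringsAsFactors = FALSE, row.names = NULL)
}

## Apply the terminal/longer-exon collapse: a record whose ONLY splice
## junction (one boundary) is shared with a strictly longer junction-bearing
## record is excluded and mapped onto the longest such record.  Internal
## records (both boundaries are junctions somewhere) and junction-free
## records (single-exon transcripts) are always retained.
.collapseExonRecords <- function(rec) {
  n <- nrow(rec)
  kept <- rep(TRUE, n)
  repIdx <- seq_len(n)
  if (!n) return(cbind(rec, kept = kept, repIdx = repIdx)[0, ])
  pureStart <- rec$startJunct & !rec$endJunct
  pureEnd <- rec$endJunct & !rec$startJunct
  jKeyStart <- paste(rec$chrom, rec$strand, "S", rec$start)
  jKeyEnd <- paste(rec$chrom, rec$strand, "E", rec$end)
  for (i in which(pureStart | pureEnd)) {
    if (pureStart[i]) {
      sharers <- which(rec$startJunct & jKeyStart == jKeyStart[i])
    } else {
      sharers <- which(rec$endJunct & jKeyEnd == jKeyEnd[i])
    }
    sharers <- setdiff(sharers, i)
    longer <- sharers[rec$width[sharers] > rec$width[i]]
    if (length(longer)) {
      kept[i] <- FALSE
      # longest sharer; ties broken lexicographically by (chrom, start, end)
      o <- order(-rec$width[longer], rec$chrom[longer], rec$start[longer],
                 rec$end[longer])
      repIdx[i] <- longer[o[1]]
    }
  }
  # resolve collapse chains (shorter -> longer -> longest)
  repeat {
    nxt <- repIdx[repIdx]
    if (identical(nxt, repIdx)) break
    repIdx <- nxt
  }
  rec$kept <- kept
  rec$repIdx <- repIdx
  rec
}

.collapsedRecords <- function(gs) {
  rec <- .collapseExonRecords(.exonRecords(.exonOccurrences(gs)))
  rec[rec$kept, , drop = FALSE]
}

#' Non-redundant ("unique") exon set of a geneset
#'
#' Collapses the per-transcript redundant exon complement to a non-redundant
#' set: exact duplicates are merged; a terminal exon whose single internal
#' splice junction is shared with a longer exon is dropped in favour of the
#' longer exon; internal exons that overlap but differ in at least one
#' splice junction are all retained.  Exons of single-exon transcripts carry
#' no splice junctions and are retained after exact-duplicate merging.
#'
#' @param gs A \code{Geneset}.
#' @return \code{GRanges} with metadata columns \code{txIds}
#'   (\code{CharacterList} of source transcripts), \code{terminal},
#'   \code{hasCds} and \code{key}.
#' @export
uniqueExonSet <- function(gs) {
  rec <- .collapsedRecords(gs)
  gr <- GenomicRanges::GRanges(
    rec$chrom, IRanges::IRanges(rec$start, rec$end), strand = rec$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    txIds = IRanges::CharacterList(rec$txIds),
    terminal = rec$terminal, hasCds = rec$hasCds, key = rec$key)
  gr
}

## ---- partitions ------------------------------------------------------------

.makePartition <- function(kind, A, B, keysA, keysB, membersA, membersB) {
  shared <- intersect(keysA, keysB)
  new("FeaturePartition", kind = kind,
      nameA = genesetName(A), nameB = genesetName(B),
      shared = sort(shared),
      uniqueA = sort(setdiff(keysA, keysB)),
      uniqueB = sort(setdiff(keysB, keysA)),
      members = S4Vectors::DataFrame(
        key = c(keysA, setdiff(keysB, keysA)),
        memberA = IRanges::CharacterList(
          c(membersA, rep(list(character(0)),
                          length(setdiff(keysB, keysA))))),
        memberB = IRanges::CharacterList(
          c(lapply(keysA, function(k)
              if (k %in% keysB) membersB[[match(k, keysB)]] else character(0)),
            membersB[match(setdiff(keysB, keysA), keysB)]))))
}

#' Compare transcripts, translations or exons between two genesets
#'
#' Partitions the distinct equivalence keys of each feature kind into those
#' present in both genesets, only in the first, and only in the second.  For
#' exons the partition is computed over the union of the two non-redundant
#' exon sets, with the terminal/longer-exon collapse applied across the
#' union: a terminal exon in one set whose single junction is shared with a
#' longer exon in the other counts as shared.
#'
#' @param A,B Locus-filtered \code{Geneset} objects.
#' @return A \code{FeaturePartition}.
#' @export
compareTranscripts <- function(A, B) {
  kA <- transcriptKeys(A); kB <- transcriptKeys(B)
  uA <- unique(unname(kA)); uB <- unique(unname(kB))
  .makePartition("transcript", A, B, uA, uB,
                 lapply(uA, function(k) names(kA)[kA == k]),
                 lapply(uB, function(k) names(kB)[kB == k]))
}

#' @rdname compareTranscripts
#' @export
compareTranslations <- function(A, B) {
  kA <- translationKeys(A); kA <- kA[!is.na(kA)]
  kB <- translationKeys(B); kB <- kB[!is.na(kB)]
  uA <- unique(unname(kA)); uB <- unique(unname(kB))
  .makePartition("translation", A, B, uA, uB,
                 lapply(uA, function(k) names(kA)[kA == k]),
                 lapply(uB, function(k) names(kB)[kB == k]))
}

#' @rdname compareTranscripts
#' @export
compareExons <- function(A, B) {
  ra <- .collapsedRecords(A)
  rb <- .collapsedRecords(B)
  ra$side <- "A"; rb$side <- "B"
  un <- rbind(ra[, c("key", "chrom", "strand", "start", "end", "width",
                     "startJunct", "endJunct", "terminal", "hasCds",
                     "side")],
              rb[, c("key", "chrom", "strand", "start", "end", "width",
                     "startJunct", "endJunct", "terminal", "hasCds",
                     "side")])
  # merge exact-coordinate matches across sides, OR-ing junction usage
  sp <- split(seq_len(nrow(un)), un$key)
  first <- vapply(sp, `[`, 1L, 1L)
  mrg <- data.frame(
    key = names(sp),
    chrom = un$chrom[first], strand = un$strand[first],
    start = un$start[first], end = un$end[first], width = un$width[first],
    startJunct = vapply(sp, function(i) any(un$startJunct[i]), NA),
    endJunct = vapply(sp, function(i) any(un$endJunct[i]), NA),
    terminal = vapply(sp, function(i) any(un$terminal[i]), NA),
    hasCds = vapply(sp, function(i) any(un$hasCds[i]), NA),
    inA = vapply(sp, function(i) any(un$side[i] == "A"), NA),
    inB = vapply(sp, function(i) any(un$side[i] == "B"), NA),
    stringsAsFactors = FALSE, row.names = NULL)
  col <- .collapseExonRecords(mrg)
  # representatives inherit side membership from collapsed members
  repInA <- tapply(col$inA, col$repIdx, any)
  repInB <- tapply(col$inB, col$repIdx, any)
  keptIdx <- which(col$kept)
  inA <- as.logical(repInA[as.character(keptIdx)])
  inB <- as.logical(repInB[as.character(keptIdx)])
  inA[is.na(inA)] <- FALSE; inB[is.na(inB)] <- FALSE
  keys <- col$key[keptIdx]
  .makePartition("exon", A, B, keys[inA], keys[inB],
                 as.list(keys[inA]), as.list(keys[inB]))
}

## ---- coverage and per-locus statistics -------------------------------------

#' Strand-wise genomic coverage of a non-redundant exon set
#'
#' The headline coverage is the sum of member exon lengths per
#' strand; since terminal exons sharing a donor but not an acceptor can
#' leave some genomic sequence counted twice, the merged footprint (union of
#' intervals) is reported alongside.  Percentages use the total genome
#' length (sum of chromosome sizes) as denominator for every row.
#'
#' @param ue \code{GRanges} from [uniqueExonSet()].
#' @param sizes Named integer chromosome lengths covering all chromosomes
#'   present in \code{ue}.
#' @return data.frame with rows for strand \code{+}, \code{-} and
#'   \code{combined}: \code{summed_bp}, \code{merged_bp},
#'   \code{percent_summed}, \code{percent_merged}.
#' @export
genomicCoverage <- function(ue, sizes) {
  chr <- unique(as.character(GenomeInfoDb::seqnames(ue)))
  missing <- setdiff(chr, names(sizes))
  if (length(missing))
    stop("chromosome absent from sizes table: ", missing[1])
  genomeBp <- sum(as.numeric(sizes))
  one <- function(gr) {
    summed <- sum(as.numeric(BiocGenerics::width(gr)))
    merged <- sum(as.numeric(BiocGenerics::width(
      GenomicRanges::reduce(gr, ignore.strand = TRUE))))
    c(summed = summed, merged = merged)
  }
  rows <- list(
    `+` = one(ue[BiocGenerics::strand(ue) == "+"]),
    `-` = one(ue[BiocGenerics::strand(ue) == "-"]),
    combined = one(ue))
  out <- data.frame(
    strand = names(rows),
    summed_bp = vapply(rows, `[[`, 0, "summed"),
    merged_bp = vapply(rows, `[[`, 0, "merged"),
    row.names = NULL, stringsAsFactors = FALSE)
  out$percent_summed <- 100 * out$summed_bp / genomeBp
  out$percent_merged <- 100 * out$merged_bp / genomeBp
  out
}

#' Per-locus alternative-splicing statistics
#'
#' Means, over loci carrying at least one multi-exon transcript, of the
#' number of distinct transcript keys (alternatively spliced transcripts),
#' distinct translation keys, and non-redundant exons at the locus.
#'
#' @param gs A locus-filtered \code{Geneset}.
#' @return List with \code{mean_transcripts}, \code{mean_translations},
#'   \code{mean_unique_exons}, \code{n_multiexon_loci} and
#'   \code{degenerate} (TRUE when no multi-exon locus exists; means are then
#'   reported as 0).
#' @export
perLocusStats <- function(gs) {
  td <- gs@txData
  tk <- transcriptKeys(gs)
  lk <- translationKeys(gs)
  nex <- lengths(gs@exons)
  genes <- unique(td$gene_id)
  multi <- vapply(genes, function(g) any(nex[td$gene_id == g] > 1L), NA)
  if (!any(multi))
    return(list(mean_transcripts = 0, mean_translations = 0,
                mean_unique_exons = 0, n_multiexon_loci = 0L,
                degenerate = TRUE))
  gsel <- genes[multi]
  nT <- nL <- nE <- numeric(length(gsel))
  for (j in seq_along(gsel)) {
    sel <- td$gene_id == gsel[j]
    nT[j] <- length(unique(tk[sel]))
    lkj <- lk[sel]
    nL[j] <- length(unique(lkj[!is.na(lkj)]))
    nE[j] <- nrow(.collapsedRecords(keepTranscripts(gs, td$tx_id[sel])))
  }
  list(mean_transcripts = mean(nT), mean_translations = mean(nL),
       mean_unique_exons = mean(nE), n_multiexon_loci = length(gsel),
       degenerate = FALSE)
}
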