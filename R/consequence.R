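#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   GENETIC_CODE reverseComplement DNAString
#' @importFrom VariantAnnotation readVcf expand writeVcf VRanges
NULL

## Severity rank table, most (1) to least severe.  The order follows the
## Ensembl convention for selecting a single most-severe call per variant;
## it is exposed via consequenceTerms() and can be swapped wholesale by
## advanced users through the `rank` argument of mostSevere().
.TERM_ORDER <- c(
  "splice_acceptor", "splice_donor", "stop_gained", "frameshift",
  "stop_lost", "start_lost", "inframe_indel", "missense", "splice_region",
  "synonymous", "coding_sequence_ambiguous", "utr5", "utr3",
  "noncoding_exon")
.TERM_RANK <- setNames(seq_along(.TERM_ORDER), .TERM_ORDER)

.BROAD_MAP <- c(
  stop_gained = "LoF", frameshift = "LoF", splice_donor = "LoF",
  splice_acceptor = "LoF", stop_lost = "LoF", start_lost = "LoF",
  missense = "CDS", synonymous = "CDS", inframe_indel = "CDS",
  coding_sequence_ambiguous = "CDS",
  splice_region = "splice",
  utr5 = "other", utr3 = "other", noncoding_exon = "other")

#' Consequence term vocabulary
#'
#' @return Character vector of consequence terms in severity order, most
#'   severe first.
#' @export
consequenceTerms <- function() .TERM_ORDER

#' Most severe consequence term
#'
#' @param terms Non-empty character vector of consequence terms.
#' @param rank Named integer severity rank table (1 = most severe).
#' @return The single most severe term.
#' @export
mostSevere <- function(terms, rank = .TERM_RANK) {
  if (!length(terms)) stop("mostSevere() requires a non-empty term list")
  bad <- setdiff(terms, names(rank))
  if (length(bad)) stop("unknown consequence term: ", bad[1])
  terms[which.min(rank[terms])]
}

#' Broad class of a consequence term
#'
#' Maps each consequence term to one of the four broad classes: \code{LoF}
#' (stop gained/lost, start lost, frameshift, essential splice site),
#' \code{CDS} (missense, synonymous, in-frame indel, ambiguous coding),
#' \code{splice} (splice region) and \code{other} (UTR and non-coding
#' exon).
#'
#' @param term Character vector of consequence terms.
#' @return Character vector of broad classes.
#' @export
broadClass <- function(term) {
  out <- unname(.BROAD_MAP[term])
  if (anyNA(out) && any(!is.na(term)))
    stop("unknown consequence term: ", term[is.na(out)][1])
  out
}

## broad-class severity (most severe member term decides)
.broadRank <- function(broad) {
  c(LoF = 1L, CDS = 2L, splice = 3L, other = 4L)[broad]
}

## ---- reference sequence access ---------------------------------------------

## genome sequences are handled internally as a named character vector (one
## string per chromosome) to keep per-variant lookups cheap
.asGenomeChar <- function(genome) {
  if (is.character(genome) && !is.null(names(genome)) &&
      all(nzchar(names(genome))))
    return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*", "", names(genome))
    return(out)
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  stop("genome must be a DNAStringSet, a named character vector of ",
       "sequences, or a FASTA path")
}

.genomeSubseq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome))
    stop("chromosome ", chrom, " absent from reference sequence")
  if (end > nchar(genome[[chrom]]))
    stop("reference sequence for ", chrom,
         " is shorter than the requested span")
  substr(genome[[chrom]], start, end)
}

.revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, "", fixed = TRUE),
                function(b) paste(rev(b), collapse = ""), "",
                USE.NAMES = FALSE))
}

## ---- variant representation ------------------------------------------------

#' Read variants from a VCF file
#'
#' Reads a VCF 4.x file, splits multi-allelic records into biallelic
#' variants, and returns a plain variant table.
#'
#' @param path VCF path.
#' @return data.frame with columns \code{id}, \code{chrom}, \code{pos}
#'   (1-based), \code{ref}, \code{alt}.
#' @export
readVariants <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- suppressWarnings(VariantAnnotation::readVcf(path))
  v <- VariantAnnotation::expand(v)
  rr <- SummarizedExperiment::rowRanges(v)
  data.frame(
    id = names(rr),
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    stringsAsFactors = FALSE, row.names = NULL)
}

## Normalise one variant: trim shared flanks, then left-align pure indels
## against the reference (VCF representation is ambiguous for repeats).
.normalizeVariant <- function(chrom, pos, ref, alt, genome) {
  # trim shared suffix
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # trim shared prefix (keep anchored form: stop at length 1)
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  # left-shift anchored pure indels while the representation is ambiguous
  if (nchar(ref) != nchar(alt) && min(nchar(ref), nchar(alt)) == 1L &&
      substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    repeat {
      if (pos <= 1L) break
      lastR <- substr(ref, nchar(ref), nchar(ref))
      lastA <- substr(alt, nchar(alt), nchar(alt))
      if (lastR != lastA) break
      prev <- .genomeSubseq(genome, chrom, pos - 1L, pos - 1L)
      ref <- paste0(prev, substr(ref, 1L, nchar(ref) - 1L))
      alt <- paste0(prev, substr(alt, 1L, nchar(alt) - 1L))
      pos <- pos - 1L
    }
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

## Genomic footprint of a variant: SNV/MNV = substituted bases; deletion =
## the deleted bases (excluding the anchor); insertion = the two bases
## flanking the insertion point.
.variantSpan <- function(pos, ref, alt) {
  if (nchar(ref) == nchar(alt)) c(pos, pos + nchar(ref) - 1L)
  else if (nchar(ref) > nchar(alt)) c(pos + 1L, pos + nchar(ref) - 1L)
  else c(pos, pos + 1L)
}

## ---- per-transcript classification -----------------------------------------

.codonTermSNV <- function(pos, alt, cst, cen, strand, genome, chrom) {
  pieces <- vapply(seq_along(cst), function(j)
    .genomeSubseq(genome, chrom, cst[j], cen[j]), "")
  if (strand == "+") {
    cdsSeq <- paste(pieces, collapse = "")
    prior <- if (any(pos > cen)) sum((cen - cst + 1L)[cen < pos]) else 0L
    i <- which(pos >= cst & pos <= cen)
    cdsPos <- prior + (pos - cst[i] + 1L)
  } else {
    cdsSeq <- paste(rev(.revcomp(pieces)), collapse = "")
    prior <- if (any(pos < cst)) sum((cen - cst + 1L)[cst > pos]) else 0L
    i <- which(pos >= cst & pos <= cen)
    cdsPos <- prior + (cen[i] - pos + 1L)
  }
  codIdx <- (cdsPos - 1L) %/% 3L
  if ((codIdx + 1L) * 3L > nchar(cdsSeq))
    return("coding_sequence_ambiguous")  # incomplete terminal codon
  refCodon <- substr(cdsSeq, codIdx * 3L + 1L, codIdx * 3L + 3L)
  altBase <- if (strand == "-") .revcomp(alt) else alt
  posInCodon <- (cdsPos - 1L) %% 3L + 1L
  altCodon <- refCodon
  substr(altCodon, posInCodon, posInCodon) <- altBase
  aaR <- Biostrings::GENETIC_CODE[[refCodon]]
  aaA <- Biostrings::GENETIC_CODE[[altCodon]]
  if (aaR != "*" && aaA == "*") "stop_gained"
  else if (aaR == "*" && aaA != "*") "stop_lost"
  else if (codIdx == 0L && refCodon == "ATG" && altCodon != "ATG")
    "start_lost"
  else if (aaR == aaA) "synonymous"
  else "missense"
}

#' Classify one variant against one transcript
#'
#' Minimal variant-consequence caller.  A variant receives terms only when
#' it falls in an exon or the proximal splice region of the transcript
#' (donor/acceptor: the first/last 2 intronic bp; splice region: exonic bp
#' 1-3 from a splice junction or intronic bp 3-8).  CDS SNVs are translated
#' with the standard genetic code on the spliced, strand-oriented CDS; CDS
#' indels are frameshift when the length change is not a multiple of 3,
#' in-frame otherwise.  Exonic variants outside the CDS are utr5/utr3 by
#' position on the coding strand; exonic variants of CDS-less transcripts
#' are noncoding_exon.  Transcripts tagged \code{CDS_start_NF} have no
#' anchorable reading frame: CDS-overlapping variants get
#' \code{coding_sequence_ambiguous}.
#'
#' @param chrom,pos,ref,alt Normalised variant (1-based \code{pos}).
#' @param exons Sorted exon \code{GRanges} of the transcript.
#' @param cds CDS \code{GRanges} (possibly empty).
#' @param strand \code{"+"} or \code{"-"}.
#' @param tags Character vector of transcript tags.
#' @param genome \code{DNAStringSet}, named character vector of sequences,
#'   or FASTA path.
#' @return Character vector of consequence terms (possibly empty).
#' @export
annotateVariantTranscript <- function(chrom, pos, ref, alt, exons, cds,
                                      strand, tags, genome) {
  cst <- BiocGenerics::start(cds); cen <- BiocGenerics::end(cds)
  o <- order(cst)
  .classifyTx(chrom, pos, ref, alt,
              BiocGenerics::start(exons), BiocGenerics::end(exons),
              cst[o], cen[o], strand, tags, .asGenomeChar(genome))
}

## vector-level classifier (hot path); st/en are sorted exon bounds, cst/cen
## sorted CDS bounds (length 0 for non-coding), genome a named character
## vector of chromosome sequences
.classifyTx <- function(chrom, pos, ref, alt, st, en, cst, cen,
                        strand, tags, genome) {
  k <- length(st)
  span <- .variantSpan(pos, ref, alt)
  a <- span[1]; b <- span[2]
  isSNV <- nchar(ref) == 1L && nchar(alt) == 1L
  terms <- character(0)

  exHit <- which(a <= en & b >= st)
  inExon <- length(exHit) > 0L

  # exonic splice region: within 3 bp of a splice-junction boundary
  for (i in exHit) {
    if (i > 1L && b >= st[i] && a <= st[i] + 2L)
      terms <- c(terms, "splice_region")
    if (i < k && a <= en[i] && b >= en[i] - 2L)
      terms <- c(terms, "splice_region")
  }

  # intronic windows
  if (k > 1L) for (j in seq_len(k - 1L)) {
    is <- en[j] + 1L; ie <- st[j + 1L] - 1L
    if (b < is || a > ie) next
    left <- c(is, is + 1L); right <- c(ie - 1L, ie)
    donor <- if (strand == "+") left else right
    acceptor <- if (strand == "+") right else left
    if (a <= donor[2] && b >= donor[1]) terms <- c(terms, "splice_donor")
    if (a <= acceptor[2] && b >= acceptor[1])
      terms <- c(terms, "splice_acceptor")
    # intronic splice region: 3..8 bp from either junction
    if ((a <= is + 7L && b >= is + 2L) || (a <= ie - 2L && b >= ie - 7L))
      terms <- c(terms, "splice_region")
  }

  if (inExon) {
    if (length(cst)) {
      inCds <- any(a <= cen & b >= cst)
      if (inCds) {
        if ("CDS_start_NF" %in% tags) {
          terms <- c(terms, "coding_sequence_ambiguous")
        } else if (isSNV) {
          terms <- c(terms, .codonTermSNV(pos, alt, cst, cen, strand,
                                          genome, chrom))
        } else {
          lenChange <- nchar(alt) - nchar(ref)
          terms <- c(terms,
                     if (lenChange %% 3L != 0L) "frameshift"
                     else "inframe_indel")
        }
      } else {
        cdsLo <- min(cst); cdsHi <- max(cen)
        terms <- c(terms,
          if (b < cdsLo) { if (strand == "+") "utr5" else "utr3" }
          else if (a > cdsHi) { if (strand == "+") "utr3" else "utr5" }
          else "coding_sequence_ambiguous")
      }
    } else {
      terms <- c(terms, "noncoding_exon")
    }
  }
  unique(terms)
}

## ---- dataset-level annotation ----------------------------------------------

#' Annotate a variant set against a geneset
#'
#' Runs the minimal consequence caller for every variant against every
#' overlapping transcript of the geneset, keeping one record per variant
#' that receives at least one term ("maps to" the geneset).  A single most
#' severe call is selected per variant by severity ranking, and mapped to
#' its broad class.
#'
#' @param variants A variant table (data.frame with \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt} and optional \code{id}) or a path to
#'   a VCF file.
#' @param gs A locus-filtered \code{Geneset}.
#' @param genome \code{DNAStringSet} or FASTA path.
#' @param externalCalls Optional data.frame of precomputed per-variant
#'   calls (columns \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{term}), e.g. exported from an external effect predictor; when
#'   supplied the internal caller is bypassed and terms are taken verbatim.
#' @return \code{DataFrame} with one row per mapping variant: \code{key},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{geneset},
#'   \code{most_severe}, \code{broad}, \code{terms} (unique terms across
#'   transcripts), \code{txIds}, \code{n_tx}.  Attributes (in
#'   \code{metadata()}): \code{n_omitted} (variants with zero terms),
#'   \code{n_no_contig}, \code{mismatches} (ref-allele disagreements with
#'   the reference sequence; such variants are skipped).
#' @export
annotateVariants <- function(variants, gs, genome, externalCalls = NULL) {
  if (is.character(variants) && length(variants) == 1L)
    variants <- readVariants(variants)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% colnames(variants)))
  if (!"id" %in% colnames(variants))
    variants$id <- paste0("v", seq_len(nrow(variants)))

  if (!is.null(externalCalls)) {
    key <- paste(externalCalls$chrom, externalCalls$pos, externalCalls$ref,
                 externalCalls$alt, sep = ":")
    sp <- split(externalCalls$term, key)
    vkey <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
                  sep = ":")
    keep <- vkey %in% names(sp)
    vv <- variants[keep, , drop = FALSE]
    ms <- vapply(sp[vkey[keep]], mostSevere, "")
    out <- S4Vectors::DataFrame(
      key = vkey[keep], chrom = vv$chrom, pos = vv$pos, ref = vv$ref,
      alt = vv$alt, geneset = genesetName(gs), most_severe = ms,
      broad = broadClass(ms),
      terms = IRanges::CharacterList(lapply(sp[vkey[keep]], unique)),
      txIds = IRanges::CharacterList(rep(list(character(0)), sum(keep))),
      n_tx = NA_integer_)
    S4Vectors::metadata(out) <- list(n_omitted = sum(!keep),
                                     n_no_contig = 0L,
                                     mismatches = variants[0, , drop = FALSE])
    return(out)
  }

  genome <- .asGenomeChar(genome)
  td <- gs@txData
  spans <- unlist(range(gs@exons), use.names = FALSE)
  txChrom <- as.character(GenomeInfoDb::seqnames(spans))
  txStrand <- as.character(BiocGenerics::strand(spans))
  exSt <- as.list(BiocGenerics::start(gs@exons))
  exEn <- as.list(BiocGenerics::end(gs@exons))
  cdsSorted <- GenomicRanges::sort(gs@cds)
  cdSt <- as.list(BiocGenerics::start(cdsSorted))
  cdEn <- as.list(BiocGenerics::end(cdsSorted))
  txTags <- as.list(td$tags)
  # candidate transcripts per variant via one overlap query (8 bp slop
  # covers the widest splice-region window)
  slop <- GenomicRanges::GRanges(
    txChrom,
    IRanges::IRanges(pmax(1L, BiocGenerics::start(spans) - 8L),
                     BiocGenerics::end(spans) + 8L))

  gsChroms <- unique(txChrom)
  rows <- list()
  nOm <- 0L; nNoContig <- 0L
  mism <- list()
  for (r in seq_len(nrow(variants))) {
    chrom <- variants$chrom[r]
    if (!chrom %in% gsChroms) { nNoContig <- nNoContig + 1L; next }
    nv <- .normalizeVariant(chrom, variants$pos[r], variants$ref[r],
                            variants$alt[r], genome)
    obs <- .genomeSubseq(genome, chrom, nv$pos,
                         nv$pos + nchar(nv$ref) - 1L)
    if (obs != nv$ref) {
      mism[[length(mism) + 1L]] <- data.frame(
        id = variants$id[r], chrom = chrom, pos = nv$pos, ref = nv$ref,
        observed = obs, stringsAsFactors = FALSE)
      next
    }
    span <- .variantSpan(nv$pos, nv$ref, nv$alt)
    vgr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(span[1], span[2]))
    cand <- S4Vectors::queryHits(GenomicRanges::findOverlaps(slop, vgr))
    terms <- character(0); hitTx <- character(0)
    for (ti in cand) {
      tt <- .classifyTx(chrom, nv$pos, nv$ref, nv$alt,
                        exSt[[ti]], exEn[[ti]], cdSt[[ti]], cdEn[[ti]],
                        txStrand[ti], txTags[[ti]], genome)
      if (length(tt)) {
        terms <- c(terms, tt)
        hitTx <- c(hitTx, td$tx_id[ti])
      }
    }
    if (!length(terms)) { nOm <- nOm + 1L; next }
    ms <- mostSevere(unique(terms))
    rows[[length(rows) + 1L]] <- list(
      key = paste(chrom, nv$pos, nv$ref, nv$alt, sep = ":"),
      chrom = chrom, pos = nv$pos, ref = nv$ref, alt = nv$alt,
      most_severe = ms, terms = sort(unique(terms)), txIds = hitTx)
  }
  out <- S4Vectors::DataFrame(
    key = vapply(rows, `[[`, "", "key"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    pos = vapply(rows, function(x) as.integer(x$pos), 0L),
    ref = vapply(rows, `[[`, "", "ref"),
    alt = vapply(rows, `[[`, "", "alt"),
    geneset = rep(genesetName(gs), length(rows)),
    most_severe = vapply(rows, `[[`, "", "most_severe"),
    broad = if (length(rows))
      broadClass(vapply(rows, `[[`, "", "most_severe")) else character(0),
    terms = IRanges::CharacterList(lapply(rows, `[[`, "terms")),
    txIds = IRanges::CharacterList(lapply(rows, `[[`, "txIds")),
    n_tx = vapply(rows, function(x) length(x$txIds), 0L))
  S4Vectors::metadata(out) <- list(
    n_omitted = nOm, n_no_contig = nNoContig,
    mismatches = if (length(mism)) do.call(rbind, mism) else
      data.frame(id = character(0), chrom = character(0), pos = integer(0),
                 ref = character(0), observed = character(0)))
  out
}
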