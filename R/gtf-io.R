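#' @importFrom rtracklayer import export
#' @importFrom GenomeInfoDb seqnames
#' @importFrom utils read.table write.table
NULL

## Default biotype synonym maps.  GENCODE and RefSeq GTF dialects name the
## same concepts differently; parsing normalises onto the package's fixed
## vocabularies.  Users may extend/override via readGeneset() arguments.
.DEFAULT_TX_BIOTYPE_MAP <- c(
  protein_coding           = "protein_coding",
  nonsense_mediated_decay  = "NMD",
  NMD                      = "NMD",
  retained_intron          = "retained_intron",
  processed_transcript     = "processed_transcript"
)

.DEFAULT_LOCUS_BIOTYPE_MAP <- c(
  coding         = "coding",
  protein_coding = "coding",
  lncRNA         = "lncRNA",
  lincRNA        = "lncRNA",
  misc_RNA       = "misc_RNA"
)

.normTxBiotype <- function(x, map = .DEFAULT_TX_BIOTYPE_MAP) {
  out <- unname(map[x])
  out[is.na(out)] <- "other"
  out[is.na(x)] <- "other"
  out
}

.normLocusBiotype <- function(x, map = .DEFAULT_LOCUS_BIOTYPE_MAP) {
  out <- unname(map[x])
  xs <- ifelse(is.na(x), "", x)
  ifelse(!is.na(out), out,
  ifelse(xs == "", "other",
  ifelse(grepl("pseudogene", xs), "pseudogene",
  ifelse(startsWith(xs, "IG_") | xs == "IG", "IG",
  ifelse(startsWith(xs, "TR_") | xs == "TR", "TR", "other")))))
}

#' Read a chromosome-sizes file
#'
#' Two-column whitespace-separated text: chromosome name, length in bp.
#'
#' @param path Path to the file.
#' @return Named integer vector of chromosome lengths (possibly empty).
#' @export
readChromSizes <- function(path) {
  if (!file.exists(path)) stop("chromosome sizes file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(setNames(integer(0), character(0)))
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(fields) < 2))
    stop("chromosome sizes parse error: line ",
         which(lengths(fields) < 2)[1], " has fewer than two columns")
  nm <- vapply(fields, `[`, "", 1L)
  lenRaw <- vapply(fields, `[`, "", 2L)
  if (any(!grepl("^[0-9]+$", lenRaw)))
    stop("chromosome sizes parse error: non-integer length at line ",
         which(!grepl("^[0-9]+$", lenRaw))[1])
  if (anyDuplicated(nm))
    stop("duplicate chromosome name in sizes file: ",
         nm[duplicated(nm)][1])
  len <- as.integer(lenRaw)
  if (any(len <= 0)) stop("chromosome lengths must be positive")
  setNames(len, nm)
}

#' Write a chromosome-sizes file
#'
#' @param sizes Named integer vector.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeChromSizes <- function(sizes, path) {
  writeLines(paste(names(sizes), as.integer(sizes), sep = "\t"), path)
  invisible(path)
}

## Pre-scan of GTF lines for structural problems rtracklayer reports less
## helpfully: wrong field counts and exon/CDS features lacking transcript_id.
.prevalidateGtf <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9L)
      stop("GTF parse error at line ", i, ": expected 9 tab-separated ",
           "fields, found ", length(fields))
    if (fields[3] %in% c("exon", "CDS") &&
        !grepl("transcript_id\\s+\"", fields[9]))
      stop("GTF parse error at line ", i, ": ", fields[3],
           " feature lacks a transcript_id attribute")
  }
  lines
}

## Recover the complete per-transcript tag set from the raw attribute
## columns.  rtracklayer keeps only the last value of repeated keys, but the
## GENCODE dialect repeats `tag "..."`; comma-separated values inside a
## single tag attribute are also honoured.
.collectTags <- function(lines) {
  tags <- list()
  for (ln in lines) {
    if (!nzchar(ln) || startsWith(ln, "#")) next
    attrs <- sub("^([^\t]*\t){8}", "", ln)
    tx <- regmatches(attrs, regexpr('transcript_id\\s+"[^"]*"', attrs))
    if (!length(tx)) next
    tx <- sub('^transcript_id\\s+"([^"]*)"$', "\\1", tx)
    tv <- regmatches(attrs, gregexpr('\\btag\\s+"[^"]*"', attrs))[[1]]
    if (!length(tv)) next
    tv <- sub('^tag\\s+"([^"]*)"$', "\\1", tv)
    tv <- unlist(strsplit(tv, ",", fixed = TRUE))
    tags[[tx]] <- union(tags[[tx]], tv)
  }
  tags
}

.firstNonNA <- function(x) {
  x <- x[!is.na(x)]
  if (length(x)) x[1] else NA_character_
}

#' Read a gene annotation GTF into a Geneset
#'
#' Parses a GTF file (gene/transcript/exon/CDS features) into the package's
#' \code{Geneset} container.  Biotypes are normalised onto the fixed
#' vocabulary via configurable synonym maps, tags (including repeated
#' GENCODE-style \code{tag} attributes) are collected per transcript, and a
#' RefSeq-style accession class is inferred from the transcript id prefix
#' (\code{NM_}/\code{NR_}/\code{XM_}/\code{XR_}).
#'
#' @param path Path to the GTF file.
#' @param name Geneset label.
#' @param chromSizes Optional named integer vector (see
#'   [readChromSizes()]), stored on the object and used by
#'   [validateGeneset()].
#' @param assembly Assembly label.
#' @param txBiotypeMap,locusBiotypeMap Named character synonym maps onto the
#'   internal vocabularies.
#' @param biotypeKeys,locusKeys Attribute keys searched (first match wins)
#'   for transcript and gene biotypes.
#'
#' @return A \code{Geneset}.
#' @export
readGeneset <- function(path, name = basename(path), chromSizes = NULL,
                        assembly = "custom",
                        txBiotypeMap = .DEFAULT_TX_BIOTYPE_MAP,
                        locusBiotypeMap = .DEFAULT_LOCUS_BIOTYPE_MAP,
                        biotypeKeys = c("transcript_type",
                                        "transcript_biotype"),
                        locusKeys = c("gene_type", "gene_biotype")) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- .prevalidateGtf(path)
  content <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(content)) {
    return(Geneset(name,
                   GenomicRanges::GRangesList(setNames(list(), character(0))),
                   assembly = assembly, chromSizes = chromSizes))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  typ <- as.character(mc$type)
  getKey <- function(keys) {
    out <- rep(NA_character_, length(gr))
    for (k in keys)
      if (k %in% colnames(mc)) {
        v <- as.character(mc[[k]])
        out[is.na(out)] <- v[is.na(out)]
      }
    out
  }
  txBio  <- getKey(biotypeKeys)
  locBio <- getKey(locusKeys)
  txid   <- as.character(mc$transcript_id)
  gid    <- as.character(mc$gene_id)

  isExon <- typ == "exon"
  isCds  <- typ == "CDS"
  allTx  <- unique(txid[isExon | isCds])
  if (!length(allTx))
    return(Geneset(name,
                   GenomicRanges::GRangesList(setNames(list(), character(0))),
                   assembly = assembly, chromSizes = chromSizes))

  strip <- function(g) { S4Vectors::mcols(g) <- NULL; g }
  exl <- GenomicRanges::split(strip(gr[isExon]),
                              factor(txid[isExon], levels = allTx))
  exl <- GenomicRanges::sort(exl)
  cdl <- GenomicRanges::split(strip(gr[isCds]),
                              factor(txid[isCds], levels = allTx))
  cdl <- GenomicRanges::sort(cdl)

  # CDS containment check: every CDS base must lie inside the exon union
  if (any(lengths(cdl) > 0)) {
    covered <- sum(IRanges::width(IRanges::intersect(
      IRanges::ranges(cdl), IRanges::ranges(exl))))
    cdsBp <- sum(IRanges::width(IRanges::ranges(cdl)))
    off <- which(covered < cdsBp)
    if (length(off))
      stop("validation error: CDS outside exons for transcript ",
           allTx[off[1]])
  }

  # per-transcript metadata: take the first non-NA value across feature rows
  txGene <- vapply(allTx, function(t)
    .firstNonNA(gid[txid == t & (isExon | isCds)]), "")
  txBioV <- vapply(allTx, function(t) .firstNonNA(txBio[txid == t]), "")
  geneBioByGene <- tapply(locBio, gid, .firstNonNA)
  locBioV <- unname(geneBioByGene[txGene])

  tagList <- .collectTags(lines)
  tags <- IRanges::CharacterList(lapply(allTx, function(t)
    if (is.null(tagList[[t]])) character(0) else tagList[[t]]))

  td <- S4Vectors::DataFrame(
    tx_id = allTx,
    gene_id = txGene,
    biotype = .normTxBiotype(txBioV, txBiotypeMap),
    accession_class = .accessionClass(allTx),
    tags = tags,
    locus_biotype = .normLocusBiotype(locBioV, locusBiotypeMap))

  Geneset(name, exl, cdl, td, assembly = assembly, chromSizes = chromSizes)
}

#' Write a Geneset to GTF
#'
#' Emits gene, transcript, exon and CDS features.  Tags are written as a
#' single comma-separated \code{tag} attribute (re-read losslessly by
#' [readGeneset()]).
#'
#' @param gs A \code{Geneset}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGeneset <- function(gs, path) {
  td <- gs@txData
  ex <- gs@exons
  cd <- gs@cds
  txSpan <- unlist(range(ex), use.names = FALSE)
  txn <- length(ex)

  geneIds <- unique(td$gene_id)
  geneRows <- do.call(c, lapply(geneIds, function(g) {
    sp <- range(unlist(ex[td$gene_id == g], use.names = FALSE))
    sp
  }))
  geneBio <- td$locus_biotype[match(geneIds, td$gene_id)]

  exFlat <- unlist(ex, use.names = FALSE)
  exTx <- rep(td$tx_id, lengths(ex))
  cdFlat <- unlist(cd, use.names = FALSE)
  cdTx <- rep(td$tx_id, lengths(cd))
  # GTF frame: bases to skip at the start of each CDS piece, transcript order
  cdPhase <- unlist(lapply(seq_along(cd), function(i) {
    cc <- cd[[i]]
    if (!length(cc)) return(integer(0))
    w <- BiocGenerics::width(cc)
    if (as.character(BiocGenerics::strand(cc))[1] == "-") w <- rev(w)
    ph <- (3L - cumsum(c(0L, w[-length(w)])) %% 3L) %% 3L
    if (as.character(BiocGenerics::strand(cc))[1] == "-") ph <- rev(ph)
    ph
  }), use.names = FALSE)

  tagStr <- vapply(td$tags, function(t)
    if (length(t)) paste(t, collapse = ",") else NA_character_, "")

  mk <- function(g, type, gene_id, transcript_id = NA_character_,
                 gene_type = NA_character_, transcript_type = NA_character_,
                 tag = NA_character_, phase = NA_integer_) {
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(
      source = "GenesetCompare", type = type, phase = phase,
      gene_id = gene_id, transcript_id = transcript_id,
      gene_type = gene_type, transcript_type = transcript_type, tag = tag)
    g
  }
  rows <- c(
    mk(geneRows, "gene", geneIds, gene_type = geneBio),
    mk(txSpan, "transcript", td$gene_id, td$tx_id,
       gene_type = td$locus_biotype, transcript_type = td$biotype,
       tag = tagStr),
    mk(exFlat, "exon", td$gene_id[match(exTx, td$tx_id)], exTx),
    mk(cdFlat, "CDS", td$gene_id[match(cdTx, td$tx_id)], cdTx,
       phase = cdPhase))
  rtracklayer::export(rows, path, format = "gtf")
  invisible(path)
}

#' Validate a Geneset against its domain invariants
#'
#' Checks, per transcript: exons sorted, non-overlapping and on a single
#' chromosome/strand; CDS contained in the exon union; transcripts without
#' CDS carry a non-coding biotype or a truncation tag.  Per gene: all
#' transcripts on one chromosome.  When chromosome sizes are available,
#' every feature must lie within its chromosome.
#'
#' Violations are returned as data, not raised as conditions.
#'
#' @param gs A \code{Geneset}.
#' @param sizes Named integer chromosome lengths; defaults to the sizes
#'   stored on the object.
#' @return Character vector of violation messages (empty when valid).
#' @export
validateGeneset <- function(gs, sizes = chromSizes(gs)) {
  v <- character(0)
  td <- gs@txData
  for (i in seq_len(nrow(td))) {
    id <- td$tx_id[i]
    e <- gs@exons[[i]]
    if (!length(e)) { v <- c(v, paste0("transcript ", id, ": no exons")); next }
    if (length(unique(as.character(GenomeInfoDb::seqnames(e)))) > 1L ||
        length(unique(as.character(BiocGenerics::strand(e)))) > 1L)
      v <- c(v, paste0("transcript ", id,
                       ": exons span multiple chromosomes/strands"))
    st <- BiocGenerics::start(e); en <- BiocGenerics::end(e)
    if (is.unsorted(st))
      v <- c(v, paste0("transcript ", id, ": exons not sorted"))
    if (length(e) > 1L && any(st[-1] <= en[-length(e)]))
      v <- c(v, paste0("transcript ", id, ": overlapping exons"))
    cdsI <- gs@cds[[i]]
    if (length(cdsI)) {
      notIn <- sum(IRanges::width(IRanges::setdiff(
        IRanges::ranges(cdsI), IRanges::ranges(e))))
      if (notIn > 0)
        v <- c(v, paste0("transcript ", id, ": CDS outside exons"))
      if (length(unique(as.character(GenomeInfoDb::seqnames(cdsI)))) > 1L ||
          !identical(unique(as.character(GenomeInfoDb::seqnames(cdsI))),
                     unique(as.character(GenomeInfoDb::seqnames(e)))))
        v <- c(v, paste0("transcript ", id,
                         ": CDS on different chromosome than exons"))
    } else {
      noncoding <- td$biotype[i] %in% c("retained_intron",
                                        "processed_transcript", "other")
      truncated <- any(td$tags[[i]] %in% c("CDS_start_NF", "CDS_end_NF",
                                           "mRNA_start_NF", "mRNA_end_NF"))
      if (!noncoding && !truncated)
        v <- c(v, paste0("transcript ", id,
                         ": coding biotype without CDS or truncation tag"))
    }
    if (length(sizes)) {
      chr <- as.character(GenomeInfoDb::seqnames(e))[1]
      if (!chr %in% names(sizes))
        v <- c(v, paste0("transcript ", id, ": chromosome ", chr,
                         " absent from sizes table"))
      else if (max(en) > sizes[[chr]])
        v <- c(v, paste0("transcript ", id,
                         ": exon end beyond chromosome length"))
      if (min(st) < 1L)
        v <- c(v, paste0("transcript ", id, ": exon start below 1"))
    }
  }
  for (g in unique(td$gene_id)) {
    e <- unlist(gs@exons[td$gene_id == g], use.names = FALSE)
    if (length(unique(as.character(GenomeInfoDb::seqnames(e)))) > 1L)
      v <- c(v, paste0("gene ", g, ": transcripts on multiple chromosomes"))
  }
  v
}
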