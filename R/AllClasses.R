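#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges CharacterList
#' @import GenomicRanges
NULL

#' Geneset: a transcript-level gene annotation set
#'
#' A \code{Geneset} holds a complete transcript-level annotation of a genome
#' (for example a GENCODE-like or RefSeq-like annotation): per-transcript
#' exon and CDS ranges plus transcript- and locus-level metadata.  It is the
#' object every analysis stage of the package consumes.
#'
#' @slot name Label for the geneset (e.g. \code{"setA"}).
#' @slot assembly Assembly label (informational).
#' @slot exons \code{GRangesList}, one element per transcript, exons in
#'   genomic order, non-overlapping, all on one chromosome and strand.
#' @slot cds \code{GRangesList} parallel to \code{exons}; may contain
#'   zero-length elements for non-coding transcripts.  CDS intervals are
#'   stored verbatim as annotated (no stop-codon extension is applied).
#' @slot txData \code{DataFrame} with one row per transcript: \code{tx_id},
#'   \code{gene_id}, \code{biotype} (one of \code{protein_coding},
#'   \code{NMD}, \code{retained_intron}, \code{processed_transcript},
#'   \code{other}), \code{accession_class} (\code{NM}, \code{NR}, \code{XM},
#'   \code{XR} or \code{none}), \code{tags} (a \code{CharacterList} of tags
#'   such as \code{basic} or \code{CDS_start_NF}) and \code{locus_biotype}
#'   (one of \code{coding}, \code{lncRNA}, \code{pseudogene}, \code{IG},
#'   \code{TR}, \code{misc_RNA}, \code{other}).
#' @slot chromSizes Named integer vector of chromosome lengths (possibly
#'   empty when no sizes file was supplied).
#'
#' @seealso [readGeneset()], [validateGeneset()], [applySubsetRule()]
#' @exportClass Geneset
setClass("Geneset",
  slots = c(
    name       = "character",
    assembly   = "character",
    exons      = "GRangesList",
    cds        = "GRangesList",
    txData     = "DataFrame",
    chromSizes = "integer"
  )
)

.TX_BIOTYPES    <- c("protein_coding", "NMD", "retained_intron",
                     "processed_transcript", "other")
.LOCUS_BIOTYPES <- c("coding", "lncRNA", "pseudogene", "IG", "TR",
                     "misc_RNA", "other")
.ACC_CLASSES    <- c("NM", "NR", "XM", "XR", "none")
.KNOWN_TAGS     <- c("basic", "CDS_start_NF", "CDS_end_NF",
                     "mRNA_start_NF", "mRNA_end_NF")

setValidity("Geneset", function(object) {
  # hard structural checks only; domain-level checks live in validateGeneset()
  n <- length(object@exons)
  if (length(object@cds) != n)
    return("exons and cds must have one element per transcript")
  if (nrow(object@txData) != n)
    return("txData must have one row per transcript")
  need <- c("tx_id", "gene_id", "biotype", "accession_class", "tags",
            "locus_biotype")
  if (!all(need %in% colnames(object@txData)))
    return(paste("txData lacks columns:",
                 paste(setdiff(need, colnames(object@txData)), collapse = ", ")))
  if (anyDuplicated(object@txData$tx_id))
    return("transcript ids must be unique across the geneset")
  TRUE
})

#' Construct a Geneset
#'
#' @param name Geneset label.
#' @param exons \code{GRangesList} of exons, one element per transcript,
#'   named by transcript id.
#' @param cds \code{GRangesList} of CDS intervals parallel to \code{exons}
#'   (zero-length elements for non-coding transcripts).  If missing, all
#'   transcripts are treated as non-coding.
#' @param txData \code{DataFrame} or data.frame of transcript metadata (see
#'   the class documentation).  Missing columns are filled with defaults.
#' @param assembly Assembly label.
#' @param chromSizes Named integer vector of chromosome lengths, or NULL.
#'
#' @return A \code{Geneset} object.
#' @export
Geneset <- function(name, exons, cds = NULL, txData = NULL,
                    assembly = "custom", chromSizes = NULL) {
  stopifnot(is(exons, "GRangesList"))
  n <- length(exons)
  txid <- names(exons)
  if (is.null(txid)) stop("exons GRangesList must be named by transcript id")
  if (is.null(cds)) {
    cds <- GenomicRanges::GRangesList(rep(list(GenomicRanges::GRanges()), n))
    names(cds) <- txid
  }
  cds <- cds[txid]
  if (is.null(txData)) txData <- S4Vectors::DataFrame(tx_id = txid)
  txData <- S4Vectors::DataFrame(txData)
  if (!"tx_id" %in% colnames(txData)) txData$tx_id <- txid
  txData <- txData[match(txid, txData$tx_id), , drop = FALSE]
  if (!"gene_id" %in% colnames(txData)) txData$gene_id <- txData$tx_id
  if (!"biotype" %in% colnames(txData))
    txData$biotype <- rep("protein_coding", n)
  if (!"accession_class" %in% colnames(txData))
    txData$accession_class <- .accessionClass(txData$tx_id)
  if (!"tags" %in% colnames(txData))
    txData$tags <- IRanges::CharacterList(rep(list(character(0)), n))
  if (!is(txData$tags, "CharacterList"))
    txData$tags <- IRanges::CharacterList(txData$tags)
  if (!"locus_biotype" %in% colnames(txData))
    txData$locus_biotype <- rep("coding", n)
  rownames(txData) <- NULL
  new("Geneset",
      name = as.character(name), assembly = as.character(assembly),
      exons = exons, cds = cds, txData = txData,
      chromSizes = .asChromSizes(chromSizes))
}

.asChromSizes <- function(chromSizes) {
  if (is.null(chromSizes)) return(setNames(integer(0), character(0)))
  sz <- as.integer(chromSizes)
  names(sz) <- names(chromSizes)
  sz
}

## accession class from a transcript id prefix (RefSeq convention)
.accessionClass <- function(ids) {
  cls <- rep("none", length(ids))
  for (p in c("NM", "NR", "XM", "XR"))
    cls[startsWith(ids, paste0(p, "_"))] <- p
  cls
}

## ---- accessors -----------------------------------------------------------

#' @describeIn Geneset Geneset label.
#' @param x,object A \code{Geneset}.
#' @export
genesetName <- function(x) x@name

#' @describeIn Geneset Per-transcript exon ranges (\code{GRangesList}).
#' @export
exonRanges <- function(x) x@exons

#' @describeIn Geneset Per-transcript CDS ranges (\code{GRangesList}).
#' @export
cdsRanges <- function(x) x@cds

#' @describeIn Geneset Transcript metadata table (\code{DataFrame}).
#' @export
transcriptTable <- function(x) x@txData

#' @describeIn Geneset Named integer vector of chromosome sizes.
#' @export
chromSizes <- function(x) x@chromSizes

#' @describeIn Geneset Number of transcripts.
#' @export
setMethod("length", "Geneset", function(x) length(x@exons))

setMethod("show", "Geneset", function(object) {
  td <- object@txData
  nc <- sum(lengths(object@cds) > 0)
  cat("Geneset object \"", object@name, "\" (assembly: ", object@assembly,
      ")\n", sep = "")
  cat("  ", length(unique(td$gene_id)), " genes; ", nrow(td),
      " transcripts (", nc, " coding)\n", sep = "")
  bt <- table(td$biotype)
  cat("  biotypes:", paste(names(bt), as.integer(bt), sep = "=",
                           collapse = ", "), "\n")
  if (length(object@chromSizes))
    cat("  chromSizes for", length(object@chromSizes), "chromosome(s)\n")
})

#' Subset a Geneset by transcript ids
#'
#' @param gs A \code{Geneset}.
#' @param txIds Character vector of transcript ids to keep.
#' @return A \code{Geneset} containing only the requested transcripts.
#' @export
keepTranscripts <- function(gs, txIds) {
  keep <- gs@txData$tx_id %in% txIds
  initialize(gs,
             exons = gs@exons[keep],
             cds = gs@cds[keep],
             txData = gs@txData[keep, , drop = FALSE])
}

#' FeaturePartition: shared/unique partition of annotation features
#'
#' Result of comparing one feature kind (transcripts, translations or exons)
#' between two genesets: the equivalence keys present in both sets, only in
#' the first, and only in the second.
#'
#' @slot kind One of \code{"transcript"}, \code{"translation"},
#'   \code{"exon"}.
#' @slot nameA,nameB Labels of the compared genesets.
#' @slot shared,uniqueA,uniqueB Character vectors of equivalence keys.
#' @slot members Optional \code{DataFrame} mapping keys to member ids.
#'
#' @exportClass FeaturePartition
setClass("FeaturePartition",
  slots = c(kind = "character", nameA = "character", nameB = "character",
            shared = "character", uniqueA = "character",
            uniqueB = "character", members = "DataFrame"))

#' @describeIn FeaturePartition Named integer vector
#'   \code{c(shared, unique_A, unique_B)}.
#' @param x,object A \code{FeaturePartition}.
#' @export
partitionCounts <- function(x) {
  c(shared = length(x@shared), unique_A = length(x@uniqueA),
    unique_B = length(x@uniqueB))
}

#' @describeIn FeaturePartition Accessor for the key lists; \code{which} is
#'   one of \code{"shared"}, \code{"uniqueA"}, \code{"uniqueB"}.
#' @param which Which side of the partition to return.
#' @export
partitionKeys <- function(x, which = c("shared", "uniqueA", "uniqueB")) {
  slot(x, match.arg(which))
}

setMethod("show", "FeaturePartition", function(object) {
  cnt <- partitionCounts(object)
  cat("FeaturePartition (", object@kind, "): ", object@nameA, " vs ",
      object@nameB, "\n", sep = "")
  cat("  shared: ", cnt[["shared"]], "; unique to ", object@nameA, ": ",
      cnt[["unique_A"]], "; unique to ", object@nameB, ": ",
      cnt[["unique_B"]], "\n", sep = "")
})
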