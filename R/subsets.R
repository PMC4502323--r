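#' Restrict a Geneset to protein-coding loci
#'
#' Two conventions are supported.  \code{gencode_like} keeps genes whose
#' locus biotype is \code{coding} and drops lncRNA, pseudogene, IG and TR
#' loci.  \code{refseq_like} additionally keeps \code{misc_RNA} loci where
#' at least one transcript at the locus carries a CDS (the convention used
#' when importing curated RefSeq annotation, where coding products can sit
#' at loci labelled misc_RNA).
#'
#' @param gs A \code{Geneset}.
#' @param side \code{"gencode_like"} or \code{"refseq_like"}.
#' @return The locus-filtered \code{Geneset}.
#' @export
selectProteinCodingLoci <- function(gs,
                                    side = c("gencode_like", "refseq_like")) {
  side <- match.arg(side)
  td <- gs@txData
  keepGene <- unique(td$gene_id[td$locus_biotype == "coding"])
  if (side == "refseq_like") {
    misc <- td$locus_biotype == "misc_RNA"
    hasCdsTx <- lengths(gs@cds) > 0
    keepGene <- union(keepGene, unique(td$gene_id[misc & hasCdsTx]))
  }
  keepTranscripts(gs, td$tx_id[td$gene_id %in% keepGene])
}

.BUILTIN_RULES <- c("comprehensive", "basic", "nxr", "nr")

#' Apply a geneset subset rule
#'
#' Derives one of the four standard compared genesets from a locus-filtered
#' annotation:
#' \describe{
#'   \item{comprehensive}{All transcripts at the retained loci.}
#'   \item{basic}{Full-length protein-coding transcripts only: tagged
#'     \code{basic}, or (equivalently) biotype \code{protein_coding} with a
#'     non-empty CDS and neither \code{CDS_start_NF} nor \code{CDS_end_NF};
#'     NMD, retained_intron and processed_transcript biotypes are excluded.}
#'   \item{nxr}{All NM/NR/XM/XR-accessioned transcripts in genes containing
#'     at least one curated (NM/NR) transcript.}
#'   \item{nr}{Curated NM/NR transcripts only.}
#' }
#' Genes left with zero transcripts are dropped.  A custom rule may be given
#' as a function \code{function(txData, hasCds)} returning a logical keep
#' vector over transcripts.
#'
#' @param gs A locus-filtered \code{Geneset}.
#' @param rule Rule name (one of \code{"comprehensive"}, \code{"basic"},
#'   \code{"nxr"}, \code{"nr"}) or a predicate function.
#' @return The filtered \code{Geneset}.
#' @export
applySubsetRule <- function(gs, rule = "comprehensive") {
  td <- gs@txData
  hasCds <- lengths(gs@cds) > 0
  if (is.function(rule)) {
    keep <- rule(td, hasCds)
  } else {
    if (!is.character(rule) || length(rule) != 1L ||
        !rule %in% .BUILTIN_RULES)
      stop("unknown subset rule: ",
           paste(deparse(rule), collapse = ""),
           " (expected one of ", paste(.BUILTIN_RULES, collapse = ", "),
           " or a predicate function)")
    keep <- switch(rule,
      comprehensive = rep(TRUE, nrow(td)),
      basic = {
        nf <- vapply(td$tags, function(t)
          any(t %in% c("CDS_start_NF", "CDS_end_NF")), NA)
        tagged <- vapply(td$tags, function(t) "basic" %in% t, NA)
        structural <- td$biotype == "protein_coding" & hasCds & !nf
        excluded <- td$biotype %in% c("NMD", "retained_intron",
                                      "processed_transcript")
        (tagged | structural) & !excluded
      },
      nxr = {
        acc <- td$accession_class
        knownGenes <- unique(td$gene_id[acc %in% c("NM", "NR")])
        acc %in% c("NM", "NR", "XM", "XR") & td$gene_id %in% knownGenes
      },
      nr = td$accession_class %in% c("NM", "NR"))
  }
  keepTranscripts(gs, td$tx_id[keep])
}

#' Serialise/deserialise subset rules
#'
#' Built-in rules round-trip through a small JSON config so that pipeline
#' runs are reproducible from a file.
#'
#' @param rules Named character vector or list of rule names per side, e.g.
#'   \code{list(A = "comprehensive", B = "nxr")}.
#' @param path JSON path.
#' @return \code{writeSubsetRules}: invisibly, \code{path};
#'   \code{readSubsetRules}: the rules list.
#' @export
writeSubsetRules <- function(rules, path) {
  jsonlite::write_json(as.list(rules), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSubsetRules
#' @export
readSubsetRules <- function(path) {
  rules <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(unlist(rules), .BUILTIN_RULES)
  if (length(bad)) stop("unknown subset rule in config: ", bad[1])
  as.list(rules)
}
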