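#' Classify exons or introns by geneset ownership
#'
#' Builds the per-transcript redundant feature complement (exons, or introns
#' derived from consecutive exon pairs) of two genesets and labels every
#' feature occurrence by ownership: present only in the first geneset
#' (\code{A_only}), only in the second (\code{B_only}), or in both
#' (\code{common}).  Feature identity is exact
#' (chromosome, strand, start, end) equality.  Exon occurrences carry a
#' terminal flag (first or last exon in the source transcript).
#'
#' @param A,B Locus-filtered \code{Geneset} objects.
#' @param kind \code{"exon"} or \code{"intron"}.
#' @return data.frame with one row per feature occurrence from either
#'   geneset: \code{geneset}, \code{tx_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand}, \code{kind}, \code{terminal}, \code{label}.
#' @export
classifyFeatures <- function(A, B, kind = c("exon", "intron")) {
  kind <- match.arg(kind)
  featOf <- function(gs) {
    ex <- gs@exons
    n <- lengths(ex)
    if (kind == "exon") {
      flat <- unlist(ex, use.names = FALSE)
      idx <- unlist(lapply(n, seq_len))
      data.frame(
        geneset = genesetName(gs),
        tx_id = rep(gs@txData$tx_id, n),
        chrom = as.character(GenomeInfoDb::seqnames(flat)),
        start = BiocGenerics::start(flat),
        end = BiocGenerics::end(flat),
        strand = as.character(BiocGenerics::strand(flat)),
        kind = "exon",
        terminal = idx == 1L | idx == rep(n, n),
        stringsAsFactors = FALSE)
    } else {
      rows <- lapply(which(n > 1L), function(i) {
        e <- ex[[i]]
        data.frame(
          geneset = genesetName(gs),
          tx_id = gs@txData$tx_id[i],
          chrom = as.character(GenomeInfoDb::seqnames(e))[1],
          start = BiocGenerics::end(e)[-length(e)] + 1L,
          end = BiocGenerics::start(e)[-1] - 1L,
          strand = as.character(BiocGenerics::strand(e))[1],
          kind = "intron",
          terminal = FALSE,
          stringsAsFactors = FALSE)
      })
      if (!length(rows))
        return(data.frame(geneset = character(0), tx_id = character(0),
                          chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          kind = character(0), terminal = logical(0),
                          stringsAsFactors = FALSE))
      do.call(rbind, rows)
    }
  }
  fa <- featOf(A); fb <- featOf(B)
  keyOf <- function(f) paste(f$chrom, f$strand, f$start, f$end, sep = "|")
  inA <- unique(keyOf(fa)); inB <- unique(keyOf(fb))
  all <- rbind(fa, fb)
  k <- keyOf(all)
  all$label <- ifelse(k %in% inA & k %in% inB, "common",
               ifelse(k %in% inA, "A_only", "B_only"))
  all
}

#' Mean read density over an interval
#'
#' Averages a per-base coverage track (e.g. from a bedGraph file) over the
#' nucleotide span of an interval, in reads per bp.  Positions absent from
#' the track read as zero.
#'
#' @param track \code{GRanges} with a numeric \code{score} column (as
#'   returned by [readCoverageTrack()]).
#' @param iv \code{GRanges} of intervals (one or more).
#' @return Numeric vector of mean densities, one per interval.
#' @export
intervalDensity <- function(track, iv) {
  if (any(BiocGenerics::width(iv) == 0L))
    stop("intervalDensity() is undefined for zero-length intervals")
  hits <- GenomicRanges::findOverlaps(iv, track, ignore.strand = TRUE)
  ov <- GenomicRanges::pintersect(
    iv[S4Vectors::queryHits(hits)], track[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE)
  contrib <- as.numeric(BiocGenerics::width(ov)) *
    track$score[S4Vectors::subjectHits(hits)]
  sums <- rep(0, length(iv))
  agg <- tapply(contrib, S4Vectors::queryHits(hits), sum)
  sums[as.integer(names(agg))] <- as.numeric(agg)
  sums / as.numeric(BiocGenerics::width(iv))
}

#' Read / write a coverage track
#'
#' Plain-text bedGraph is the supported interchange format for per-base
#' read-density tracks.
#'
#' @param path bedGraph path.
#' @return \code{GRanges} with a \code{score} column.
#' @export
readCoverageTrack <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' @rdname readCoverageTrack
#' @param track \code{GRanges} with \code{score}.
#' @export
writeCoverageTrack <- function(track, path) {
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}

#' Per-feature expression summaries across samples
#'
#' Computes, for every feature, the mean read density in each sample track,
#' and summarises across samples: the maximum (expression in the sample with
#' highest expression), the median, and the mean.
#'
#' @param features \code{GRanges} of features, or a data.frame with
#'   \code{chrom}, \code{start}, \code{end}, \code{strand} columns (as from
#'   [classifyFeatures()]).
#' @param tracks List of coverage tracks (each a \code{GRanges} with
#'   \code{score}); one per sample.
#' @return \code{DataFrame} with \code{density} (numeric matrix features x
#'   samples), \code{max_density}, \code{median_density},
#'   \code{mean_density}.
#' @export
featureExpression <- function(features, tracks) {
  if (!length(tracks)) stop("featureExpression() requires >= 1 track")
  if (is.data.frame(features))
    features <- GenomicRanges::GRanges(
      features$chrom, IRanges::IRanges(features$start, features$end),
      strand = features$strand)
  dens <- vapply(tracks, function(tr) intervalDensity(tr, features),
                 numeric(length(features)))
  dens <- matrix(dens, nrow = length(features))
  out <- S4Vectors::DataFrame(
    max_density = apply(dens, 1, max),
    median_density = apply(dens, 1, stats::median),
    mean_density = rowMeans(dens))
  out$density <- dens
  out
}

#' Empirical cumulative distribution of expression values
#'
#' Right-continuous ECDF over per-feature read densities.  The fraction at
#' threshold 0 equals the proportion of zero-expression (silent) features.
#'
#' @param values Non-negative finite numeric vector (length >= 1).
#' @return data.frame with \code{threshold} (sorted unique values) and
#'   \code{fraction} (cumulative proportion <= threshold).
#' @export
expressionEcdf <- function(values) {
  if (!length(values)) stop("expressionEcdf() requires a non-empty input")
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative")
  thr <- sort(unique(values))
  data.frame(threshold = thr,
             fraction = vapply(thr, function(t) mean(values <= t), 0))
}
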