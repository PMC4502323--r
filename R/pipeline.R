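#' Run configuration for a full comparison
#'
#' A plain list describing one end-to-end run; serialisable to/from JSON so
#' that runs are reproducible from a config file.
#'
#' @param gtfA,gtfB Paths to the two annotation GTFs.
#' @param ruleA,ruleB Subset rule per side (see [applySubsetRule()]).
#' @param sideA,sideB Locus-selection convention per side (see
#'   [selectProteinCodingLoci()]).
#' @param chromSizes Path to a chromosome-sizes file (required for coverage
#'   percentages).
#' @param vcf Optional VCF path; when absent the variant stages are skipped.
#' @param fasta Reference FASTA path (required with \code{vcf}).
#' @param tracks Optional character vector of bedGraph paths; when absent
#'   the expression stage is skipped.
#' @param granularity Concordance granularity (see [classifyVariants()]).
#' @param outDir Output directory for report tables.
#' @return List of class \code{RunConfig}.
#' @export
runConfig <- function(gtfA, gtfB, ruleA = "comprehensive", ruleB = "nxr",
                      sideA = "gencode_like", sideB = "refseq_like",
                      chromSizes = NULL, vcf = NULL, fasta = NULL,
                      tracks = NULL, granularity = "term",
                      outDir = NULL) {
  cfg <- list(gtfA = gtfA, gtfB = gtfB, ruleA = ruleA, ruleB = ruleB,
              sideA = sideA, sideB = sideB, chromSizes = chromSizes,
              vcf = vcf, fasta = fasta, tracks = tracks,
              granularity = granularity, outDir = outDir)
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' @rdname runConfig
#' @param cfg A \code{RunConfig}.
#' @param path JSON path.
#' @export
writeRunConfig <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg)[!vapply(cfg, is.null, NA)], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(runConfig, cfg)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.round1 <- function(x) round(x, 1)

#' Run the full geneset-comparison pipeline
#'
#' Orchestrates subset selection, structural comparison, variant
#' consequence annotation and concordance, and exon/intron expression
#' summaries, as configured.  Emits one JSON summary plus TSV report tables
#' to \code{outDir} when set; always returns the result bundle.  Percentages
#' in the reports are rounded to one decimal; counts are exact.
#'
#' @param cfg A \code{RunConfig} (or path to a config JSON).
#' @return List with \code{genesets}, \code{partitions}, \code{locusStats},
#'   \code{coverage}, \code{concordance} (or NULL when skipped),
#'   \code{expression} (or NULL), \code{summary} (the JSON-ready summary
#'   list), and \code{files} when written.
#' @export
runFullComparison <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- readRunConfig(cfg)
  sizes <- if (!is.null(cfg$chromSizes)) readChromSizes(cfg$chromSizes)
           else NULL
  message("stage: load")
  A <- readGeneset(cfg$gtfA, name = "A", chromSizes = sizes)
  B <- readGeneset(cfg$gtfB, name = "B", chromSizes = sizes)
  message("stage: subset")
  A <- applySubsetRule(selectProteinCodingLoci(A, cfg$sideA), cfg$ruleA)
  B <- applySubsetRule(selectProteinCodingLoci(B, cfg$sideB), cfg$ruleB)

  message("stage: compare")
  parts <- list(transcripts = compareTranscripts(A, B),
                translations = compareTranslations(A, B),
                exons = compareExons(A, B))
  locus <- list(A = perLocusStats(A), B = perLocusStats(B))
  coverage <- if (!is.null(sizes))
    list(A = genomicCoverage(uniqueExonSet(A), sizes),
         B = genomicCoverage(uniqueExonSet(B), sizes)) else NULL

  concord <- NULL
  if (!is.null(cfg$vcf)) {
    if (is.null(cfg$fasta))
      stop("stage annotate failed: a reference FASTA is required with a VCF")
    message("stage: annotate")
    annA <- annotateVariants(cfg$vcf, A, cfg$fasta)
    annB <- annotateVariants(cfg$vcf, B, cfg$fasta)
    message("stage: concord")
    records <- classifyVariants(annA, annB, cfg$granularity)
    concord <- list(annA = annA, annB = annB, records = records,
                    summary = concordanceSummary(records))
  }

  expr <- NULL
  if (!is.null(cfg$tracks) && length(cfg$tracks)) {
    message("stage: express")
    trks <- lapply(cfg$tracks, readCoverageTrack)
    expr <- list()
    for (kind in c("exon", "intron")) {
      feats <- classifyFeatures(A, B, kind)
      if (!nrow(feats)) next
      fx <- featureExpression(feats, trks)
      ecdfs <- lapply(split(seq_len(nrow(feats)), feats$label), function(i)
        list(max = expressionEcdf(fx$max_density[i]),
             median = expressionEcdf(fx$median_density[i])))
      expr[[kind]] <- list(features = feats, expression = fx,
                           ecdf = ecdfs)
    }
  }

  summary <- list(
    genesets = list(A = list(n_tx = length(A)), B = list(n_tx = length(B))),
    partitions = lapply(parts, partitionCounts),
    locus_stats = lapply(locus, function(l)
      lapply(l[c("mean_transcripts", "mean_translations",
                 "mean_unique_exons")], .round1)),
    coverage = if (!is.null(coverage)) lapply(coverage, function(cv)
      list(summed_bp = cv$summed_bp[cv$strand == "combined"],
           percent_summed = .round1(
             cv$percent_summed[cv$strand == "combined"]))) else NULL,
    concordance = if (!is.null(concord)) {
      ov <- concord$summary$overall
      setNames(as.list(.round1(ov$percent)), ov$status)
    } else "skipped",
    expression = if (!is.null(expr)) lapply(expr, function(e)
      lapply(split(e$expression$median_density, e$features$label),
             function(v) .round1(mean(v == 0) * 100))) else "skipped")

  files <- NULL
  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    od <- cfg$outDir
    files <- c(
      partitions = .writeTsv(data.frame(
        kind = names(parts),
        do.call(rbind, lapply(parts, partitionCounts))),
        file.path(od, "partitions.tsv")),
      locus_stats = .writeTsv(data.frame(
        geneset = names(locus),
        do.call(rbind, lapply(locus, function(l)
          vapply(l[c("mean_transcripts", "mean_translations",
                     "mean_unique_exons")], .round1, 0)))),
        file.path(od, "locus_stats.tsv")))
    if (!is.null(coverage))
      files <- c(files, coverage = .writeTsv(
        cbind(geneset = rep(names(coverage), each = 3L),
              do.call(rbind, coverage)),
        file.path(od, "coverage.tsv")))
    if (!is.null(concord)) {
      files <- c(files,
        concordance_records = .writeTsv(concord$records,
          file.path(od, "concordance_records.tsv")),
        concordance_by_class = .writeTsv(concord$summary$by_class,
          file.path(od, "concordance_by_class.tsv")),
        percent_nonconcordant = .writeTsv(
          transform(concord$summary$percent_nonconcordant,
                    percent_nonconcordant =
                      .round1(percent_nonconcordant)),
          file.path(od, "percent_nonconcordant.tsv")))
    }
    if (!is.null(expr)) {
      for (kind in names(expr)) {
        ec <- expr[[kind]]$ecdf
        tab <- do.call(rbind, lapply(names(ec), function(lb)
          cbind(label = lb, stat = rep(c("max", "median"),
                                       c(nrow(ec[[lb]]$max),
                                         nrow(ec[[lb]]$median))),
                rbind(ec[[lb]]$max, ec[[lb]]$median))))
        files <- c(files, .writeTsv(tab,
          file.path(od, paste0("ecdf_", kind, ".tsv"))))
      }
    }
    jsonlite::write_json(summary, file.path(od, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, summary = file.path(od, "summary.json"))
  }

  list(genesets = list(A = A, B = B), partitions = parts,
       locusStats = locus, coverage = coverage, concordance = concord,
       expression = expr, summary = summary, files = files)
}
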