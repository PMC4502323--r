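#' Classify variant annotation across two genesets
#'
#' Joins two per-geneset annotation tables (from [annotateVariants()]) by
#' variant and assigns each variant mapping to at least one geneset a
#' status: \code{concordant} (annotated in both, equal at the chosen
#' granularity), \code{discordant} (annotated in both, unequal), or
#' \code{unique_A}/\code{unique_B} (annotated in only one geneset).
#'
#' @param annA,annB Annotation tables from [annotateVariants()].
#' @param granularity \code{"term"} compares the selected most-severe term;
#'   \code{"broad"} compares broad classes; \code{"termset"} compares the
#'   full set of terms collected across transcripts.
#' @return data.frame with one row per variant: \code{key}, \code{status},
#'   \code{term_A}, \code{term_B}, \code{broad_A}, \code{broad_B} and
#'   \code{class} (the broad-class stratum: the more severe of the
#'   available broad classes).
#' @export
classifyVariants <- function(annA, annB,
                             granularity = c("term", "broad", "termset")) {
  granularity <- match.arg(granularity)
  keys <- union(annA$key, annB$key)
  ia <- match(keys, annA$key)
  ib <- match(keys, annB$key)
  termA <- ifelse(is.na(ia), NA_character_, annA$most_severe[ia])
  termB <- ifelse(is.na(ib), NA_character_, annB$most_severe[ib])
  broadA <- ifelse(is.na(ia), NA_character_, annA$broad[ia])
  broadB <- ifelse(is.na(ib), NA_character_, annB$broad[ib])
  eq <- switch(granularity,
    term = termA == termB,
    broad = broadA == broadB,
    termset = vapply(seq_along(keys), function(i) {
      if (is.na(ia[i]) || is.na(ib[i])) return(NA)
      setequal(annA$terms[[ia[i]]], annB$terms[[ib[i]]])
    }, NA))
  status <- ifelse(is.na(ia), "unique_B",
            ifelse(is.na(ib), "unique_A",
            ifelse(eq, "concordant", "discordant")))
  # stratify by the more severe of the available broad classes
  ra <- ifelse(is.na(broadA), 5L, .broadRank(broadA))
  rb <- ifelse(is.na(broadB), 5L, .broadRank(broadB))
  cls <- ifelse(pmin(ra, rb) == ra, broadA, broadB)
  cls[is.na(broadA)] <- broadB[is.na(broadA)]
  cls[is.na(broadB)] <- broadA[is.na(broadB)]
  data.frame(key = keys, status = status, term_A = termA, term_B = termB,
             broad_A = broadA, broad_B = broadB, class = cls,
             stringsAsFactors = FALSE)
}

.STATUS_LEVELS <- c("concordant", "discordant", "unique_A", "unique_B")
.BROAD_LEVELS <- c("LoF", "CDS", "splice", "other")

#' Summarise variant concordance
#'
#' Aggregates per-variant concordance records into the standard report
#' tables: overall status counts and percentages; counts by broad class and
#' status; within-status class proportions; percent non-concordant (unique
#' plus discordant) per broad class; and, among non-concordant LoF, missense
#' and synonymous variants, the proportion contributed by each geneset.
#'
#' @param records data.frame from [classifyVariants()].
#' @return List with elements \code{overall} (status, n, percent),
#'   \code{by_class} (class x status counts),
#'   \code{class_proportions} (within-status class proportions),
#'   \code{percent_nonconcordant} (per class), and \code{contributions}
#'   (per category LoF/missense/synonymous: side shares among
#'   non-concordant variants), plus \code{n_variants}.
#' @export
concordanceSummary <- function(records) {
  n <- nrow(records)
  statusF <- factor(records$status, levels = .STATUS_LEVELS)
  overall <- data.frame(
    status = .STATUS_LEVELS,
    n = as.integer(table(statusF)),
    stringsAsFactors = FALSE)
  overall$percent <- if (n) 100 * overall$n / n else 0

  classF <- factor(records$class, levels = .BROAD_LEVELS)
  byClass <- as.data.frame.matrix(table(classF, statusF))
  byClass <- cbind(class = rownames(byClass), byClass,
                   stringsAsFactors = FALSE)
  rownames(byClass) <- NULL

  classProp <- byClass
  for (s in .STATUS_LEVELS) {
    tot <- sum(byClass[[s]])
    classProp[[s]] <- if (tot) 100 * byClass[[s]] / tot else 0
  }

  nonconc <- records$status != "concordant"
  pctNon <- vapply(.BROAD_LEVELS, function(cl) {
    sel <- !is.na(records$class) & records$class == cl
    if (!sum(sel)) return(0)
    100 * sum(nonconc & sel) / sum(sel)
  }, 0)
  pctNon <- data.frame(class = .BROAD_LEVELS,
                       percent_nonconcordant = unname(pctNon),
                       stringsAsFactors = FALSE)

  # side contributions among non-concordant LoF / missense / synonymous:
  # a side contributes a variant when its own call is in the category and
  # the variant is non-concordant (discordant from that side's perspective,
  # or unique to that side).
  contrib <- lapply(list(LoF = function(t) !is.na(t) & broadClass0(t) == "LoF",
                         missense = function(t) !is.na(t) & t == "missense",
                         synonymous = function(t) !is.na(t) &
                           t == "synonymous"),
    function(pred) {
      aSel <- nonconc & records$status != "unique_B" & pred(records$term_A)
      bSel <- nonconc & records$status != "unique_A" & pred(records$term_B)
      nA <- sum(aSel); nB <- sum(bSel)
      tot <- nA + nB
      c(n_A = nA, n_B = nB,
        percent_A = if (tot) 100 * nA / tot else 0,
        percent_B = if (tot) 100 * nB / tot else 0)
    })
  contrib <- data.frame(category = names(contrib),
                        do.call(rbind, contrib),
                        row.names = NULL, stringsAsFactors = FALSE)

  list(n_variants = n, overall = overall, by_class = byClass,
       class_proportions = classProp, percent_nonconcordant = pctNon,
       contributions = contrib)
}

## broadClass that tolerates NA (used on possibly-absent side terms)
broadClass0 <- function(term) {
  out <- rep(NA_character_, length(term))
  ok <- !is.na(term)
  out[ok] <- broadClass(term[ok])
  out
}
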