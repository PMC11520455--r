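#' PSL alignment score
#'
#' The alignment score used to rank paralogous alignments:
#' `matches + repMatches - misMatches - qNumInsert - tNumInsert`.
#' Because assembled-fragment aggregates are sums over their member
#' records, the score is linear: the score of a merged fragment equals the
#' sum of its members' scores. May be negative.
#'
#' @param x a [PslAlignments-class], or any data.frame with `matches`,
#'   `repMatches`, `misMatches`, `qNumInsert`, `tNumInsert` columns (e.g.
#'   an assembled-fragment table).
#' @return integer vector of scores, one per record / row.
#' @examples
#' df <- data.frame(matches = 100, repMatches = 0, misMatches = 5,
#'                  qNumInsert = 2, tNumInsert = 1)
#' pslScore(df)   # 92
#' @export
pslScore <- function(x) {
  df <- if (is(x, "PslAlignments")) pslRecords(x) else x
  as.integer(df$matches + df$repMatches - df$misMatches -
             df$qNumInsert - df$tNumInsert)
}

#' Infer the parent and daughter of a duplicate gene pair
#'
#' For each paralog, the gene span is used as a query: per partner species
#' the liftover records overlapping it are assembled under the gap value
#' and the primary fragment's aggregate [pslScore()] is taken as the
#' paralog's score in that species, normalised by the paralog's annotated
#' gene length (reported per kb). The parent call goes to the paralog with
#' the greater mean score across partner species (normalised by default;
#' configurable). Ties, or a paralog with no alignments, yield
#' `"undetermined"` with a reason. The call is invariant to the input
#' order of the pair.
#'
#' @param genePair character vector of two reference gene ids.
#' @param reference reference species id.
#' @param annotations named list of [GeneAnnotation-class].
#' @param refPsl named list of [PslAlignments-class] (reference as query).
#' @param tree a [SpeciesTree-class].
#' @param gapValue assembly gap value (default 200).
#' @param average `"normalized"` (default) or `"raw"`: which per-species
#'   score is averaged for the verdict.
#' @return list with `parent`, `daughter` (NA when undetermined),
#'   `reason`, `means` (mean score per paralog), `margin`, and `scores`,
#'   a per-species table of raw and normalised scores.
#' @export
inferParentDaughter <- function(genePair, reference, annotations, refPsl,
                                tree, gapValue = 200,
                                average = c("normalized", "raw")) {
  average <- match.arg(average)
  if (length(genePair) != 2L)
    .userError("genePair must name exactly two genes")
  refAnn <- annotations[[reference]]
  rows <- list()
  for (g in genePair) {
    span <- geneSpan(refAnn, g)
    glen <- IRanges::width(span)
    for (sp in setdiff(displayOrder(tree), reference)) {
      psl <- refPsl[[sp]]
      if (is.null(psl)) next
      sub <- .subsetPslToQuery(psl, span)
      frags <- assembleFragments(sub, gapValue, species = sp)
      if (!nrow(frags)) next
      raw <- pslScore(frags[1, , drop = FALSE])  # primary fragment
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, partner_species = sp, raw_score = raw,
        normalized_score = raw / (glen / 1000),
        n_alignments = frags$n_members[1], stringsAsFactors = FALSE)
    }
  }
  scores <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), partner_species = character(0),
               raw_score = integer(0), normalized_score = numeric(0),
               n_alignments = integer(0), stringsAsFactors = FALSE)
  col <- if (average == "normalized") "normalized_score" else "raw_score"
  means <- vapply(genePair, function(g) {
    v <- scores[[col]][scores$gene_id == g]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  res <- list(parent = NA_character_, daughter = NA_character_,
              reason = "", means = means, margin = NA_real_,
              scores = scores)
  if (anyNA(means)) {
    res$reason <- sprintf("no alignments for %s",
                          paste(genePair[is.na(means)], collapse = ", "))
    return(res)
  }
  if (means[1] == means[2]) {
    res$reason <- "tied mean scores"
    return(res)
  }
  res$parent <- genePair[which.max(means)]
  res$daughter <- genePair[which.min(means)]
  res$margin <- abs(means[1] - means[2])
  res
}
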