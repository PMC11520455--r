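#' Assemble liftover fragments into larger homologous fragments
#'
#' Chains PSL records under the gap value: records are grouped by target
#' sequence and strand, sorted by target start, and a chain is extended
#' while the gap between the next record's target start and the running
#' target end does not exceed `gapValue`. Each chain becomes one assembled
#' fragment whose alignment statistics are the sums over its members.
#' Output is sorted by decreasing fragment length (target-span extent).
#'
#' @param x a [PslAlignments-class]; all records must share one query
#'   sequence (one query region, one target species).
#' @param gapValue maximum allowed gap in bp (`>= 0`); overlapping or
#'   abutting records always merge.
#' @param species optional species label copied into the output.
#' @return data.frame of assembled fragments (1-based closed `t_start`,
#'   `t_end`; `length` = target-span extent; summed aggregates; `members`
#'   list column of record indices into `x`).
#' @examples
#' mk <- function(ts, te) paste(te - ts, 0, 0, 0, 0, 0, 0, 0, "+", "q", 1000,
#'   0, te - ts, "t", 5000, ts, te, 1, paste0(te - ts, ","),
#'   "0,", paste0(ts, ","), sep = "\t")
#' psl <- readPsl(c(mk(100, 200), mk(210, 300)))
#' assembleFragments(psl, gapValue = 10)$length   # one fragment, 200
#' nrow(assembleFragments(psl, gapValue = 9))     # two fragments
#' @export
assembleFragments <- function(x, gapValue, species = NA_character_) {
  p <- paramSet(gapValue = gapValue)
  df <- pslRecords(x)
  if (!nrow(df)) return(.emptyFragmentDf())
  if (length(unique(df$qName)) > 1L)
    .userError("records span multiple query sequences (%s); assemble one query at a time",
               paste(unique(df$qName), collapse = ", "))
  qs <- .pslQuerySpans(x)
  out <- list()
  for (grp in split(seq_len(nrow(df)),
                    list(df$tName[seq_len(nrow(df))],
                         df$strand[seq_len(nrow(df))]), drop = TRUE)) {
    s <- df$tStart[grp] + 1L   # 1-based closed target spans
    e <- df$tEnd[grp]
    ord <- order(s, e)
    grp <- grp[ord]; s <- s[ord]; e <- e[ord]
    emax <- cummax(e)
    # gap between record i and the running chain end, in intervening bases
    newChain <- c(TRUE, s[-1] - emax[-length(emax)] - 1L > p$gapValue)
    chain <- cumsum(newChain)
    for (k in unique(chain)) {
      m <- grp[chain == k]
      out[[length(out) + 1L]] <- data.frame(
        species = species, t_seq = df$tName[m[1]], strand = df$strand[m[1]],
        t_start = min(s[chain == k]), t_end = max(e[chain == k]),
        length = max(e[chain == k]) - min(s[chain == k]) + 1L,
        n_members = length(m),
        matches = sum(df$matches[m]), misMatches = sum(df$misMatches[m]),
        repMatches = sum(df$repMatches[m]), nCount = sum(df$nCount[m]),
        qNumInsert = sum(df$qNumInsert[m]), tNumInsert = sum(df$tNumInsert[m]),
        q_start = min(qs$q_start[m]), q_end = max(qs$q_end[m]),
        members = I(list(m)), stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$length, -res$matches, res$t_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter assembled fragments by length
#'
#' Retains fragments whose target-span extent is at least
#' `filteringPct`/100 of the query length (inclusive threshold). Input
#' order is preserved in both outputs.
#'
#' @param fragments fragment data.frame from [assembleFragments()].
#' @param queryLen query region length in bp (`> 0`).
#' @param filteringPct minimum length as a percentage of `queryLen`.
#' @return list with elements `retained` and `discarded`.
#' @export
filterFragments <- function(fragments, queryLen, filteringPct) {
  p <- paramSet(filteringPct = filteringPct)
  if (!is.numeric(queryLen) || queryLen <= 0)
    .userError("queryLen must be > 0")
  keep <- fragments$length >= p$filteringPct / 100 * queryLen
  list(retained = fragments[keep, , drop = FALSE],
       discarded = fragments[!keep, , drop = FALSE])
}

#' Classify retained fragments of one species
#'
#' The primary fragment is the longest retained fragment (ties broken by
#' larger aggregate matches, then smaller target start). Other fragments
#' that overlap any annotated gene overlapped by the primary are co-gene
#' fragments (drawn with the primary in the top panel); the rest are
#' secondary fragments, labelled `"(filtered)"` in the bottom panel --
#' typically paralogous alignments.
#'
#' @param fragments retained fragment data.frame of one species.
#' @param annotation the species' [GeneAnnotation-class].
#' @return the data.frame with added `class` (primary / co_gene /
#'   secondary) and `label` columns; zero rows stay legal (gene loss or
#'   divergence).
#' @export
classifyFragments <- function(fragments, annotation) {
  fragments$class <- character(nrow(fragments))
  fragments$label <- character(nrow(fragments))
  if (!nrow(fragments)) return(fragments)
  prim <- order(-fragments$length, -fragments$matches,
                fragments$t_start)[1]
  fr <- GenomicRanges::GRanges(
    fragments$t_seq,
    IRanges::IRanges(fragments$t_start, fragments$t_end))
  genes <- annotatedGenes(annotation)
  hitsPrim <- GenomicRanges::findOverlaps(fr[prim], genes,
                                          ignore.strand = TRUE)
  primGenes <- genes[S4Vectors::subjectHits(hitsPrim)]
  co <- rep(FALSE, nrow(fragments))
  if (length(primGenes)) {
    co <- IRanges::overlapsAny(fr, primGenes, ignore.strand = TRUE)
  }
  fragments$class <- ifelse(co, "co_gene", "secondary")
  fragments$class[prim] <- "primary"
  fragments$label <- ifelse(fragments$class == "secondary", "(filtered)", "")
  fragments
}

#' Extend fragments to the full span of overlapped genes
#'
#' The "full genes extension" of the synteny plot: each fragment's target
#' span is widened to the union of the spans of all genes it overlaps, so
#' aligned genes are shown at full length. Applied to a fixpoint (a span
#' widened onto a further gene is widened again), which makes the
#' operation idempotent. Alignment aggregates are unchanged; fragments in
#' intergenic space are returned as-is.
#'
#' @param fragments fragment data.frame.
#' @param annotation the species' [GeneAnnotation-class].
#' @return the data.frame with updated `t_start`, `t_end`, `length`.
#' @export
fullGeneExtension <- function(fragments, annotation) {
  if (!nrow(fragments)) return(fragments)
  genes <- annotatedGenes(annotation)
  for (i in seq_len(nrow(fragments))) {
    repeat {
      fr <- GenomicRanges::GRanges(
        fragments$t_seq[i],
        IRanges::IRanges(fragments$t_start[i], fragments$t_end[i]))
      hit <- genes[IRanges::overlapsAny(genes, fr, ignore.strand = TRUE)]
      if (!length(hit)) break
      ns <- min(fragments$t_start[i], min(GenomicRanges::start(hit)))
      ne <- max(fragments$t_end[i], max(GenomicRanges::end(hit)))
      if (ns == fragments$t_start[i] && ne == fragments$t_end[i]) break
      fragments$t_start[i] <- ns
      fragments$t_end[i] <- ne
    }
    fragments$length[i] <- fragments$t_end[i] - fragments$t_start[i] + 1L
  }
  fragments
}

#' Resolve a query to a reference region
#'
#' Accepts a gene name (looked up in the reference annotation) or raw
#' coordinates in `"seq:start-end"` / `"seq:start..end"` form (1-based
#' closed). Coordinates are bounds-checked against the annotation's
#' sequence lengths when known.
#'
#' @param query gene name or coordinate string.
#' @param annotation the reference species' [GeneAnnotation-class].
#' @return `GRanges` of length 1 with a `source` metadata column.
#' @export
resolveQuery <- function(query, annotation) {
  if (grepl(":", query, fixed = TRUE)) {
    m <- regmatches(query,
      regexec("^\\s*([^:]+):\\s*([0-9]+)\\s*(?:\\.\\.|-)\\s*([0-9]+)\\s*$",
              query))[[1]]
    if (length(m) != 4L)
      .userError("cannot parse coordinates '%s' (expected seq:start-end)", query)
    seq <- m[2]; s <- as.integer(m[3]); e <- as.integer(m[4])
    if (s >= e) .userError("query start %d >= end %d", s, e)
    sl <- GenomeInfoDb::seqlengths(annotatedGenes(annotation))
    if (!(seq %in% GenomeInfoDb::seqlevels(annotatedGenes(annotation))))
      .userError("unknown sequence '%s'", seq)
    if (!is.na(sl[seq]) && e > sl[seq])
      .userError("query end %d beyond length of '%s' (%d)", e, seq, sl[seq])
    gr <- GenomicRanges::GRanges(seq, IRanges::IRanges(s, e))
    gr$source <- "coordinates"
  } else {
    g <- annotatedGenes(annotation)
    hit <- g[g$gene_id == query]
    if (!length(hit)) .userError("unknown gene '%s'", query)
    gr <- GenomicRanges::granges(hit)
    GenomicRanges::strand(gr) <- "*"
    gr$source <- paste0("gene:", query)
  }
  gr
}
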