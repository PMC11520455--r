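#' Build synteny links between adjacent display tracks
#'
#' For every pair of species adjacent in the display order, the pairwise
#' alignment blocks are restricted (and by default clipped) to the two
#' species' displayed fragment spans, then chained under the gap value.
#' Unlike fragment assembly -- where the gap is measured on the target
#' axis only -- link chaining requires the gap condition on *both* sides,
#' so the link set is symmetric under exchanging the pair's query/target
#' roles. One link is emitted per chain; links on opposite relative
#' orientation are marked `inverted` and drawn as crossing ribbons.
#'
#' @param fragments displayed fragment data.frame across species (the
#'   `fragments` slot of a [SyntenyQuery-class], or any data.frame with
#'   `species`, `t_seq`, `t_start`, `t_end` columns).
#' @param order display order (character vector of species).
#' @param pairPsl named list of [PslAlignments-class]; the record for the
#'   adjacent pair `(a, b)` is looked up under `"a|b"` (a as query) or
#'   `"b|a"` (transposed on the fly). A missing pair raises a warning and
#'   contributes no links.
#' @param gapValue chaining gap in bp.
#' @param clip clip link intervals to the displayed fragment spans
#'   (default); otherwise links keep the full extent of their blocks.
#' @return data.frame of links (`species_a/b`, `seq_a/b`, `start/end`,
#'   `orientation` same|inverted, `support` = aligned bases).
#' @export
buildLinks <- function(fragments, order, pairPsl, gapValue, clip = TRUE) {
  p <- paramSet(gapValue = gapValue)
  out <- list()
  spanIr <- function(sp) {
    f <- fragments[fragments$species == sp, , drop = FALSE]
    split(IRanges::IRanges(f$t_start, f$t_end), f$t_seq)
  }
  for (k in seq_len(length(order) - 1L)) {
    a <- order[k]; b <- order[k + 1L]
    psl <- NULL
    if (!is.null(pairPsl[[paste(a, b, sep = "|")]])) {
      psl <- pairPsl[[paste(a, b, sep = "|")]]
    } else if (!is.null(pairPsl[[paste(b, a, sep = "|")]])) {
      psl <- transposePsl(pairPsl[[paste(b, a, sep = "|")]])
    }
    if (is.null(psl)) {
      warning(sprintf("no pairwise alignment for adjacent pair %s/%s; no links drawn",
                      a, b))
      next
    }
    out[[length(out) + 1L]] <-
      .linksForPair(a, b, psl, spanIr(a), spanIr(b), p$gapValue, clip)
  }
  res <- if (length(out)) do.call(rbind, out) else .emptyLinkDf()
  rownames(res) <- NULL
  res
}

# Chain clipped blocks of one species pair. spansA/spansB: per-seqname
# IRanges of displayed fragment spans.
.linksForPair <- function(a, b, psl, spansA, spansB, gapValue, clip) {
  bl <- pslBlocks(psl)
  if (!nrow(bl)) return(.emptyLinkDf())
  keep <- logical(nrow(bl))
  for (i in seq_len(nrow(bl))) {
    sa <- spansA[[bl$qName[i]]]; sb <- spansB[[bl$tName[i]]]
    keep[i] <- !is.null(sa) && !is.null(sb) &&
      any(IRanges::overlapsAny(IRanges::IRanges(bl$q_start[i], bl$q_end[i]), sa)) &&
      any(IRanges::overlapsAny(IRanges::IRanges(bl$t_start[i], bl$t_end[i]), sb))
  }
  bl <- bl[keep, , drop = FALSE]
  if (!nrow(bl)) return(.emptyLinkDf())
  if (clip) {
    clipTo <- function(s, e, spans) {
      ir <- IRanges::restrict(IRanges::IRanges(s, e),
                              start = min(IRanges::start(spans)),
                              end = max(IRanges::end(spans)))
      c(IRanges::start(ir), IRanges::end(ir))
    }
    for (i in seq_len(nrow(bl))) {
      qc <- clipTo(bl$q_start[i], bl$q_end[i], spansA[[bl$qName[i]]])
      tc <- clipTo(bl$t_start[i], bl$t_end[i], spansB[[bl$tName[i]]])
      bl$q_start[i] <- qc[1]; bl$q_end[i] <- qc[2]
      bl$t_start[i] <- tc[1]; bl$t_end[i] <- tc[2]
    }
  }
  out <- list()
  for (grp in split(seq_len(nrow(bl)),
                    list(bl$qName, bl$tName, bl$strand), drop = TRUE)) {
    g <- bl[grp, , drop = FALSE]
    g <- g[order(g$t_start, g$q_start), , drop = FALSE]
    # transitive merge closure: two blocks join when the gap condition
    # holds on BOTH axes; symmetric in query/target by construction
    gap1 <- function(s1, e1, s2, e2) max(s2 - e1, s1 - e2) - 1L
    chain <- seq_len(nrow(g))
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(g))) for (j in seq_len(nrow(g))) {
        if (chain[i] == chain[j]) next
        if (gap1(g$t_start[i], g$t_end[i], g$t_start[j], g$t_end[j]) <= gapValue &&
            gap1(g$q_start[i], g$q_end[i], g$q_start[j], g$q_end[j]) <= gapValue) {
          chain[chain == chain[j]] <- chain[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (k in unique(chain)) {
      m <- g[chain == k, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        species_a = a, seq_a = m$qName[1],
        start_a = min(m$q_start), end_a = max(m$q_end),
        species_b = b, seq_b = m$tName[1],
        start_b = min(m$t_start), end_b = max(m$t_end),
        orientation = if (m$strand[1] == "+") "same" else "inverted",
        support = sum(pmin(m$q_end - m$q_start, m$t_end - m$t_start) + 1L),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
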