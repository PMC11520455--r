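#' Parameter sweeps over the gap value and the filtering percentage
#'
#' Reproduces the two diagnostic curves of the assembly parameters:
#' (a) for each gap value, the fraction of queries whose liftover
#' fragments assemble into exactly one fragment in at least one species
#' (filtering at 0%), and (b) for each filtering percentage, the mean
#' number of retained fragments per species over all (query, species)
#' pairs (gap value fixed). Both curves are monotone by construction of
#' the chaining and filtering rules.
#'
#' The fragment count per (query, species) at gap value g is computed in
#' one pass from the sorted inter-record gaps (count = 1 + number of gaps
#' exceeding g), so the whole gap grid costs one sort per pair.
#'
#' @param queries character vector of gene names (or coordinate strings)
#'   on the reference.
#' @param reference reference species id.
#' @param annotations named list of [GeneAnnotation-class].
#' @param refPsl named list of [PslAlignments-class] (reference as query).
#' @param tree a [SpeciesTree-class].
#' @param gapGrid gap values to sweep (default 0..1000 step 50).
#' @param pctGrid filtering percentages to sweep (default 0..50 step 2).
#' @param gapForPct gap value used while sweeping the percentage
#'   (default 200).
#' @return list with data.frames `gapCurve` (`gap_value`,
#'   `fraction_single_fragment`) and `pctCurve` (`filtering_pct`,
#'   `mean_retained_fragments`).
#' @export
sweepParameters <- function(queries, reference, annotations, refPsl, tree,
                            gapGrid = seq(0, 1000, by = 50),
                            pctGrid = seq(0, 50, by = 2),
                            gapForPct = 200) {
  if (!length(gapGrid) || !length(pctGrid))
    .userError("sweep grids must be non-empty")
  species <- setdiff(displayOrder(tree), reference)
  refAnn <- annotations[[reference]]

  # per (query, species): sorted target spans of the overlapping records
  spans <- list(); qlens <- numeric(length(queries))
  for (qi in seq_along(queries)) {
    qr <- resolveQuery(queries[qi], refAnn)
    qlens[qi] <- IRanges::width(qr)
    for (sp in species) {
      sub <- .subsetPslToQuery(refPsl[[sp]], qr)
      df <- pslRecords(sub)
      key <- paste(qi, sp, sep = "\r")
      if (!nrow(df)) { spans[[key]] <- NULL; next }
      # single (tName, strand) group per gene in practice; keep grouping
      spans[[key]] <- lapply(
        split(seq_len(nrow(df)), paste(df$tName, df$strand)),
        function(idx) {
          s <- df$tStart[idx] + 1L; e <- df$tEnd[idx]
          o <- order(s, e)
          s <- s[o]; e <- cummax(e[o])
          list(s = s, e = e,
               gaps = if (length(s) > 1L) s[-1] - e[-length(e)] - 1L
                      else integer(0))
        })
    }
  }

  # (a) fully-assembled fraction per gap value
  frac <- vapply(gapGrid, function(g) {
    ok <- vapply(seq_along(queries), function(qi) {
      for (sp in species) {
        grp <- spans[[paste(qi, sp, sep = "\r")]]
        if (is.null(grp)) next
        nfrag <- sum(vapply(grp, function(x) 1L + sum(x$gaps > g),
                            integer(1)))
        if (nfrag == 1L) return(TRUE)
      }
      FALSE
    }, logical(1))
    mean(ok)
  }, numeric(1))

  # (b) mean retained fragments per species per filtering percentage,
  # at the fixed gap value
  counts <- matrix(0, nrow = length(queries) * length(species),
                   ncol = length(pctGrid))
  row <- 0L
  for (qi in seq_along(queries)) {
    for (sp in species) {
      row <- row + 1L
      grp <- spans[[paste(qi, sp, sep = "\r")]]
      if (is.null(grp)) next
      lens <- unlist(lapply(grp, function(x) {
        brk <- c(TRUE, x$gaps > gapForPct)
        chain <- cumsum(brk)
        vapply(split(seq_along(chain), chain), function(idx)
          max(x$e[idx]) - min(x$s[idx]) + 1L, numeric(1))
      }), use.names = FALSE)
      counts[row, ] <- vapply(pctGrid, function(p)
        sum(lens >= p / 100 * qlens[qi]), numeric(1))
    }
  }
  list(
    gapCurve = data.frame(gap_value = gapGrid,
                          fraction_single_fragment = frac),
    pctCurve = data.frame(filtering_pct = pctGrid,
                          mean_retained_fragments = colMeans(counts))
  )
}
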