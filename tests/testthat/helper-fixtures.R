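# Shared fixtures. The golden clade (the simulator's default study
# conditions, seed 42) is expensive, so it is built once per test run and
# memoised here.

.fixtureCache <- new.env(parent = emptyenv())

goldenClade <- function() {
  if (is.null(.fixtureCache$golden))
    .fixtureCache$golden <- simulateClade(simCladeConfig(seed = 42))
  .fixtureCache$golden
}

nullClade <- function() {
  if (is.null(.fixtureCache$null0))
    .fixtureCache$null0 <- simulateClade(simCladeConfig(
      seed = 7, nGenes = 12, subRate = 0, indelRate = 0, dupRate = 0,
      inversionRate = 0, lossRate = 0, annotationGapProb = 0,
      subNoise = FALSE))
  .fixtureCache$null0
}

# one single-block PSL line; qStart/tStart are 0-based forward starts
mkPslLine <- function(tStart, tEnd, qName = "q", qSize = 100000L,
                      qStart = 0L, tName = "t", tSize = 1000000L,
                      strand = "+", matches = NULL, misMatches = 0L) {
  len <- tEnd - tStart
  if (is.null(matches)) matches <- len - misMatches
  qs <- if (strand == "+") qStart else qSize - (qStart + len)
  paste(matches, misMatches, 0L, 0L, 0L, 0L, 0L, 0L, strand,
        qName, qSize, qStart, qStart + len,
        tName, tSize, tStart, tEnd,
        1L, paste0(len, ","), paste0(qs, ","), paste0(tStart, ","),
        sep = "\t")
}

# brute-force merge closure over target intervals: merge any two
# fragments on the same (tName, strand) whose target gap is <= gapValue,
# until a fixpoint; the independent oracle for chain assembly
mergeClosureOracle <- function(df, gapValue) {
  frs <- lapply(seq_len(nrow(df)), function(i)
    list(tName = df$tName[i], strand = df$strand[i],
         s = df$tStart[i] + 1L, e = df$tEnd[i], matches = df$matches[i]))
  repeat {
    merged <- FALSE
    for (i in seq_along(frs)) {
      for (j in seq_along(frs)) {
        if (i >= j) next
        a <- frs[[i]]; b <- frs[[j]]
        if (a$tName != b$tName || a$strand != b$strand) next
        gap <- max(b$s - a$e, a$s - b$e) - 1L
        if (gap <= gapValue) {
          frs[[i]] <- list(tName = a$tName, strand = a$strand,
                           s = min(a$s, b$s), e = max(a$e, b$e),
                           matches = a$matches + b$matches)
          frs[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  out <- do.call(rbind, lapply(frs, function(f)
    data.frame(t_seq = f$tName, strand = f$strand, t_start = f$s,
               t_end = f$e, matches = f$matches,
               stringsAsFactors = FALSE)))
  out[order(out$t_seq, out$strand, out$t_start), , drop = FALSE]
}

# tiny two-gene annotation used across assembly/classification tests
toyAnnotation <- function(species = "sp") {
  genes <- GenomicRanges::GRanges(
    "t", IRanges::IRanges(c(100, 600), c(500, 900)), strand = "+",
    gene_id = c("gA", "gB"))
  feats <- GenomicRanges::GRanges(
    "t", IRanges::IRanges(c(100, 300, 600), c(250, 500, 900)),
    strand = "+", gene_id = c("gA", "gA", "gB"),
    type = c("exon", "exon", "exon"))
  GeneAnnotation(species, genes, feats,
                 seqlengths = c(t = 1000000L))
}
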