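#' Per-base synteny depth over the reference genome
#'
#' Depth at a reference base is the number of alignment blocks covering it,
#' across all species and all alignments -- paralogous alignments count
#' multiply, so an anciently duplicated gene aligned to two copies per
#' species reaches twice the depth of a single-copy gene. The PSL query
#' side must be the reference species; reference self-alignments are not
#' expected in the input and are not added by this function.
#'
#' @param refPsl named list of [PslAlignments-class], one per contributing
#'   species (reference as query).
#' @param seqlengths named vector of reference sequence lengths.
#' @return a [DepthProfile-class].
#' @export
depthProfile <- function(refPsl, seqlengths) {
  sl <- stats::setNames(as.integer(seqlengths), names(seqlengths))
  zero <- IRanges::RleList(lapply(sl, function(n) S4Vectors::Rle(0L, n)),
                           compress = FALSE)
  cov <- zero
  totals <- stats::setNames(numeric(length(refPsl)), names(refPsl))
  for (sp in names(refPsl)) {
    bl <- pslBlocks(refPsl[[sp]])
    totals[sp] <- sum(bl$size)
    if (!nrow(bl)) next
    if (!all(bl$qName %in% names(sl)))
      .formatError("alignment block on undeclared sequence '%s'",
                   setdiff(unique(bl$qName), names(sl))[1])
    bad <- bl$q_end > sl[bl$qName] | bl$q_start < 1L
    if (any(bad))
      .formatError("alignment block outside declared length of '%s'",
                   bl$qName[bad][1])
    for (seq in unique(bl$qName)) {
      sel <- bl$qName == seq
      cov[[seq]] <- cov[[seq]] + IRanges::coverage(
        IRanges::IRanges(bl$q_start[sel], bl$q_end[sel]),
        width = sl[[seq]])
    }
  }
  new("DepthProfile", coverage = cov, speciesTotals = totals,
      seqlengths = sl)
}

setMethod("show", "DepthProfile", function(object) {
  tot <- sum(vapply(object@coverage, function(r) sum(as.numeric(r)),
                    numeric(1)))
  glen <- sum(object@seqlengths)
  cat(sprintf("DepthProfile over %d sequence(s), %d bp\n",
              length(object@seqlengths), glen))
  cat(sprintf("  %d contributing species; mean depth %.3f\n",
              length(object@speciesTotals), tot / glen))
})

#' Coverage vectors of a depth profile
#' @param x a [DepthProfile-class].
#' @return an `RleList` of per-sequence integer coverage.
#' @export
depthCoverage <- function(x) x@coverage

#' Total depth (sum over bases) of a profile
#' @param x a [DepthProfile-class].
#' @return numeric; equals the summed block sizes of the input alignments.
#' @export
depthTotal <- function(x)
  sum(vapply(x@coverage, function(r) sum(as.numeric(r)), numeric(1)))

#' Mean depth per non-overlapping window
#'
#' Tiles each reference sequence with non-overlapping windows (default
#' 20 kb) and reports the mean depth per window; a trailing partial window
#' is averaged over its actual width.
#'
#' @param profile a [DepthProfile-class].
#' @param window window size in bp (`> 0`).
#' @return data.frame with `seq_id`, `window_start` (0-based multiples of
#'   the window size), `window_end`, `width`, `mean_depth`.
#' @export
windowMeans <- function(profile, window = 20000) {
  if (!is.numeric(window) || window <= 0) .userError("window must be > 0")
  window <- as.integer(window)
  out <- list()
  for (seq in names(profile@seqlengths)) {
    len <- profile@seqlengths[[seq]]
    starts <- seq.int(1L, len, by = window)
    ends <- pmin(starts + window - 1L, len)
    v <- IRanges::Views(profile@coverage[[seq]], start = starts, end = ends)
    out[[seq]] <- data.frame(
      seq_id = seq, window_start = starts - 1L, window_end = ends,
      width = ends - starts + 1L,
      mean_depth = IRanges::viewMeans(v), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Mean depth of a set of ranges (GRanges or per-seq IRanges list).
.rangeMeanDepth <- function(profile, gr) {
  if (!length(gr)) return(NA_real_)
  tot <- 0; n <- 0
  for (seq in unique(as.character(GenomeInfoDb::seqnames(gr)))) {
    ir <- IRanges::ranges(gr[GenomeInfoDb::seqnames(gr) == seq])
    if (!seq %in% names(profile@coverage)) next
    v <- IRanges::Views(profile@coverage[[seq]],
                        start = IRanges::start(ir), end = IRanges::end(ir))
    tot <- tot + sum(IRanges::viewSums(v))
    n <- n + sum(IRanges::width(ir))
  }
  if (n == 0) NA_real_ else tot / n
}

#' Mean synteny depth by sequence feature class
#'
#' Assigns every reference base to exactly one class by the precedence
#' exon > 5'UTR > 3'UTR > intron > intergenic, where "exon" means
#' CDS-bearing exonic bases (disjoint from the UTR classes). Overlapping
#' genes are resolved by the same precedence applied per base. Returns
#' per-gene mean depths for the four genic classes and per-block means for
#' intergenic regions, suitable for box-plot summaries.
#'
#' @param profile a [DepthProfile-class].
#' @param annotation the reference [GeneAnnotation-class].
#' @return data.frame with `unit_id` (gene id or intergenic block),
#'   `class`, `n_bases`, `mean_depth`.
#' @export
featureClassDepth <- function(profile, annotation) {
  sl <- profile@seqlengths
  genome <- GenomicRanges::GRanges(names(sl), IRanges::IRanges(1L, sl))
  red <- function(type) GenomicRanges::reduce(GenomicRanges::granges(
    geneFeatures(annotation, type = type)), ignore.strand = TRUE)
  gspan <- GenomicRanges::reduce(
    GenomicRanges::granges(annotatedGenes(annotation)), ignore.strand = TRUE)
  cls <- list()
  cls$exon <- red("CDS")
  cls$five_prime_UTR <- GenomicRanges::setdiff(red("five_prime_UTR"),
                                               cls$exon, ignore.strand = TRUE)
  cls$three_prime_UTR <- GenomicRanges::setdiff(
    red("three_prime_UTR"),
    GenomicRanges::union(cls$exon, cls$five_prime_UTR, ignore.strand = TRUE),
    ignore.strand = TRUE)
  genic <- Reduce(function(a, b) GenomicRanges::union(a, b, ignore.strand = TRUE),
                  cls)
  cls$intron <- GenomicRanges::setdiff(gspan, genic, ignore.strand = TRUE)
  cls$intergenic <- GenomicRanges::setdiff(genome, gspan, ignore.strand = TRUE)

  rows <- list()
  genes <- annotatedGenes(annotation)
  for (cn in c("exon", "five_prime_UTR", "three_prime_UTR", "intron")) {
    for (i in seq_along(genes)) {
      gr <- GenomicRanges::intersect(cls[[cn]],
                                     GenomicRanges::granges(genes[i]),
                                     ignore.strand = TRUE)
      if (!length(gr)) next
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = genes$gene_id[i], class = cn,
        n_bases = sum(IRanges::width(gr)),
        mean_depth = .rangeMeanDepth(profile, gr),
        stringsAsFactors = FALSE)
    }
  }
  ig <- cls$intergenic
  for (i in seq_along(ig)) {
    rows[[length(rows) + 1L]] <- data.frame(
      unit_id = sprintf("%s:%d-%d",
                        as.character(GenomeInfoDb::seqnames(ig))[i],
                        GenomicRanges::start(ig)[i],
                        GenomicRanges::end(ig)[i]),
      class = "intergenic", n_bases = IRanges::width(ig)[i],
      mean_depth = .rangeMeanDepth(profile, ig[i]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Mean synteny depth by gene class
#'
#' Mean depth per gene over its full span, grouped by externally supplied
#' gene classes (e.g. single-copy genes versus genes duplicated at
#' different epochs). Unknown gene ids raise a warning and are skipped.
#'
#' @param profile a [DepthProfile-class].
#' @param geneClasses named list of character vectors of gene ids.
#' @param annotation the reference [GeneAnnotation-class].
#' @return data.frame with `gene_id`, `class`, `mean_depth`.
#' @export
geneClassDepth <- function(profile, geneClasses, annotation) {
  genes <- annotatedGenes(annotation)
  rows <- list()
  for (cn in names(geneClasses)) {
    ids <- geneClasses[[cn]]
    miss <- setdiff(ids, genes$gene_id)
    if (length(miss))
      warning(sprintf("skipping %d unknown gene id(s) in class '%s'",
                      length(miss), cn))
    ids <- setdiff(ids, miss)
    for (id in ids) {
      g <- genes[genes$gene_id == id]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = id, class = cn,
        mean_depth = .rangeMeanDepth(profile, GenomicRanges::granges(g)),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), class = character(0),
               mean_depth = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Write a depth profile as BedGraph
#'
#' One line per constant-depth run (0-based half-open intervals, as the
#' format specifies), including zero-depth runs.
#'
#' @param profile a [DepthProfile-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeBedGraph <- function(profile, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph name=synteny_depth", con)
  for (seq in names(profile@coverage)) {
    r <- profile@coverage[[seq]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0L, ends[-length(ends)])
    writeLines(sprintf("%s\t%d\t%d\t%d", seq, starts, ends,
                       S4Vectors::runValue(r)), con)
  }
  invisible(file)
}
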