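#' Run a full synteny query
#'
#' The core pipeline: resolve the query on the reference, pick up the
#' liftover records overlapping it in every other species, assemble them
#' under the gap value, filter by the filtering percentage of the query
#' length, classify primary / co-gene / secondary fragments against each
#' species' annotation, optionally apply the full-genes extension, and
#' build synteny links between adjacent display tracks.
#'
#' @param query gene name or `"seq:start-end"` coordinates on the
#'   reference.
#' @param reference reference species id (a leaf of `tree`).
#' @param annotations named list of [GeneAnnotation-class] per species.
#' @param refPsl named list of [PslAlignments-class]: per non-reference
#'   species, its alignment with the reference as query.
#' @param tree a [SpeciesTree-class] giving the display order.
#' @param pairPsl optional named list (`"A|B"`) of pairwise alignments for
#'   adjacent display pairs, used for links.
#' @param gapValue,filteringPct assembly parameters (defaults 200 bp, 16).
#' @param fullGenes apply [fullGeneExtension()] to displayed fragments.
#' @param orthogroups optional [OrthogroupSet-class] used to annotate the
#'   genes table.
#' @param clipLinks clip links to displayed fragments (see [buildLinks()]).
#' @return a [SyntenyQuery-class].
#' @export
runSyntenyQuery <- function(query, reference, annotations, refPsl, tree,
                            pairPsl = NULL, gapValue = 200,
                            filteringPct = 16, fullGenes = FALSE,
                            orthogroups = NULL, clipLinks = TRUE) {
  paramSet(gapValue, filteringPct)
  if (!reference %in% displayOrder(tree))
    .userError("reference '%s' is not a leaf of the species tree", reference)
  qr <- resolveQuery(query, annotations[[reference]])
  qlen <- IRanges::width(qr)
  ord <- displayOrder(tree)

  allRet <- list(); allDis <- list()
  for (sp in setdiff(ord, reference)) {
    psl <- refPsl[[sp]]
    if (is.null(psl)) next
    sub <- .subsetPslToQuery(psl, qr)
    frags <- assembleFragments(sub, gapValue, species = sp)
    fl <- filterFragments(frags, qlen, filteringPct)
    ret <- classifyFragments(fl$retained, annotations[[sp]])
    if (fullGenes) ret <- fullGeneExtension(ret, annotations[[sp]])
    allRet[[sp]] <- ret
    allDis[[sp]] <- fl$discarded
  }
  fragments <- if (length(allRet)) do.call(rbind, allRet) else
    cbind(.emptyFragmentDf(), class = character(0), label = character(0))
  discarded <- if (length(allDis)) do.call(rbind, allDis) else
    .emptyFragmentDf()
  rownames(fragments) <- NULL; rownames(discarded) <- NULL

  # reference track: the query region itself
  refRow <- data.frame(
    species = reference, t_seq = as.character(GenomeInfoDb::seqnames(qr)),
    strand = "+", t_start = GenomicRanges::start(qr),
    t_end = GenomicRanges::end(qr), length = qlen, n_members = 0L,
    matches = NA_integer_, misMatches = NA_integer_,
    repMatches = NA_integer_, nCount = NA_integer_,
    qNumInsert = NA_integer_, tNumInsert = NA_integer_,
    q_start = GenomicRanges::start(qr), q_end = GenomicRanges::end(qr),
    members = I(list(integer(0))), class = "primary", label = "",
    stringsAsFactors = FALSE)
  fragments <- rbind(refRow, fragments)

  links <- if (!is.null(pairPsl))
    buildLinks(fragments, ord[ord %in% fragments$species], pairPsl,
               gapValue, clip = clipLinks)
  else .emptyLinkDf()

  genesTable <- .genesTable(fragments, annotations, orthogroups)
  new("SyntenyQuery", query = qr, reference = reference,
      fragments = fragments, discarded = discarded, links = links,
      genesTable = genesTable,
      params = list(gapValue = gapValue, filteringPct = filteringPct,
                    fullGenes = fullGenes),
      displayOrder = ord)
}

# Records whose forward query span overlaps the query region.
.subsetPslToQuery <- function(psl, qr) {
  df <- pslRecords(psl)
  if (!nrow(df)) return(psl)
  qs <- .pslQuerySpans(psl)
  keep <- qs$qName == as.character(GenomeInfoDb::seqnames(qr)) &
    qs$q_start <= GenomicRanges::end(qr) &
    qs$q_end >= GenomicRanges::start(qr)
  psl[keep]
}

# Genes overlapped by displayed fragments, with orthogroup labels.
.genesTable <- function(fragments, annotations, orthogroups) {
  rows <- list()
  for (sp in unique(fragments$species)) {
    ann <- annotations[[sp]]
    if (is.null(ann)) next
    f <- fragments[fragments$species == sp, , drop = FALSE]
    fr <- GenomicRanges::GRanges(f$t_seq,
                                 IRanges::IRanges(f$t_start, f$t_end))
    genes <- annotatedGenes(ann)
    hits <- GenomicRanges::findOverlaps(genes, fr, ignore.strand = TRUE)
    if (!length(hits)) next
    idx <- unique(S4Vectors::queryHits(hits))
    g <- genes[idx]
    fragClass <- vapply(idx, function(i) {
      j <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i][1]
      f$class[j]
    }, character(1))
    rows[[sp]] <- data.frame(
      species = sp, gene_id = g$gene_id,
      seq = as.character(GenomeInfoDb::seqnames(g)),
      start = GenomicRanges::start(g), end = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g)),
      orthogroup = if (is.null(orthogroups)) NA_character_ else
        orthogroupOf(orthogroups, g$gene_id),
      panel = ifelse(fragClass == "secondary", "bottom", "top"),
      stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), gene_id = character(0),
               seq = character(0), start = integer(0), end = integer(0),
               strand = character(0), orthogroup = character(0),
               panel = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

setMethod("show", "SyntenyQuery", function(object) {
  qr <- object@query
  cat(sprintf("SyntenyQuery: %s:%d-%d (%s), gap=%g, filter=%g%%\n",
              as.character(GenomeInfoDb::seqnames(qr)),
              GenomicRanges::start(qr), GenomicRanges::end(qr),
              qr$source, object@params$gapValue,
              object@params$filteringPct))
  tab <- table(factor(object@fragments$class,
                      levels = c("primary", "co_gene", "secondary")))
  cat(sprintf("  fragments: %d primary, %d co-gene, %d secondary; %d discarded\n",
              tab[["primary"]], tab[["co_gene"]], tab[["secondary"]],
              nrow(object@discarded)))
  cat(sprintf("  links: %d; genes: %d\n", nrow(object@links),
              nrow(object@genesTable)))
})

#' Accessors for SyntenyQuery results
#'
#' @param x a [SyntenyQuery-class].
#' @return `queryFragments`: fragment data.frame (with `class`);
#'   `queryLinks`: link data.frame; `queryGenes`: overlapped-genes
#'   data.frame; `queryRegion`: the resolved `GRanges`.
#' @export
queryFragments <- function(x) x@fragments

#' @rdname queryFragments
#' @export
queryLinks <- function(x) x@links

#' @rdname queryFragments
#' @export
queryGenes <- function(x) x@genesTable

#' @rdname queryFragments
#' @export
queryRegion <- function(x) x@query

#' Write the tabular outputs of a synteny query
#'
#' Emits the three tables of the query result -- assembled fragment
#' coordinates, aligned genes and synteny links -- as TSV files
#' (`fragments.tsv`, `genes.tsv`, `links.tsv`; 1-based closed
#' coordinates), mirroring the tables shown alongside the synteny plot.
#'
#' @param x a [SyntenyQuery-class].
#' @param dir output directory (created if needed).
#' @return the file paths, invisibly.
#' @export
writeQueryTables <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "fragments.tsv")
  fr <- x@fragments
  fr <- fr[, c("species", "t_seq", "t_start", "t_end", "strand", "length",
               "n_members", "matches", "class", "label")]
  .writeTsv(fr, f1)
  f2 <- file.path(dir, "genes.tsv")
  .writeTsv(x@genesTable, f2)
  f3 <- file.path(dir, "links.tsv")
  .writeTsv(x@links, f3)
  invisible(c(f1, f2, f3))
}
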