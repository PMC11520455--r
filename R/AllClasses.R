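#' @import methods
#' @importFrom S4Vectors isSorted
NULL

#' PslAlignments: a set of pairwise alignment records in PSL layout
#'
#' Container for 21-column PSL records (BLAT lineage), the atomic alignment
#' unit of the pipeline. Records are stored bit-faithful to the file
#' (0-based half-open spans, negative-strand query block starts in
#' reverse-complement coordinates, as PSL specifies); coordinate accessors
#' such as [pslBlocks()] convert to the 1-based closed convention used
#' everywhere else in the package.
#'
#' @slot records data.frame with one row per PSL line; the three per-block
#'   fields (`blockSizes`, `qStarts`, `tStarts`) are list columns of
#'   integer vectors.
#' @seealso [readPsl()], [writePsl()], [pslBlocks()]
#' @export
setClass("PslAlignments", representation(records = "data.frame"))

.PSL_COLS <- c(
  "matches", "misMatches", "repMatches", "nCount",
  "qNumInsert", "qBaseInsert", "tNumInsert", "tBaseInsert", "strand",
  "qName", "qSize", "qStart", "qEnd",
  "tName", "tSize", "tStart", "tEnd",
  "blockCount", "blockSizes", "qStarts", "tStarts"
)

# Vectorised scan for the earliest invalid record; returns NULL or
# list(idx, msg). Used by both the validity method and the parser (which
# maps record index back to a file line).
.pslFirstError <- function(df) {
  n <- nrow(df)
  if (!n) return(NULL)
  hits <- list()
  note <- function(idx, msg) {
    if (length(idx)) hits[[length(hits) + 1L]] <<- list(idx = min(idx),
                                                        msg = msg)
  }
  note(which(!(df$strand %in% c("+", "-"))),
       "unsupported strand (translated two-character strands are not supported)")
  note(which(!(df$qStart >= 0 & df$qStart < df$qEnd & df$qEnd <= df$qSize)),
       "query span violates 0 <= qStart < qEnd <= qSize")
  note(which(!(df$tStart >= 0 & df$tStart < df$tEnd & df$tEnd <= df$tSize)),
       "target span violates 0 <= tStart < tEnd <= tSize")
  nb <- lengths(df$blockSizes)
  note(which(nb != df$blockCount | lengths(df$qStarts) != df$blockCount |
               lengths(df$tStarts) != df$blockCount),
       "block list lengths do not match blockCount")
  note(which(vapply(df$blockSizes, function(b) any(b <= 0), logical(1))),
       "non-positive block size")
  note(which(mapply(function(ts, bs) {
    n <- length(bs)
    n > 1L && any(ts[-1] < (ts[-n] + bs[-n]))
  }, df$tStarts, df$blockSizes)),
       "target blocks are not strictly increasing / non-overlapping")
  note(which(vapply(df$blockSizes, sum, numeric(1)) !=
               df$matches + df$misMatches + df$repMatches + df$nCount),
       "sum(blockSizes) != matches + misMatches + repMatches + nCount")
  tFirst <- vapply(df$tStarts, `[`, numeric(1), 1L)
  tLast <- mapply(function(ts, bs) ts[length(ts)] + bs[length(bs)],
                  df$tStarts, df$blockSizes)
  note(which(tFirst != df$tStart | tLast != df$tEnd),
       "target blocks do not span [tStart, tEnd)")
  qFirst <- vapply(df$qStarts, `[`, numeric(1), 1L)
  qLast <- mapply(function(qs, bs) qs[length(qs)] + bs[length(bs)],
                  df$qStarts, df$blockSizes)
  # on '-' records qStarts are reverse-complement coordinates; the forward
  # span they cover must still equal [qStart, qEnd)
  plus <- df$strand == "+"
  note(which((plus & (qFirst != df$qStart | qLast != df$qEnd)) |
               (!plus & (df$qSize - qLast != df$qStart |
                           df$qSize - qFirst != df$qEnd))),
       "query blocks do not span [qStart, qEnd)")
  if (!length(hits)) return(NULL)
  hits[[which.min(vapply(hits, `[[`, numeric(1), "idx"))]]
}

setValidity("PslAlignments", function(object) {
  df <- object@records
  if (!all(.PSL_COLS %in% names(df)))
    return(paste("missing PSL columns:",
                 paste(setdiff(.PSL_COLS, names(df)), collapse = ", ")))
  e <- .pslFirstError(df)
  if (is.null(e)) TRUE else sprintf("record %d: %s", e$idx, e$msg)
})

#' GeneAnnotation: gene models of one species
#'
#' Gene spans plus their exon/CDS/UTR sub-features, parsed from GFF3 and
#' held as `GRanges` (1-based closed). Isoforms are collapsed: sub-feature
#' intervals of all transcripts of a gene are unioned per feature type.
#'
#' @slot species single species identifier.
#' @slot genes `GRanges` of gene spans with a `gene_id` metadata column.
#' @slot features `GRanges` of sub-features with `gene_id` and `type`
#'   (exon, CDS, five_prime_UTR, three_prime_UTR) metadata columns.
#' @seealso [readGeneAnnotation()], [writeGff3()]
#' @export
setClass("GeneAnnotation", representation(
  species = "character", genes = "GRanges", features = "GRanges"
))

setValidity("GeneAnnotation", function(object) {
  g <- object@genes; f <- object@features
  if (length(object@species) != 1L) return("species must be a single string")
  if (is.null(g$gene_id)) return("genes need a gene_id column")
  if (anyDuplicated(g$gene_id)) return("duplicated gene_id")
  if (length(f)) {
    if (is.null(f$gene_id) || is.null(f$type))
      return("features need gene_id and type columns")
    idx <- match(f$gene_id, g$gene_id)
    if (anyNA(idx)) return("feature gene_id not found among genes")
    bad <- GenomicRanges::start(f) < GenomicRanges::start(g)[idx] |
      GenomicRanges::end(f) > GenomicRanges::end(g)[idx]
    if (any(bad)) return("sub-feature interval outside its gene span")
  }
  TRUE
})

#' OrthogroupSet: orthogroup membership across species
#'
#' Long-format mapping of orthogroup id to gene ids per species. A gene may
#' belong to at most one orthogroup.
#'
#' @slot table data.frame with columns `orthogroup`, `species`, `gene_id`.
#' @slot species character vector of species columns of the source table.
#' @seealso [readOrthogroups()]
#' @export
setClass("OrthogroupSet", representation(
  table = "data.frame", species = "character"
))

setValidity("OrthogroupSet", function(object) {
  tb <- object@table
  if (!all(c("orthogroup", "species", "gene_id") %in% names(tb)))
    return("table needs orthogroup, species, gene_id columns")
  dup <- duplicated(tb$gene_id)
  if (any(dup))
    return(sprintf("gene '%s' assigned to more than one orthogroup",
                   tb$gene_id[dup][1]))
  TRUE
})

#' SpeciesTree: rooted guide tree with a derived display order
#'
#' Wraps an `ape::phylo` tree. The display order is the left-to-right leaf
#' traversal of the tree as written, so that sister taxa are adjacent on
#' the plot tracks, mirroring the guide tree used for the alignment.
#'
#' @slot tree a rooted `phylo` object.
#' @slot displayOrder character; leaves in plotting order.
#' @seealso [readSpeciesTree()], [displayOrder()]
#' @export
setClass("SpeciesTree", representation(
  tree = "ANY", displayOrder = "character"
))

setValidity("SpeciesTree", function(object) {
  if (!inherits(object@tree, "phylo")) return("tree must be a phylo object")
  if (!setequal(object@displayOrder, object@tree$tip.label) ||
      length(object@displayOrder) != length(object@tree$tip.label))
    return("displayOrder must be a permutation of the leaf labels")
  TRUE
})

#' DepthProfile: per-base synteny depth over a reference genome
#'
#' Integer coverage of reference bases by alignment blocks from the other
#' species. Paralogous alignments count multiply; depth is a block count,
#' not a species count.
#'
#' @slot coverage `RleList`, one run-length vector per reference sequence.
#' @slot speciesTotals named numeric, aligned block bases contributed per
#'   species.
#' @slot seqlengths named integer reference sequence lengths.
#' @seealso [depthProfile()], [windowMeans()]
#' @export
setClass("DepthProfile", representation(
  coverage = "ANY", speciesTotals = "numeric", seqlengths = "numeric"
))

#' SyntheticClade: a simulated clade with ground truth
#'
#' Everything the pipeline consumes for one simulated clade -- per-species
#' annotations, reference-anchored and sister-pair PSL alignments, the
#' orthogroup table and guide tree -- plus the ground truth (copy status,
#' duplication epochs, parent/daughter roles, losses, annotation gaps) that
#' the tests compare against.
#'
#' @slot config the [simCladeConfig()] list used.
#' @slot tree a [SpeciesTree-class].
#' @slot reference reference species id (a tree leaf).
#' @slot annotations named list of [GeneAnnotation-class], one per species.
#' @slot refPsl named list of [PslAlignments-class]: each non-reference
#'   species aligned with the reference as query.
#' @slot pairPsl named list of [PslAlignments-class] keyed `"A|B"` for
#'   species pairs adjacent in display order (A is the query side).
#' @slot orthogroups an [OrthogroupSet-class] over annotated genes.
#' @slot truth data.frame of per-species gene copies and their fates.
#' @slot dupEvents data.frame (species, class, size) of mutation events.
#' @slot genomeLengths named numeric, one chromosome per species.
#' @seealso [simulateClade()], [writeClade()]
#' @export
setClass("SyntheticClade", representation(
  config = "list", tree = "SpeciesTree", reference = "character",
  annotations = "list", refPsl = "list", pairPsl = "list",
  orthogroups = "OrthogroupSet", truth = "data.frame",
  dupEvents = "data.frame", genomeLengths = "numeric"
))

#' SyntenyQuery: the assembled result of one synteny query
#'
#' @slot query `GRanges` of the resolved query region on the reference.
#' @slot reference reference species id.
#' @slot fragments data.frame of retained assembled fragments across
#'   species with a `class` column (primary / co_gene / secondary).
#' @slot discarded data.frame of length-filtered fragments.
#' @slot links data.frame of synteny links between adjacent tracks.
#' @slot genesTable data.frame of genes overlapped by displayed fragments.
#' @slot params list with `gapValue` and `filteringPct` used.
#' @slot displayOrder character, species track order.
#' @export
setClass("SyntenyQuery", representation(
  query = "GRanges", reference = "character", fragments = "data.frame",
  discarded = "data.frame", links = "data.frame", genesTable = "data.frame",
  params = "list", displayOrder = "character"
))
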