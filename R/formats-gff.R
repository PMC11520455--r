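#' Read gene models from GFF3
#'
#' Parses generic GFF3 (via \pkg{rtracklayer}) into a [GeneAnnotation-class]:
#' one model per `gene` feature, with exon/CDS/UTR intervals linked through
#' `ID`/`Parent` attributes. Sub-features whose parent chain cannot be
#' resolved to a gene raise a warning and are skipped. Isoform intervals
#' are collapsed (unioned) per feature type.
#'
#' @param file GFF3 path.
#' @param species species identifier stored on the annotation.
#' @return a [GeneAnnotation-class].
#' @export
readGeneAnnotation <- function(file, species) {
  gr <- tryCatch(
    rtracklayer::import(file, format = "gff3"),
    error = function(e) .formatError("cannot parse GFF3 '%s': %s",
                                     file, conditionMessage(e)))
  # rtracklayer does not carry ##sequence-region into seqinfo; recover the
  # declared lengths ourselves so bounds checks and BedGraph output work
  sl <- NULL
  if (length(file) == 1L && file.exists(file)) {
    dir <- grep("^##sequence-region", readLines(file, n = 200), value = TRUE)
    if (length(dir)) {
      parts <- strsplit(trimws(dir), "\\s+")
      sl <- stats::setNames(
        vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
        vapply(parts, `[`, character(1), 2L))
    }
  }
  if (!length(gr)) {
    empty <- GenomicRanges::GRanges()
    S4Vectors::mcols(empty) <- S4Vectors::DataFrame(gene_id = character(0))
    return(new("GeneAnnotation", species = species, genes = empty,
               features = GenomicRanges::GRanges()))
  }
  type <- as.character(gr$type)
  id <- if (is.null(gr$ID)) rep(NA_character_, length(gr))
        else as.character(gr$ID)
  parent1 <- if (is.null(gr$Parent)) rep(NA_character_, length(gr))
             else vapply(as.list(gr$Parent), function(p)
               if (length(p)) p[[1]] else NA_character_, character(1))

  isGene <- type == "gene"
  genes <- gr[isGene]
  gid <- id[isGene]
  if (anyNA(gid)) .formatError("gene feature without an ID attribute")
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(gene_id = gid)

  # transcript id -> gene id
  isTx <- type %in% c("mRNA", "transcript")
  txGene <- stats::setNames(parent1[isTx], id[isTx])
  orphanTx <- !(txGene %in% gid)
  if (any(orphanTx)) {
    warning(sprintf("skipping %d transcript(s) with unresolved Parent",
                    sum(orphanTx)))
    txGene <- txGene[!orphanTx]
  }

  isSub <- type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  sub <- gr[isSub]
  subParent <- parent1[isSub]
  subGene <- ifelse(subParent %in% gid, subParent,
                    txGene[subParent])
  keep <- !is.na(subGene) & subGene %in% gid
  if (any(!keep))
    warning(sprintf("skipping %d sub-feature(s) with unresolved Parent",
                    sum(!keep)))
  sub <- sub[keep]
  subGene <- subGene[keep]
  subType <- type[isSub][keep]

  # collapse isoforms: union intervals per (gene, type)
  if (length(sub)) {
    key <- paste(subGene, subType, sep = "\r")
    grl <- GenomicRanges::reduce(
      GenomicRanges::split(GenomicRanges::granges(sub), key))
    flat <- unlist(grl, use.names = TRUE)
    parts <- strsplit(names(flat), "\r", fixed = TRUE)
    feat <- GenomicRanges::granges(flat)
    names(feat) <- NULL
    S4Vectors::mcols(feat) <- S4Vectors::DataFrame(
      gene_id = vapply(parts, `[`, character(1), 1L),
      type = vapply(parts, `[`, character(1), 2L))
    idx <- match(feat$gene_id, gid)
    GenomicRanges::strand(feat) <- GenomicRanges::strand(genes)[idx]
    feat <- GenomicRanges::sort(feat, ignore.strand = TRUE)
  } else {
    feat <- GenomicRanges::GRanges()
  }
  genes <- GenomicRanges::sort(genes, ignore.strand = TRUE)
  if (!is.null(sl)) {
    for (obj in c("genes", "feat")) {
      g <- get(obj)
      GenomeInfoDb::seqlevels(g) <-
        union(GenomeInfoDb::seqlevels(g), names(sl))
      GenomeInfoDb::seqlengths(g)[names(sl)] <- sl
      assign(obj, g)
    }
  }
  new("GeneAnnotation", species = species, genes = genes, features = feat)
}

#' Construct a GeneAnnotation from GRanges
#'
#' @param species species identifier.
#' @param genes `GRanges` with a `gene_id` column.
#' @param features `GRanges` with `gene_id` and `type` columns.
#' @param seqlengths optional named vector applied to both GRanges.
#' @return a [GeneAnnotation-class].
#' @export
GeneAnnotation <- function(species, genes, features = GenomicRanges::GRanges(),
                           seqlengths = NULL) {
  if (!is.null(seqlengths)) {
    sl <- stats::setNames(as.integer(seqlengths), names(seqlengths))
    GenomeInfoDb::seqlevels(genes) <- names(sl)
    GenomeInfoDb::seqlengths(genes) <- sl
    if (length(features)) {
      GenomeInfoDb::seqlevels(features) <- names(sl)
      GenomeInfoDb::seqlengths(features) <- sl
    }
  }
  new("GeneAnnotation",
      species = species,
      genes = GenomicRanges::sort(genes, ignore.strand = TRUE),
      features = if (length(features))
        GenomicRanges::sort(features, ignore.strand = TRUE) else features)
}

#' @describeIn GeneAnnotation number of genes.
#' @param x a `GeneAnnotation`.
#' @export
setMethod("length", "GeneAnnotation", function(x) length(x@genes))

setMethod("show", "GeneAnnotation", function(object) {
  cat(sprintf("GeneAnnotation for '%s': %d gene(s), %d sub-feature(s)\n",
              object@species, length(object@genes), length(object@features)))
})

#' Gene spans of an annotation
#' @param x a [GeneAnnotation-class].
#' @return `GRanges` with a `gene_id` column.
#' @export
annotatedGenes <- function(x) x@genes

#' Sub-features of an annotation
#' @param x a [GeneAnnotation-class].
#' @param gene_id optional gene id filter.
#' @param type optional feature type filter.
#' @return `GRanges` with `gene_id` and `type` columns.
#' @export
geneFeatures <- function(x, gene_id = NULL, type = NULL) {
  f <- x@features
  if (!is.null(gene_id)) f <- f[f$gene_id %in% gene_id]
  if (!is.null(type)) f <- f[f$type %in% type]
  f
}

#' Species of an annotation
#' @param x a [GeneAnnotation-class].
#' @export
annotationSpecies <- function(x) x@species

#' Intron intervals of one gene
#'
#' Introns are the inter-exon gaps: the gene span minus the union of its
#' exon intervals.
#'
#' @param x a [GeneAnnotation-class].
#' @param gene_id single gene id.
#' @return `GRanges` of intron intervals.
#' @export
intronRanges <- function(x, gene_id) {
  g <- x@genes[x@genes$gene_id == gene_id]
  if (!length(g)) .userError("unknown gene '%s'", gene_id)
  ex <- geneFeatures(x, gene_id, "exon")
  if (!length(ex)) return(GenomicRanges::GRanges())
  GenomicRanges::setdiff(GenomicRanges::granges(g),
                         GenomicRanges::reduce(GenomicRanges::granges(ex)),
                         ignore.strand = TRUE)
}

#' Look up a gene span
#' @param x a [GeneAnnotation-class].
#' @param gene_id single gene id.
#' @return `GRanges` of length 1.
#' @export
geneSpan <- function(x, gene_id) {
  g <- x@genes[x@genes$gene_id == gene_id]
  if (!length(g)) .userError("unknown gene '%s'", gene_id)
  g
}

#' Write a GeneAnnotation as GFF3
#'
#' Canonical writer: genes sorted by position, one synthetic `mRNA` per
#' gene carrying the collapsed sub-features, `ID`/`Parent` linkage, and
#' `##sequence-region` directives when sequence lengths are known. Files
#' produced here re-read into an identical [GeneAnnotation-class] and
#' round-trip byte-for-byte through [readGeneAnnotation()] + `writeGff3`.
#'
#' @param x a [GeneAnnotation-class].
#' @param file output path or `NULL` to return lines.
#' @return the lines, invisibly when `file` is given.
#' @export
writeGff3 <- function(x, file = NULL) {
  lines <- "##gff-version 3"
  sl <- GenomeInfoDb::seqlengths(x@genes)
  sl <- sl[!is.na(sl)]
  for (s in names(sl))
    lines <- c(lines, sprintf("##sequence-region %s 1 %d", s, sl[[s]]))
  g <- x@genes
  feat <- x@features
  row <- function(seq, type, start, end, strand, attrs)
    paste(seq, "cladesynteny", type, start, end, ".", strand, ".", attrs,
          sep = "\t")
  for (i in seq_along(g)) {
    gid <- g$gene_id[i]
    seq <- as.character(GenomeInfoDb::seqnames(g))[i]
    st <- as.character(GenomicRanges::strand(g))[i]
    if (st == "*") st <- "+"
    lines <- c(lines, row(seq, "gene", GenomicRanges::start(g)[i],
                          GenomicRanges::end(g)[i], st,
                          sprintf("ID=%s", gid)))
    fid <- sprintf("%s.t1", gid)
    lines <- c(lines, row(seq, "mRNA", GenomicRanges::start(g)[i],
                          GenomicRanges::end(g)[i], st,
                          sprintf("ID=%s;Parent=%s", fid, gid)))
    ff <- feat[feat$gene_id == gid]
    if (length(ff)) {
      ff <- ff[order(GenomicRanges::start(ff),
                     match(ff$type, c("exon", "five_prime_UTR", "CDS",
                                      "three_prime_UTR")))]
      for (j in seq_along(ff))
        lines <- c(lines, row(seq, ff$type[j], GenomicRanges::start(ff)[j],
                              GenomicRanges::end(ff)[j], st,
                              sprintf("Parent=%s", fid)))
    }
  }
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}
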