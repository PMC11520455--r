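#' Write a synthetic clade as pipeline input files
#'
#' Materialises a [SyntheticClade-class] in the exact dialects the format
#' readers consume: per-species GFF3, PSL per non-reference species
#' (reference as query), pairwise PSL for adjacent display pairs, the
#' orthogroup TSV, the newick guide tree, the mutation-event TSV, the
#' ground-truth TSV and a small `meta.tsv` (reference species).
#'
#' @param clade a [SyntheticClade-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeClade <- function(clade, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSpeciesTree(clade@tree, file.path(dir, "tree.nwk"))
  writeOrthogroups(clade@orthogroups, file.path(dir, "orthogroups.tsv"))
  for (sp in names(clade@annotations))
    writeGff3(clade@annotations[[sp]], file.path(dir, paste0(sp, ".gff3")))
  for (sp in names(clade@refPsl))
    writePsl(clade@refPsl[[sp]], file.path(dir, paste0("ref_", sp, ".psl")))
  for (key in names(clade@pairPsl)) {
    ab <- strsplit(key, "|", fixed = TRUE)[[1]]
    writePsl(clade@pairPsl[[key]],
             file.path(dir, sprintf("pair_%s__%s.psl", ab[1], ab[2])))
  }
  .writeTsv(clade@dupEvents, file.path(dir, "dup_events.tsv"))
  .writeTsv(clade@truth, file.path(dir, "truth.tsv"))
  .writeTsv(data.frame(key = "reference", value = clade@reference,
                       stringsAsFactors = FALSE),
            file.path(dir, "meta.tsv"))
  invisible(dir)
}

#' Read pipeline inputs from a clade directory
#'
#' Loads a directory written by [writeClade()] (or assembled by hand in
#' the same layout) into the pieces [runSyntenyQuery()] needs.
#'
#' @param dir directory path.
#' @return list with `reference`, `tree`, `annotations`, `refPsl`,
#'   `pairPsl`, `orthogroups`, and (when present) `dupEvents` and `truth`
#'   data.frames.
#' @export
readClade <- function(dir) {
  meta <- utils::read.delim(file.path(dir, "meta.tsv"),
                            stringsAsFactors = FALSE)
  reference <- meta$value[meta$key == "reference"]
  tree <- readSpeciesTree(file.path(dir, "tree.nwk"))
  annotations <- list()
  for (sp in displayOrder(tree))
    annotations[[sp]] <- readGeneAnnotation(
      file.path(dir, paste0(sp, ".gff3")), sp)
  refPsl <- list()
  for (f in list.files(dir, pattern = "^ref_.*\\.psl$")) {
    sp <- sub("^ref_(.*)\\.psl$", "\\1", f)
    refPsl[[sp]] <- readPsl(file.path(dir, f))
  }
  pairPsl <- list()
  for (f in list.files(dir, pattern = "^pair_.*\\.psl$")) {
    ab <- strsplit(sub("^pair_(.*)\\.psl$", "\\1", f), "__",
                   fixed = TRUE)[[1]]
    pairPsl[[paste(ab[1], ab[2], sep = "|")]] <- readPsl(file.path(dir, f))
  }
  out <- list(reference = reference, tree = tree,
              annotations = annotations, refPsl = refPsl,
              pairPsl = pairPsl,
              orthogroups = readOrthogroups(file.path(dir, "orthogroups.tsv")))
  devf <- file.path(dir, "dup_events.tsv")
  if (file.exists(devf)) out$dupEvents <- readDupEvents(devf)
  trf <- file.path(dir, "truth.tsv")
  if (file.exists(trf))
    out$truth <- utils::read.delim(trf, stringsAsFactors = FALSE)
  out
}

setMethod("show", "SyntheticClade", function(object) {
  cat(sprintf("SyntheticClade: %d species (reference %s), %d orthogroups\n",
              length(object@annotations), object@reference,
              length(object@orthogroups)))
  cat(sprintf("  %d truth rows; %d mutation events; seed %d\n",
              nrow(object@truth), nrow(object@dupEvents),
              object@config$seed))
})

#' Accessors for SyntheticClade slots
#' @param x a [SyntheticClade-class].
#' @return the corresponding slot.
#' @export
cladeAnnotations <- function(x) x@annotations

#' @rdname cladeAnnotations
#' @export
cladeRefPsl <- function(x) x@refPsl

#' @rdname cladeAnnotations
#' @export
cladePairPsl <- function(x) x@pairPsl

#' @rdname cladeAnnotations
#' @export
cladeTree <- function(x) x@tree

#' @rdname cladeAnnotations
#' @export
cladeReference <- function(x) x@reference

#' @rdname cladeAnnotations
#' @export
cladeOrthogroups <- function(x) x@orthogroups

#' @rdname cladeAnnotations
#' @export
cladeTruth <- function(x) x@truth

#' @rdname cladeAnnotations
#' @export
cladeDupEvents <- function(x) x@dupEvents

#' @rdname cladeAnnotations
#' @export
cladeGenomeLengths <- function(x) x@genomeLengths

#' Reference gene classes of a simulated clade
#'
#' Classifies the annotated reference genes the way duplicate-gene depth
#' analyses bin them: `single_copy` (exactly one annotated copy in every
#' species, no losses, no duplications anywhere in the orthogroup),
#' `ancient` / `old` / `recent` duplicates by the epoch of the most
#' recent duplication on the reference lineage, and `other` (everything
#' else, e.g. orthogroups duplicated off the reference path or with
#' losses).
#'
#' @param clade a [SyntheticClade-class].
#' @return named list of character vectors of reference gene ids.
#' @export
geneClasses <- function(clade) {
  tr <- cladeTruth(clade)
  ref <- cladeReference(clade)
  nsp <- length(cladeAnnotations(clade))
  perOg <- split(tr, tr$orthogroup)
  singleOgs <- names(perOg)[vapply(perOg, function(g) {
    !any(g$status == "lost") && !any(g$role %in% c("parent", "daughter")) &&
      all(table(factor(g$species[g$status != "lost"],
                       levels = unique(tr$species))) == 1L) &&
      all(g$status[!is.na(g$gene_id)] == "annotated")
  }, logical(1))]
  rt <- tr[tr$species == ref & tr$status == "annotated", , drop = FALSE]
  out <- list(
    single_copy = rt$gene_id[rt$orthogroup %in% singleOgs],
    recent = rt$gene_id[rt$epoch == "recent"],
    old = rt$gene_id[rt$epoch == "old"],
    ancient = rt$gene_id[rt$epoch == "ancient"])
  out$other <- setdiff(rt$gene_id, unlist(out))
  out
}
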