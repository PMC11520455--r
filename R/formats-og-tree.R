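#' Read an orthogroup table
#'
#' Tab-separated, one orthogroup per row: column 1 is the orthogroup id,
#' the remaining columns (named after species in the header) hold
#' comma-separated gene ids. A gene listed in two orthogroups is an error.
#'
#' @param file path, or a character vector of lines.
#' @return an [OrthogroupSet-class].
#' @export
readOrthogroups <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\t", file) && file.exists(file))
    readLines(file) else file
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) .formatError("orthogroup table is empty")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 2L)
    .formatError("orthogroup table needs an id column and >=1 species column")
  species <- hdr[-1]
  rows <- list()
  for (i in seq_along(lines)[-1]) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    length(f) <- length(hdr)          # pad short rows with NA
    og <- f[1]
    for (j in seq_along(species)) {
      cell <- f[j + 1L]
      if (is.na(cell) || !nzchar(trimws(cell))) next
      genes <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
      genes <- genes[nzchar(genes)]
      if (length(genes))
        rows[[length(rows) + 1L]] <- data.frame(
          orthogroup = og, species = species[j], gene_id = genes,
          stringsAsFactors = FALSE)
    }
  }
  tb <- if (length(rows)) do.call(rbind, rows) else
    data.frame(orthogroup = character(0), species = character(0),
               gene_id = character(0), stringsAsFactors = FALSE)
  dup <- duplicated(tb$gene_id)
  if (any(dup))
    .formatError("gene '%s' is assigned to more than one orthogroup",
                 tb$gene_id[dup][1])
  new("OrthogroupSet", table = tb, species = species)
}

#' Construct an OrthogroupSet from a long table
#' @param table data.frame with columns `orthogroup`, `species`, `gene_id`.
#' @param species optional species order (defaults to order of appearance).
#' @return an [OrthogroupSet-class].
#' @export
OrthogroupSet <- function(table, species = unique(table$species)) {
  rownames(table) <- NULL
  new("OrthogroupSet", table = table, species = species)
}

#' @describeIn OrthogroupSet number of orthogroups.
#' @param x an `OrthogroupSet`.
#' @export
setMethod("length", "OrthogroupSet", function(x)
  length(unique(x@table$orthogroup)))

setMethod("show", "OrthogroupSet", function(object) {
  cat(sprintf("OrthogroupSet: %d orthogroup(s), %d gene(s), %d species\n",
              length(object), nrow(object@table), length(object@species)))
})

#' Access the long-format orthogroup table
#' @param x an [OrthogroupSet-class].
#' @return data.frame with columns `orthogroup`, `species`, `gene_id`.
#' @export
orthogroupTable <- function(x) x@table

#' Orthogroup membership lookups
#'
#' `orthogroupOf` maps gene ids to their orthogroup (NA when unassigned);
#' `orthogroupMembers` lists the genes of one orthogroup, optionally for
#' one species.
#'
#' @param x an [OrthogroupSet-class].
#' @param gene_id character vector of gene ids.
#' @return for `orthogroupOf`, a character vector parallel to `gene_id`.
#' @export
orthogroupOf <- function(x, gene_id) {
  x@table$orthogroup[match(gene_id, x@table$gene_id)]
}

#' @rdname orthogroupOf
#' @param orthogroup single orthogroup id.
#' @param species optional species filter.
#' @export
orthogroupMembers <- function(x, orthogroup, species = NULL) {
  tb <- x@table[x@table$orthogroup == orthogroup, , drop = FALSE]
  if (!nrow(tb)) .userError("orthogroup '%s' not found", orthogroup)
  if (!is.null(species)) tb <- tb[tb$species %in% species, , drop = FALSE]
  tb$gene_id
}

#' Write an orthogroup table
#' @param x an [OrthogroupSet-class].
#' @param file output path or `NULL` to return lines.
#' @return the lines, invisibly when `file` is given.
#' @export
writeOrthogroups <- function(x, file = NULL) {
  tb <- x@table
  ogs <- unique(tb$orthogroup)
  lines <- paste(c("Orthogroup", x@species), collapse = "\t")
  for (og in ogs) {
    cells <- vapply(x@species, function(sp)
      paste(tb$gene_id[tb$orthogroup == og & tb$species == sp],
            collapse = ","), character(1))
    lines <- c(lines, paste(c(og, cells), collapse = "\t"))
  }
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Read a species guide tree
#'
#' Parses newick (via \pkg{ape}) and derives the display order: the
#' left-to-right leaf traversal of the tree as written, which places
#' sister taxa on adjacent plot tracks.
#'
#' @param file newick path, or a newick string.
#' @return a [SpeciesTree-class].
#' @examples
#' displayOrder(readSpeciesTree("((A,B),(C,D));"))
#' @export
readSpeciesTree <- function(file) {
  txt <- if (length(file) == 1L && file.exists(file))
    paste(readLines(file), collapse = "") else paste(file, collapse = "")
  tree <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(tree))
    .formatError("cannot parse newick tree")
  if (anyDuplicated(tree$tip.label))
    .formatError("duplicated leaf labels in species tree")
  new("SpeciesTree", tree = tree, displayOrder = .leafOrder(tree))
}

# Leaves in cladewise (left-to-right as written) traversal order.
.leafOrder <- function(tree) {
  tree <- stats::reorder(tree, "cladewise")
  tips <- tree$edge[, 2][tree$edge[, 2] <= length(tree$tip.label)]
  tree$tip.label[tips]
}

#' Display order of a species tree
#' @param x a [SpeciesTree-class].
#' @return character vector of leaf names in track order.
#' @export
displayOrder <- function(x) x@displayOrder

#' The underlying phylo object
#' @param x a [SpeciesTree-class].
#' @export
guideTree <- function(x) x@tree

setMethod("show", "SpeciesTree", function(object) {
  cat(sprintf("SpeciesTree with %d leaves: %s\n",
              length(object@displayOrder),
              paste(object@displayOrder, collapse = ", ")))
})

#' Write a species tree as newick
#' @param x a [SpeciesTree-class].
#' @param file output path.
#' @export
writeSpeciesTree <- function(x, file) {
  ape::write.tree(x@tree, file = file)
  invisible(file)
}

#' Validate assembly parameters
#'
#' The two user-facing pipeline parameters: the gap value (maximum base-pair
#' gap between adjacent liftover fragments merged into one assembled
#' fragment; default 200) and the filtering percentage (minimum assembled
#' fragment length as a percentage of the query length; default 16).
#'
#' @param gapValue gap value in bp, `>= 0`.
#' @param filteringPct filtering percentage in `[0, 100]`.
#' @return a named list with the validated parameters.
#' @export
paramSet <- function(gapValue = 200, filteringPct = 16) {
  if (!is.numeric(gapValue) || length(gapValue) != 1L || gapValue < 0)
    .userError("gapValue must be a single number >= 0")
  if (!is.numeric(filteringPct) || length(filteringPct) != 1L ||
      filteringPct < 0 || filteringPct > 100)
    .userError("filteringPct must be in [0, 100]")
  list(gapValue = gapValue, filteringPct = filteringPct)
}
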