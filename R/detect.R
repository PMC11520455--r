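#' Flag species missing an ortholog, with annotation-gap candidates
#'
#' For an orthogroup with a reference member, runs the synteny query on
#' the reference gene and inspects every species that lacks an annotated
#' member: if a retained fragment still covers the expected syntenic
#' interval, the species is flagged as an annotation-gap candidate (the
#' gene is probably there but missing from the GFF3) and the primary
#' fragment span is reported as the candidate interval; if no fragment is
#' retained, the species is flagged as a loss/divergence candidate.
#'
#' @param orthogroup orthogroup id.
#' @param orthogroups an [OrthogroupSet-class].
#' @param reference reference species id.
#' @param annotations named list of [GeneAnnotation-class].
#' @param refPsl named list of [PslAlignments-class] (reference as query).
#' @param tree a [SpeciesTree-class].
#' @param gapValue,filteringPct assembly parameters.
#' @return data.frame with `orthogroup`, `species`, `status`
#'   (`annotation_gap` / `loss_or_divergence`) and the candidate interval
#'   (`seq`, `start`, `end`; NA for losses). Zero rows when every species
#'   has an annotated member.
#' @export
detectMissingOrtholog <- function(orthogroup, orthogroups, reference,
                                  annotations, refPsl, tree,
                                  gapValue = 200, filteringPct = 16) {
  tb <- orthogroupTable(orthogroups)
  if (!orthogroup %in% tb$orthogroup)
    .userError("orthogroup '%s' not in the table", orthogroup)
  members <- tb[tb$orthogroup == orthogroup, , drop = FALSE]
  if (length(unique(members$species)) < 2L)
    .userError("orthogroup '%s' has members in fewer than 2 species",
               orthogroup)
  refGenes <- members$gene_id[members$species == reference]
  if (!length(refGenes))
    .userError("orthogroup '%s' has no member in reference '%s'",
               orthogroup, reference)
  qr <- runSyntenyQuery(refGenes[1], reference, annotations, refPsl, tree,
                        gapValue = gapValue, filteringPct = filteringPct)
  frags <- queryFragments(qr)
  out <- list()
  for (sp in setdiff(displayOrder(tree), reference)) {
    if (sp %in% members$species) next
    f <- frags[frags$species == sp, , drop = FALSE]
    if (nrow(f)) {
      prim <- f[f$class == "primary", , drop = FALSE][1, ]
      out[[length(out) + 1L]] <- data.frame(
        orthogroup = orthogroup, species = sp, status = "annotation_gap",
        seq = prim$t_seq, start = prim$t_start, end = prim$t_end,
        stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        orthogroup = orthogroup, species = sp,
        status = "loss_or_divergence", seq = NA_character_,
        start = NA_integer_, end = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(orthogroup = character(0), species = character(0),
               status = character(0), seq = character(0),
               start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Screen every orthogroup of a clade for missing orthologs
#'
#' Convenience wrapper running [detectMissingOrtholog()] over all
#' orthogroups that have a reference member; orthogroups with members in
#' fewer than two species are skipped.
#'
#' @param orthogroups an [OrthogroupSet-class].
#' @inheritParams detectMissingOrtholog
#' @return row-bound detection reports (possibly zero rows).
#' @export
screenMissingOrthologs <- function(orthogroups, reference, annotations,
                                   refPsl, tree, gapValue = 200,
                                   filteringPct = 16) {
  tb <- orthogroupTable(orthogroups)
  out <- list()
  for (og in unique(tb$orthogroup)) {
    members <- tb[tb$orthogroup == og, , drop = FALSE]
    if (length(unique(members$species)) < 2L) next
    if (!reference %in% members$species) next
    out[[length(out) + 1L]] <- detectMissingOrtholog(
      og, orthogroups, reference, annotations, refPsl, tree,
      gapValue = gapValue, filteringPct = filteringPct)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(orthogroup = character(0), species = character(0),
               status = character(0), seq = character(0),
               start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
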