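# Finalization of a simulated clade: genome layout, annotations, PSL
# emission, orthogroups, ground truth. Split from the evolution step for
# readability; everything here is deterministic given the evolved state
# and the RNG stream.

# shared ancestral substitution load of two copies, given the tree MRCA of
# their species: the snapshot at the MRCA if they were still one lineage
# there, otherwise the registry value at the duplication where the
# lineages split.
.sharedSubs <- function(a, b, mrca, dupRegistry) {
  sa <- a$snapshots[[as.character(mrca)]]
  sb <- b$snapshots[[as.character(mrca)]]
  if (identical(sa$path, sb$path)) return(min(sa$subs, sb$subs))
  ta <- strsplit(sa$path, "|", fixed = TRUE)[[1]]
  tb <- strsplit(sb$path, "|", fixed = TRUE)[[1]]
  n <- min(length(ta), length(tb))
  j <- which(ta[seq_len(n)] != tb[seq_len(n)])
  j <- if (length(j)) j[1] else n + 1L
  cand <- c(if (j <= length(ta)) ta[j], if (j <= length(tb)) tb[j])
  ids <- sub("^D", "", cand[startsWith(cand, "D")])
  min(vapply(ids, function(id) dupRegistry[[id]]$subs, numeric(1)))
}

# root-coordinate intervals of the CDS and UTRs of an ancestral gene:
# first/last utrLength exonic bases are UTR, the rest of the exons is CDS
.rootGeneParts <- function(gene, utrLength) {
  ex <- gene$exons
  exIr <- IRanges::IRanges(ex[, 1] + 1L, ex[, 2])  # 1-based on root coords
  exonic <- sum(IRanges::width(exIr))
  u <- min(utrLength, max(0L, (exonic - 3L) %/% 2L))
  takeBases <- function(ir, n, fromStart) {
    picked <- IRanges::IRanges()
    idx <- if (fromStart) seq_along(ir) else rev(seq_along(ir))
    for (i in idx) {
      if (n <= 0L) break
      w <- min(n, IRanges::width(ir)[i])
      picked <- c(picked, if (fromStart)
        IRanges::IRanges(IRanges::start(ir)[i], IRanges::start(ir)[i] + w - 1L)
        else IRanges::IRanges(IRanges::end(ir)[i] - w + 1L, IRanges::end(ir)[i]))
      n <- n - w
    }
    picked
  }
  utr5 <- takeBases(exIr, u, TRUE)
  utr3 <- takeBases(exIr, u, FALSE)
  cds <- IRanges::setdiff(exIr, IRanges::union(utr5, utr3))
  list(exon = exIr, CDS = cds, five_prime_UTR = utr5, three_prime_UTR = utr3)
}

# map 1-based root intervals through a homology map into genome
# coordinates (1-based closed) of a placed copy
.mapFeature <- function(ir, map, gstart, glen, strand) {
  mm <- .mapMatched(map)
  out <- list()
  for (k in seq_along(ir)) {
    rs <- IRanges::start(ir)[k] - 1L; re <- IRanges::end(ir)[k]
    for (i in seq_len(nrow(mm))) {
      s <- max(rs, mm$rs[i]); e <- min(re, mm$re[i])
      if (s >= e) next
      ls <- mm$local[i] + (s - mm$rs[i]); le <- ls + (e - s)
      out[[length(out) + 1L]] <- c(ls, le)
    }
  }
  if (!length(out)) return(IRanges::IRanges())
  loc <- do.call(rbind, out)
  gs <- if (strand == "+") gstart + loc[, 1] else gstart + glen - loc[, 2]
  IRanges::reduce(IRanges::IRanges(gs, gs + (loc[, 2] - loc[, 1]) - 1L))
}

# leaves under a node
.leavesUnder <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, .leavesUnder, phy = phy))
}

.assembleClade <- function(env, st, phy, rootGenes, refPath) {
  cfg <- env$cfg
  ord <- displayOrder(st)
  ref <- cfg$reference
  ntip <- length(phy$tip.label)
  ogId <- function(og) sprintf("OG%04d", og)

  # species-specific intron elongation, as insertions at intron midpoints
  if (cfg$intronExpansion > 1) {
    for (sp in setdiff(ord, ref)) {
      copies <- env$leaves[[sp]]
      for (ci in seq_along(copies)) {
        g <- rootGenes[[copies[[ci]]$og]]
        ex <- g$exons
        if (nrow(ex) < 2L) next
        for (j in seq_len(nrow(ex) - 1L)) {
          mid <- (ex[j, 2] + ex[j + 1L, 1]) %/% 2L
          extra <- round((cfg$intronExpansion - 1) *
                           (ex[j + 1L, 1] - ex[j, 2]))
          if (extra < 1) next
          copies[[ci]]$map <- tryCatch(
            mapInsertion(copies[[ci]]$map, mid, extra),
            error = function(e) copies[[ci]]$map)
        }
      }
      env$leaves[[sp]] <- copies
    }
  }

  # annotation gaps: present, sole-copy genes of non-reference leaves
  annotGap <- list()
  refOgs <- vapply(env$leaves[[ref]], `[[`, numeric(1), "og")
  for (sp in ord) {
    copies <- env$leaves[[sp]]
    gap <- logical(length(copies))
    if (sp != ref && cfg$annotationGapProb > 0) {
      ogs <- vapply(copies, `[[`, numeric(1), "og")
      cnt <- table(ogs)
      for (ci in seq_along(copies)) {
        if (cnt[[as.character(ogs[ci])]] > 1L) next
        if (!(ogs[ci] %in% refOgs)) next
        if (stats::runif(1) < cfg$annotationGapProb) gap[ci] <- TRUE
      }
    }
    annotGap[[sp]] <- gap
  }

  # genome layout
  layout <- list(); genomeLengths <- c()
  for (sp in ord) {
    copies <- env$leaves[[sp]]
    pos <- vapply(copies, `[[`, numeric(1), "orderPos")
    o <- order(pos)
    copies <- copies[o]
    gapFlag <- annotGap[[sp]][o]
    cursor <- 0L; rows <- list()
    for (ci in seq_along(copies)) {
      cp <- copies[[ci]]
      igap <- .runifInt(cfg$intergenicRange[1], cfg$intergenicRange[2])
      gstart <- cursor + igap + 1L
      glen <- mapLength(cp$map)
      rows[[ci]] <- list(copy = cp, gstart = gstart, glen = glen,
                         annotated = !gapFlag[ci])
      cursor <- gstart + glen - 1L
    }
    finalGap <- .runifInt(cfg$intergenicRange[1], cfg$intergenicRange[2])
    layout[[sp]] <- rows
    genomeLengths[sp] <- cursor + finalGap
  }
  chrom <- stats::setNames(paste0(ord, "_I"), ord)

  # annotations + truth rows
  partsCache <- lapply(rootGenes, .rootGeneParts, utrLength = cfg$utrLength)
  annotations <- list(); truthRows <- list(); ogRows <- list()
  for (sp in ord) {
    rows <- layout[[sp]]
    gR <- list(); fR <- list()
    for (r in rows) {
      cp <- r$copy
      gid <- .copyGeneId(sp, cp)
      parts <- partsCache[[cp$og]]
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        species = sp, gene_id = gid, orthogroup = ogId(cp$og),
        root_gene = cp$og, suffix = cp$suffix, role = cp$role,
        epoch = .classifyEpoch(cp, env, refPath, phy),
        status = if (r$annotated) "annotated" else "unannotated",
        seq = chrom[[sp]], start = r$gstart,
        end = r$gstart + r$glen - 1L, strand = cp$strand,
        divergence = cp$subs, path = cp$path, stringsAsFactors = FALSE)
      if (!r$annotated) next
      gR[[length(gR) + 1L]] <- data.frame(
        seq = chrom[[sp]], start = r$gstart, end = r$gstart + r$glen - 1L,
        strand = cp$strand, gene_id = gid, stringsAsFactors = FALSE)
      for (ft in names(parts)) {
        ir <- .mapFeature(parts[[ft]], cp$map, r$gstart, r$glen, cp$strand)
        if (!length(ir)) next
        fR[[length(fR) + 1L]] <- data.frame(
          seq = chrom[[sp]], start = IRanges::start(ir),
          end = IRanges::end(ir), strand = cp$strand, gene_id = gid,
          type = ft, stringsAsFactors = FALSE)
      }
      ogRows[[length(ogRows) + 1L]] <- data.frame(
        orthogroup = ogId(cp$og), species = sp, gene_id = gid,
        stringsAsFactors = FALSE)
    }
    gdf <- do.call(rbind, gR)
    fdf <- do.call(rbind, fR)
    genes <- GenomicRanges::GRanges(gdf$seq,
      IRanges::IRanges(gdf$start, gdf$end), strand = gdf$strand,
      gene_id = gdf$gene_id)
    feats <- GenomicRanges::GRanges(fdf$seq,
      IRanges::IRanges(fdf$start, fdf$end), strand = fdf$strand,
      gene_id = fdf$gene_id, type = fdf$type)
    sl <- stats::setNames(genomeLengths[[sp]], chrom[[sp]])
    annotations[[sp]] <- GeneAnnotation(sp, genes, feats, seqlengths = sl)
  }

  # loss truth rows
  for (ls in env$losses) {
    for (sp in .leavesUnder(phy, ls$node)) {
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        species = sp, gene_id = NA_character_, orthogroup = ogId(ls$og),
        root_gene = ls$og, suffix = NA_integer_, role = "lost",
        epoch = "none", status = "lost", seq = NA_character_,
        start = NA_integer_, end = NA_integer_, strand = NA_character_,
        divergence = NA_real_, path = ls$path, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truthRows)
  rownames(truth) <- NULL

  # mutation events attributed to descendant leaves
  evRows <- list()
  for (ev in env$events) {
    for (sp in .leavesUnder(phy, ev$node)) {
      evRows[[length(evRows) + 1L]] <- data.frame(
        species = sp, class = ev$class, size = ev$size,
        stringsAsFactors = FALSE)
    }
  }
  dupEvents <- if (length(evRows)) do.call(rbind, evRows) else
    data.frame(species = character(0), class = character(0),
               size = numeric(0), stringsAsFactors = FALSE)

  orthogroups <- OrthogroupSet(do.call(rbind, ogRows), species = ord)

  # PSL emission
  emitPair <- function(spQ, spT) {
    mrca <- ape::getMRCA(phy, c(spQ, spT))
    rowsQ <- layout[[spQ]]; rowsT <- layout[[spT]]
    ogT <- vapply(rowsT, function(r) r$copy$og, numeric(1))
    recs <- list()
    for (rq in rowsQ) {
      for (ti in which(ogT == rq$copy$og)) {
        rt <- rowsT[[ti]]
        d <- rq$copy$subs + rt$copy$subs -
          2 * .sharedSubs(rq$copy, rt$copy, mrca, env$dupRegistry)
        if (d > cfg$maxDivergence) next
        rec <- .fragmentRecords(
          rq$copy$map, rt$copy$map,
          qName = chrom[[spQ]], qSize = genomeLengths[[spQ]],
          qOffset = rq$gstart, qStrand = rq$copy$strand,
          tName = chrom[[spT]], tSize = genomeLengths[[spT]],
          tOffset = rt$gstart, tStrand = rt$copy$strand,
          divergence = d, breakAtIndels = cfg$breakAtIndels,
          minBlock = cfg$minBlock)
        if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
      }
    }
    if (!length(recs)) return(PslAlignments())
    PslAlignments(do.call(rbind, recs))
  }

  refPsl <- list()
  for (sp in setdiff(ord, ref)) refPsl[[sp]] <- emitPair(ref, sp)
  pairPsl <- list()
  for (k in seq_len(length(ord) - 1L)) {
    a <- ord[k]; b <- ord[k + 1L]
    pairPsl[[paste(a, b, sep = "|")]] <-
      if (a == ref) refPsl[[b]] else emitPair(a, b)
  }

  new("SyntheticClade", config = cfg, tree = st, reference = ref,
      annotations = annotations, refPsl = refPsl, pairPsl = pairPsl,
      orthogroups = orthogroups, truth = truth, dupEvents = dupEvents,
      genomeLengths = stats::setNames(as.numeric(genomeLengths[ord]),
                                      chrom[ord]))
}

# duplication epoch of a copy relative to the reference lineage:
# ancient = before any split; recent = on the reference terminal branch;
# old = on an internal branch of the reference path; other = off-path.
.classifyEpoch <- function(cp, env, refPath, phy) {
  toks <- strsplit(cp$path, "|", fixed = TRUE)[[1]]
  dups <- sub("^D", "", toks[startsWith(toks, "D")])
  if (!length(dups)) {
    # an undup'd copy can still be the parent of a duplication event
    if (cp$role == "parent") {
      ids <- names(env$dupRegistry)[vapply(env$dupRegistry, function(d)
        d$og == cp$og, logical(1))]
      if (length(ids)) dups <- ids[length(ids)]
    }
  }
  if (!length(dups)) return("none")
  d <- env$dupRegistry[[dups[length(dups)]]]   # most recent duplication
  if (!is.null(d$epoch) && !is.na(d$epoch)) return(d$epoch)
  ntip <- length(phy$tip.label)
  rootNode <- ntip + 1L
  if (d$node == rootNode) return("ancient")
  if (!(d$node %in% refPath)) return("other")
  if (d$node <= ntip) "recent" else "old"
}
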