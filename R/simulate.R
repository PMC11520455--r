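#' Configuration for a synthetic clade
#'
#' Bundles (and validates) the parameters of the coordinate-level clade
#' simulator. Evolution happens on gene copies carried along the guide
#' tree: substitutions accumulate as expected per-base divergence (with
#' mild gamma noise), small indels break the homology maps, duplications
#' create tandem or dispersed daughter copies (with extra divergence for
#' the daughter), inversions flip copy orientation, and losses remove
#' copies. Loss and annotation-gap events are only drawn from copies that
#' are single-copy in their genome, so the ground truth stays identifiable
#' from synteny. Rates are per unit branch length (per copy, except
#' `subRate`, which is per base).
#'
#' @param seed RNG seed; the whole clade is deterministic given the seed.
#' @param tree newick guide tree with branch lengths.
#' @param reference reference species (leaf name).
#' @param nGenes number of ancestral genes.
#' @param exonCountRange,exonSizeRange,intronSizeRange,utrLength,
#'   intergenicRange gene and genome geometry (bp).
#' @param subRate expected substitutions per base per unit branch length.
#' @param subNoise multiply each branch's substitution load by a
#'   `Gamma(40, 40)` draw (mean 1) to avoid perfectly clock-like leaves.
#' @param indelRate expected indels per copy per unit branch length.
#' @param indelSizeRange uniform indel size range in bp.
#' @param dupRate expected duplications per copy per unit branch length.
#' @param tandemFraction probability a daughter is tandem (adjacent to its
#'   parent) rather than dispersed.
#' @param daughterExtraDivergence divergence added to a daughter copy at
#'   birth (accelerated evolution of the redundant copy).
#' @param inversionRate,lossRate per-copy rates of whole-copy inversion
#'   and gene loss.
#' @param annotationGapProb per-gene probability (non-reference leaves)
#'   that a present gene is dropped from the GFF3 while its alignment
#'   remains -- an annotation gap.
#' @param maxDivergence pairs more diverged than this are not emitted,
#'   emulating liftover mapping failure on highly diverged sequence.
#' @param intronExpansion multiply intron lengths at the leaves by this
#'   factor (1 = off), applied as insertions at intron midpoints.
#' @param breakAtIndels,minBlock liftover fragmentation (see
#'   [fragmentAlignments()]).
#' @param forcedDuplications optional list of
#'   `list(epoch = "ancient"|"recent", count =, extraDivergence =)`
#'   entries: "ancient" duplications are applied before the root splits,
#'   "recent" ones on the reference terminal branch.
#' @return a validated config list for [simulateClade()].
#' @export
simCladeConfig <- function(seed = 42,
                           tree = "(((S1:1,S2:1):1,(S3:1,S4:1):1):1,S5:3);",
                           reference = "S1",
                           nGenes = 100,
                           exonCountRange = c(2, 6),
                           exonSizeRange = c(80, 300),
                           intronSizeRange = c(50, 200),
                           utrLength = 60,
                           intergenicRange = c(500, 3500),
                           subRate = 0.02,
                           subNoise = TRUE,
                           indelRate = 0.5,
                           indelSizeRange = c(10, 150),
                           dupRate = 0.004,
                           tandemFraction = 0.7,
                           daughterExtraDivergence = 0.12,
                           inversionRate = 0.01,
                           lossRate = 0.003,
                           annotationGapProb = 0.02,
                           maxDivergence = 0.35,
                           intronExpansion = 1,
                           breakAtIndels = TRUE,
                           minBlock = 1,
                           forcedDuplications = NULL) {
  cfg <- as.list(environment())
  rates <- c(cfg$subRate, cfg$indelRate, cfg$dupRate, cfg$inversionRate,
             cfg$lossRate, cfg$annotationGapProb)
  if (any(rates < 0)) .userError("rates must be >= 0")
  if (cfg$nGenes < 1) .userError("nGenes must be >= 1")
  st <- readSpeciesTree(cfg$tree)
  if (!cfg$reference %in% displayOrder(st))
    .userError("reference '%s' is not a leaf of the tree", cfg$reference)
  cfg
}

# ---- internal simulation machinery ------------------------------------

# One gene copy: a homology map plus lineage bookkeeping.
# path: lineage tokens ("L<og>", then "D<id>" per duplication).
# snapshots: per ancestral tree node, list(path, subs) at that node.
.newCopy <- function(og, suffix, rootLen) {
  list(og = og, suffix = suffix, path = sprintf("L%d", og),
       strand = "+", map = homologyMap(rootLen), subs = 0,
       role = "single", birthNode = NA_integer_, epoch = "none",
       orderPos = og, snapshots = list())
}

.copyGeneId <- function(species, copy) {
  base <- sprintf("%s_g%03d", species, copy$og)
  if (copy$suffix > 1L) paste0(base, ".", copy$suffix) else base
}

# uniform integer in [a, b]; safe for a == b (unlike sample())
.runifInt <- function(a, b, n = 1L) {
  as.integer(floor(stats::runif(n, a, b + 1)))
}

# Draw a root position uniformly over the matched bases of a map.
.drawMatchedPos <- function(map) {
  mm <- .mapMatched(map)
  w <- mm$re - mm$rs
  i <- sample.int(nrow(mm), 1L, prob = w)
  mm$rs[i] + sample.int(w[i], 1L) - 1L
}

.applyDuplication <- function(env, copies, ci, node, epoch, extraDiv) {
  cfg <- env$cfg
  parent <- copies[[ci]]
  env$dupCounter <- env$dupCounter + 1L
  did <- env$dupCounter
  env$dupRegistry[[as.character(did)]] <-
    list(subs = parent$subs, og = parent$og, node = node, epoch = epoch)
  env$ogSuffix[parent$og] <- env$ogSuffix[parent$og] + 1L
  daughter <- parent
  daughter$suffix <- env$ogSuffix[parent$og]
  daughter$path <- paste(parent$path, sprintf("D%d", did), sep = "|")
  daughter$subs <- parent$subs + extraDiv
  daughter$role <- "daughter"
  daughter$birthNode <- node
  daughter$epoch <- epoch
  tandem <- stats::runif(1) < cfg$tandemFraction
  daughter$orderPos <- if (tandem)
    parent$orderPos + stats::runif(1, 0.01, 0.4)
  else stats::runif(1, 0.5, cfg$nGenes + 0.5)
  if (parent$role == "single") {
    parent$role <- "parent"
    parent$epoch <- epoch
    copies[[ci]] <- parent
  }
  env$events[[length(env$events) + 1L]] <-
    list(node = node, class = "duplication", size = mapLength(parent$map),
         og = parent$og, dup_id = did, tandem = tandem)
  copies[[length(copies) + 1L]] <- daughter
  copies
}

.evolveEdge <- function(env, copies, t, node, isRefTerminal) {
  cfg <- env$cfg
  # duplications (first, so daughters see the branch's later events)
  nc <- length(copies)
  for (ci in seq_len(nc)) {
    ndup <- stats::rpois(1, cfg$dupRate * t)
    for (k in seq_len(ndup))
      copies <- .applyDuplication(env, copies, ci, node,
                                  epoch = NA_character_,
                                  extraDiv = cfg$daughterExtraDivergence)
  }
  if (isRefTerminal && !is.null(cfg$forcedDuplications)) {
    for (fd in cfg$forcedDuplications) {
      if (!identical(fd$epoch, "recent")) next
      eligible <- which(vapply(copies, function(cp)
        cp$role == "single", logical(1)))
      for (k in seq_len(fd$count)) {
        if (!length(eligible)) break
        pick <- eligible[1 + (k - 1L) %% length(eligible)]
        copies <- .applyDuplication(env, copies, pick, node, "recent",
                                    fd$extraDivergence)
      }
    }
  }
  for (ci in seq_along(copies)) {
    cp <- copies[[ci]]
    # substitutions
    load <- cfg$subRate * t *
      (if (cfg$subNoise) stats::rgamma(1, 40, 40) else 1)
    cp$subs <- cp$subs + load
    # indels
    nind <- stats::rpois(1, cfg$indelRate * t)
    for (k in seq_len(nind)) {
      size <- .runifInt(cfg$indelSizeRange[1], cfg$indelSizeRange[2])
      pos <- .drawMatchedPos(cp$map)
      if (stats::runif(1) < 0.5) {
        cp$map <- mapInsertion(cp$map, pos, size)
        env$events[[length(env$events) + 1L]] <-
          list(node = node, class = "insertion", size = size, og = cp$og)
      } else {
        mb <- .mapMatchedBases(cp$map)
        size <- min(size, max(1L, floor(mb$total / 3)))  # keep the copy alive
        del <- tryCatch(mapDeletion(cp$map, pos, size), error = function(e) NULL)
        if (!is.null(del)) {
          cp$map <- del
          env$events[[length(env$events) + 1L]] <-
            list(node = node, class = "deletion", size = size, og = cp$og)
        }
      }
    }
    # inversion
    if (stats::runif(1) < 1 - exp(-cfg$inversionRate * t)) {
      cp$strand <- if (cp$strand == "+") "-" else "+"
      env$events[[length(env$events) + 1L]] <-
        list(node = node, class = "inversion", size = mapLength(cp$map),
             og = cp$og)
    }
    copies[[ci]] <- cp
  }
  # losses: only copies that are currently the sole copy of their gene
  ogCount <- table(vapply(copies, `[[`, numeric(1), "og"))
  drop <- logical(length(copies))
  for (ci in seq_along(copies)) {
    cp <- copies[[ci]]
    if (ogCount[[as.character(cp$og)]] > 1L) next
    if (stats::runif(1) < 1 - exp(-cfg$lossRate * t)) {
      drop[ci] <- TRUE
      env$losses[[length(env$losses) + 1L]] <-
        list(node = node, og = cp$og, path = cp$path)
    }
  }
  copies[!drop]
}

#' Simulate a synthetic clade with ground truth
#'
#' Evolves `nGenes` ancestral genes along the guide tree at the
#' coordinate/event level (see [simCladeConfig()]) and emits everything
#' the pipeline consumes -- per-species GFF3-ready annotations, PSL
#' alignments of every species against the reference and between species
#' adjacent in display order, the orthogroup table over annotated genes,
#' and a mutation-event table -- together with the full ground truth
#' (orthology, duplication epochs, parent/daughter roles, losses,
#' annotation gaps). Deterministic for a fixed seed.
#'
#' @param config a [simCladeConfig()] list.
#' @return a [SyntheticClade-class].
#' @export
simulateClade <- function(config = simCladeConfig()) {
  cfg <- config
  set.seed(cfg$seed)
  st <- readSpeciesTree(cfg$tree)
  phy <- guideTree(st)
  ntip <- length(phy$tip.label)
  rootNode <- ntip + 1L
  children <- split(phy$edge[, 2], phy$edge[, 1])
  edgeLen <- stats::setNames(phy$edge.length, phy$edge[, 2])
  refTip <- which(phy$tip.label == cfg$reference)
  refPath <- .nodePath(phy, refTip)   # nodes from root to reference leaf

  env <- new.env()
  env$cfg <- cfg
  env$dupCounter <- 0L
  env$dupRegistry <- list()
  env$ogSuffix <- rep(1L, cfg$nGenes)
  env$events <- list()
  env$losses <- list()
  env$leaves <- list()

  # ancestral gene geometry
  rootGenes <- vector("list", cfg$nGenes)
  for (i in seq_len(cfg$nGenes)) {
    ne <- .runifInt(cfg$exonCountRange[1], cfg$exonCountRange[2])
    exLen <- .runifInt(cfg$exonSizeRange[1], cfg$exonSizeRange[2], ne)
    inLen <- if (ne > 1L)
      .runifInt(cfg$intronSizeRange[1], cfg$intronSizeRange[2], ne - 1L)
    else integer(0)
    pos <- 0L; ex <- matrix(0L, ne, 2)
    for (j in seq_len(ne)) {
      ex[j, ] <- c(pos, pos + exLen[j])
      pos <- pos + exLen[j] + if (j < ne) inLen[j] else 0L
    }
    rootGenes[[i]] <- list(len = pos, exons = ex)
  }

  copies <- lapply(seq_len(cfg$nGenes), function(i)
    .newCopy(i, 1L, rootGenes[[i]]$len))

  # forced ancient duplications predate every split
  if (!is.null(cfg$forcedDuplications)) {
    for (fd in cfg$forcedDuplications) {
      if (!identical(fd$epoch, "ancient")) next
      eligible <- which(vapply(copies, function(cp)
        cp$role == "single", logical(1)))
      for (k in seq_len(fd$count)) {
        if (!length(eligible)) break
        pick <- eligible[1 + (k - 1L) %% length(eligible)]
        copies <- .applyDuplication(env, copies, pick, rootNode, "ancient",
                                    fd$extraDivergence)
        eligible <- setdiff(eligible, pick)
      }
    }
  }

  descend <- function(copies, node) {
    for (cp in seq_along(copies))
      copies[[cp]]$snapshots[[as.character(node)]] <-
        list(path = copies[[cp]]$path, subs = copies[[cp]]$subs)
    if (node <= ntip) {
      env$leaves[[phy$tip.label[node]]] <- copies
      return(invisible(NULL))
    }
    for (child in children[[as.character(node)]]) {
      evolved <- .evolveEdge(env, copies, edgeLen[[as.character(child)]],
                             child,
                             isRefTerminal = (child == refTip))
      descend(evolved, child)
    }
  }
  descend(copies, rootNode)

  .assembleClade(env, st, phy, rootGenes, refPath)
}

# nodes on the path root -> tip (inclusive)
.nodePath <- function(phy, tip) {
  ntip <- length(phy$tip.label)
  parent <- stats::setNames(phy$edge[, 1], phy$edge[, 2])
  path <- tip
  while (!is.na(parent[as.character(path[1])]))
    path <- c(parent[[as.character(path[1])]], path)
  path
}
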