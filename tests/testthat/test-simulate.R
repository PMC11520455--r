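test_that("simulation is deterministic for a fixed seed", {
  cfg <- simCladeConfig(seed = 99, nGenes = 8)
  a <- simulateClade(cfg)
  b <- simulateClade(cfg)
  expect_identical(cladeTruth(a), cladeTruth(b))
  expect_identical(writePsl(cladeRefPsl(a)[[2]]),
                   writePsl(cladeRefPsl(b)[[2]]))
  expect_identical(writeGff3(cladeAnnotations(a)[[1]]),
                   writeGff3(cladeAnnotations(b)[[1]]))
  c2 <- simulateClade(simCladeConfig(seed = 100, nGenes = 8))
  expect_false(identical(cladeTruth(a), cladeTruth(c2)))
})

test_that("null evolution produces identical single-copy species", {
  cl <- nullClade()
  tr <- cladeTruth(cl)
  expect_true(all(tr$status == "annotated"))
  expect_true(all(tr$role == "single"))
  ord <- displayOrder(cladeTree(cl))
  # every gene yields exactly one full-length alignment per species
  for (sp in setdiff(ord, cladeReference(cl))) {
    psl <- cladeRefPsl(cl)[[sp]]
    expect_length(psl, 12)
    df <- pslRecords(psl)
    expect_true(all(df$misMatches == 0))
    glen <- tr$end[tr$species == sp] - tr$start[tr$species == sp] + 1L
    expect_setequal(df$tEnd - df$tStart, glen)
  }
})

test_that("duplication truth records parent, daughter and placement", {
  cl <- simulateClade(simCladeConfig(
    seed = 5, nGenes = 6, dupRate = 0, lossRate = 0,
    annotationGapProb = 0, tandemFraction = 1,
    forcedDuplications = list(list(epoch = "recent", count = 1,
                                   extraDivergence = 0.1))))
  tr <- cladeTruth(cl)
  ref <- cladeReference(cl)
  rt <- tr[tr$species == ref, ]
  expect_equal(sum(rt$role == "parent"), 1)
  expect_equal(sum(rt$role == "daughter"), 1)
  par <- rt[rt$role == "parent", ]; dau <- rt[rt$role == "daughter", ]
  expect_equal(par$orthogroup, dau$orthogroup)
  expect_equal(dau$epoch, "recent")
  # tandem daughter is adjacent to its parent on the chromosome
  ord <- rt[order(rt$start), ]
  expect_equal(abs(which(ord$gene_id == par$gene_id) -
                     which(ord$gene_id == dau$gene_id)), 1)
  # non-reference species keep a single copy
  other <- tr[tr$species != ref, ]
  expect_true(all(table(other$species, other$orthogroup) == 1))
  # the reference gene sees a secondary (paralogous) alignment in the
  # orthogroup table truth: both copies align to the same orthologs
  expect_equal(sum(orthogroupTable(cladeOrthogroups(cl))$orthogroup ==
                     par$orthogroup), 6)
})

test_that("losses remove genes from annotation, orthogroups and truth", {
  cl <- simulateClade(simCladeConfig(seed = 17, nGenes = 10, dupRate = 0,
                                     lossRate = 0.08,
                                     annotationGapProb = 0))
  tr <- cladeTruth(cl)
  losses <- tr[tr$status == "lost", ]
  expect_gt(nrow(losses), 0)
  for (i in seq_len(nrow(losses))) {
    sp <- losses$species[i]; og <- losses$orthogroup[i]
    ann <- cladeAnnotations(cl)[[sp]]
    present <- tr$gene_id[tr$species == sp & tr$orthogroup == og &
                            tr$status == "annotated"]
    expect_length(present, 0)
    tb <- orthogroupTable(cladeOrthogroups(cl))
    expect_equal(nrow(tb[tb$orthogroup == og & tb$species == sp, ]), 0)
  }
})

test_that("unannotated genes keep alignments but leave the GFF3", {
  cl <- goldenClade()
  tr <- cladeTruth(cl)
  gaps <- tr[tr$status == "unannotated", ]
  expect_gt(nrow(gaps), 0)
  for (i in seq_len(nrow(gaps))) {
    sp <- gaps$species[i]
    ann <- cladeAnnotations(cl)[[sp]]
    expect_false(gaps$gene_id[i] %in% annotatedGenes(ann)$gene_id)
    # alignment over the gene's true location still exists
    bl <- pslBlocks(cladeRefPsl(cl)[[sp]])
    hit <- bl$t_start <= gaps$end[i] & bl$t_end >= gaps$start[i]
    expect_true(any(hit))
  }
})

test_that("emitted alignments are self-consistent PSL", {
  cl <- goldenClade()
  for (sp in names(cladeRefPsl(cl))) {
    psl <- cladeRefPsl(cl)[[sp]]
    expect_true(isTRUE(methods::validObject(psl, test = TRUE)))
    df <- pslRecords(psl)
    expect_true(all(df$qEnd <= df$qSize))
    expect_true(all(df$tEnd <= df$tSize))
    expect_true(all(vapply(df$blockSizes, sum, numeric(1)) ==
                      df$matches + df$misMatches))
  }
})

test_that("written clades read back equivalently", {
  cl <- simulateClade(simCladeConfig(seed = 23, nGenes = 6))
  dir <- file.path(tempdir(), "clade23")
  writeClade(cl, dir)
  back <- readClade(dir)
  expect_identical(back$reference, cladeReference(cl))
  expect_identical(displayOrder(back$tree), displayOrder(cladeTree(cl)))
  for (sp in names(cladeRefPsl(cl)))
    expect_equal(pslRecords(back$refPsl[[sp]]),
                 pslRecords(cladeRefPsl(cl)[[sp]]))
  sortTab <- function(tb) {
    tb <- tb[order(tb$orthogroup, tb$species, tb$gene_id), ]
    rownames(tb) <- NULL
    tb
  }
  expect_equal(sortTab(orthogroupTable(back$orthogroups)),
               sortTab(orthogroupTable(cladeOrthogroups(cl))))
  for (sp in names(cladeAnnotations(cl)))
    expect_equal(
      IRanges::ranges(annotatedGenes(back$annotations[[sp]])),
      IRanges::ranges(annotatedGenes(cladeAnnotations(cl)[[sp]])))
})
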