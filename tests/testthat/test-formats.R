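test_that("PSL parsing decomposes fields and blocks correctly", {
  expect_length(readPsl(character(0)), 0)

  line <- paste(75, 5, 0, 0, 0, 0, 1, 30, "+", "chrQ", 500, 10, 90,
                "chrT", 600, 100, 210, 2, "50,30,", "10,60,", "100,180,",
                sep = "\t")
  psl <- readPsl(line)
  expect_length(psl, 1)
  df <- pslRecords(psl)
  expect_identical(df$blockSizes[[1]], c(50L, 30L))
  expect_identical(sum(df$blockSizes[[1]]), 80L)
  expect_identical(df$tStarts[[1]], c(100L, 180L))
  bl <- pslBlocks(psl)
  expect_equal(bl$t_start, c(101L, 181L))
  expect_equal(bl$q_start, c(11L, 61L))
})

test_that("PSL violations raise format errors naming the line", {
  ok <- mkPslLine(100, 200)
  bad_fields <- paste(strsplit(ok, "\t")[[1]][1:20], collapse = "\t")
  expect_error(readPsl(bad_fields), "line 1.*21 fields")

  three_sizes <- sub("100,\t0,\t100,", "50,25,25,\t0,\t100,",
                     mkPslLine(100, 200))
  expect_error(readPsl(c(ok, three_sizes)), "line 2.*blockCount")

  bad_span <- mkPslLine(200, 100)
  expect_error(readPsl(bad_span), "line 1")

  translated <- sub("\t\\+\t", "\t+-\t", mkPslLine(100, 200))
  expect_error(readPsl(translated), "strand")

  nonint <- sub("^\\d+", "abc", mkPslLine(100, 200))
  expect_error(readPsl(nonint), "non-integer")
})

test_that("PSL header blocks are tolerated and round-trips are lossless", {
  lines <- c(mkPslLine(100, 200), mkPslLine(300, 450, strand = "-"),
             mkPslLine(500, 520, misMatches = 3L))
  psl <- readPsl(lines)
  expect_identical(writePsl(psl), lines)                   # byte identity
  expect_equal(pslRecords(readPsl(writePsl(psl))), pslRecords(psl))

  withHeader <- writePsl(psl, header = TRUE)
  expect_identical(pslRecords(readPsl(withHeader)), pslRecords(psl))
  expect_length(writePsl(readPsl(character(0))), 0)
})

test_that("negative-strand queries expose forward intervals and transpose", {
  # forward query span [40, 60) on a 100 bp query, reverse orientation
  line <- mkPslLine(10, 30, qSize = 100L, qStart = 40L, strand = "-")
  psl <- readPsl(line)
  bl <- pslBlocks(psl)
  expect_equal(c(bl$q_start, bl$q_end), c(41L, 60L))
  tp <- transposePsl(psl)
  expect_identical(pslRecords(transposePsl(tp)), pslRecords(psl))
  btl <- pslBlocks(tp)
  expect_equal(c(btl$q_start, btl$q_end), c(bl$t_start, bl$t_end))
  expect_equal(c(btl$t_start, btl$t_end), c(bl$q_start, bl$q_end))
})

test_that("GFF3 models parse with the documented coordinate convention", {
  gff <- c("##gff-version 3",
           "##sequence-region chr1 1 5000",
           "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
           "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=g1.t1;Parent=g1",
           "chr1\tsrc\texon\t101\t140\t.\t+\t.\tParent=g1.t1",
           "chr1\tsrc\texon\t161\t200\t.\t+\t.\tParent=g1.t1")
  f <- tempfile(fileext = ".gff3")
  writeLines(gff, f)
  ann <- readGeneAnnotation(f, "sp")
  g <- annotatedGenes(ann)
  expect_equal(GenomicRanges::start(g), 101)
  expect_equal(GenomicRanges::end(g), 200)
  expect_equal(IRanges::width(g), 100)
  # intron = gene span minus exons (independent set-subtraction oracle)
  introns <- intronRanges(ann, "g1")
  oracle <- GenomicRanges::setdiff(
    GenomicRanges::granges(g),
    GenomicRanges::reduce(GenomicRanges::granges(
      geneFeatures(ann, "g1", "exon"))),
    ignore.strand = TRUE)
  expect_equal(IRanges::ranges(introns), IRanges::ranges(oracle))
  expect_equal(GenomicRanges::start(introns), 141)
  expect_equal(GenomicRanges::end(introns), 160)
})

test_that("GFF3 orphans warn and skip; empty annotation is legal", {
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
           "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=ghost")
  f <- tempfile(fileext = ".gff3")
  writeLines(gff, f)
  expect_warning(ann <- readGeneAnnotation(f, "sp"), "unresolved Parent")
  expect_length(geneFeatures(ann), 0)

  f2 <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", f2)
  expect_length(readGeneAnnotation(f2, "sp"), 0)
})

test_that("GFF3 written by the package round-trips byte-for-byte", {
  ann <- cladeAnnotations(nullClade())[[2]]
  f1 <- tempfile(fileext = ".gff3")
  writeGff3(ann, f1)
  ann2 <- readGeneAnnotation(f1, annotationSpecies(ann))
  f2 <- tempfile(fileext = ".gff3")
  writeGff3(ann2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(IRanges::ranges(annotatedGenes(ann2)),
               IRanges::ranges(annotatedGenes(ann)))
  expect_setequal(annotatedGenes(ann2)$gene_id,
                  annotatedGenes(ann)$gene_id)
})

test_that("orthogroup tables parse, reject duplicates, round-trip", {
  txt <- c("Orthogroup\tA\tB",
           "OG1\tgeneA1\tgeneB1,geneB2",
           "OG2\tgeneA2\t")
  og <- readOrthogroups(txt)
  expect_equal(length(og), 2)
  expect_equal(sort(orthogroupMembers(og, "OG1")),
               c("geneA1", "geneB1", "geneB2"))
  expect_equal(orthogroupOf(og, "geneB2"), "OG1")
  expect_identical(writeOrthogroups(og), txt[c(1, 2, 3)])

  dup <- c("Orthogroup\tA\tB", "OG1\tgeneA1\tgeneB1",
           "OG2\tgeneA1\tgeneB2")
  expect_error(readOrthogroups(dup), "more than one orthogroup")
})

test_that("species tree display order follows the written leaf order", {
  st <- readSpeciesTree("((A,B),(C,D));")
  expect_identical(displayOrder(st), c("A", "B", "C", "D"))
  st2 <- readSpeciesTree("(((S1:1,S2:1):1,(S3:1,S4:1):1):1,S5:3);")
  expect_identical(displayOrder(st2), c("S1", "S2", "S3", "S4", "S5"))
  # every cherry ends up adjacent on the tracks
  phy <- guideTree(st2)
  ord <- displayOrder(st2)
  for (tip in seq_along(phy$tip.label)) {
    sibs <- phy$edge[phy$edge[, 1] == phy$edge[phy$edge[, 2] == tip, 1], 2]
    if (all(sibs <= length(phy$tip.label))) {    # a cherry
      idx <- match(phy$tip.label[sibs], ord)
      expect_equal(abs(diff(idx)), 1)
    }
  }
  expect_error(readSpeciesTree("((A,B,;"), "newick")
})

test_that("parameter validation enforces the documented ranges", {
  expect_equal(paramSet()$gapValue, 200)
  expect_equal(paramSet()$filteringPct, 16)
  expect_error(paramSet(gapValue = -1), "gapValue")
  expect_error(paramSet(filteringPct = 101), "filteringPct")
})
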