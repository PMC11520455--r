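test_that("depth counts alignment blocks per base, paralogs included", {
  sl <- c(chr = 200L)
  empty <- depthProfile(list(), sl)
  expect_equal(depthTotal(empty), 0)

  one <- depthProfile(
    list(S2 = readPsl(mkPslLine(500, 510, qName = "chr", qStart = 10L,
                                qSize = 200L))), sl)
  v <- as.integer(depthCoverage(one)$chr)
  expect_equal(v[11:20], rep(1L, 10))
  expect_equal(sum(v), 10)

  # two species covering [1,100], one with an extra paralogous block
  # over [1,50]: depth 3 then 2 (brute-force per-base expectation)
  psl <- list(
    S2 = readPsl(mkPslLine(0, 100, qName = "chr", qStart = 0L, qSize = 200L)),
    S3 = readPsl(c(
      mkPslLine(300, 400, qName = "chr", qStart = 0L, qSize = 200L),
      mkPslLine(600, 650, qName = "chr", qStart = 0L, qSize = 200L))))
  prof <- depthProfile(psl, sl)
  v <- as.integer(depthCoverage(prof)$chr)
  expect_equal(v[1:50], rep(3L, 50))
  expect_equal(v[51:100], rep(2L, 50))
  expect_equal(v[101:200], rep(0L, 100))

  bad <- list(S2 = readPsl(mkPslLine(0, 100, qName = "chr", qStart = 150L,
                                     qSize = 400L)))
  expect_error(depthProfile(bad, sl), "outside declared length")
})

test_that("depth conservation holds exactly on the golden clade", {
  cl <- goldenClade()
  refAnn <- cladeAnnotations(cl)[[cladeReference(cl)]]
  prof <- depthProfile(cladeRefPsl(cl),
                       GenomeInfoDb::seqlengths(annotatedGenes(refAnn)))
  blockSum <- sum(vapply(cladeRefPsl(cl),
                         function(p) sum(pslBlocks(p)$size), numeric(1)))
  expect_identical(depthTotal(prof), blockSum)
})

test_that("window means tile the genome and average partial windows", {
  sl <- c(chr = 50000L)
  psl <- list(S2 = readPsl(mkPslLine(0, 10000, qName = "chr", qStart = 0L,
                                     qSize = 50000L, tSize = 100000L)))
  prof <- depthProfile(psl, sl)
  wm <- windowMeans(prof, 20000)
  expect_equal(nrow(wm), 3)
  expect_equal(wm$width, c(20000L, 20000L, 10000L))
  expect_equal(wm$window_start, c(0L, 20000L, 40000L))
  # depth 1 on the first half of window 1, 0 on the second: mean 0.5
  expect_equal(wm$mean_depth, c(0.5, 0, 0))

  # constant depth gives constant window means
  cl <- nullClade()
  refAnn <- cladeAnnotations(cl)[[cladeReference(cl)]]
  prof0 <- depthProfile(cladeRefPsl(cl),
                        GenomeInfoDb::seqlengths(annotatedGenes(refAnn)))
  wm0 <- windowMeans(prof0, 1e9)   # one window spanning everything
  expect_equal(nrow(wm0), 1)
  expect_equal(wm0$mean_depth, depthTotal(prof0) / sum(prof0@seqlengths))
})

test_that("feature classes follow the exon > UTR > intron precedence", {
  # one gene [101,600]: exons [101,250]+[401,600], intron between;
  # UTRs at the exonic ends, CDS in the middle
  genes <- GenomicRanges::GRanges("chr", IRanges::IRanges(101, 600),
                                  strand = "+", gene_id = "g1")
  feats <- GenomicRanges::GRanges(
    "chr",
    IRanges::IRanges(c(101, 401, 101, 151, 401, 551),
                     c(250, 600, 150, 250, 550, 600)),
    strand = "+", gene_id = "g1",
    type = c("exon", "exon", "five_prime_UTR", "CDS", "CDS",
             "three_prime_UTR"))
  ann <- GeneAnnotation("sp", genes, feats, seqlengths = c(chr = 1000L))
  psl <- list(S2 = readPsl(mkPslLine(0, 1000, qName = "chr", qStart = 0L,
                                     qSize = 1000L, tSize = 2000L)))
  prof <- depthProfile(psl, c(chr = 1000L))
  fcd <- featureClassDepth(prof, ann)
  expect_setequal(unique(fcd$class),
                  c("exon", "five_prime_UTR", "three_prime_UTR", "intron",
                    "intergenic"))
  # uniform depth 1: every class mean is 1
  expect_true(all(fcd$mean_depth == 1))
  # base counts match the hand-decomposed classes
  expect_equal(fcd$n_bases[fcd$class == "exon"], 250L)            # CDS bases
  expect_equal(fcd$n_bases[fcd$class == "five_prime_UTR"], 50L)
  expect_equal(fcd$n_bases[fcd$class == "three_prime_UTR"], 50L)
  expect_equal(fcd$n_bases[fcd$class == "intron"], 150L)
  expect_equal(sum(fcd$n_bases[fcd$class == "intergenic"]), 500L)
})

test_that("overlapping genes resolve classes per base by precedence", {
  # gene A's exon sits inside gene B's intron: those bases class as exon
  genes <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(c(301, 101), c(400, 700)), strand = "+",
    gene_id = c("gA", "gB"))
  feats <- GenomicRanges::GRanges(
    "chr",
    IRanges::IRanges(c(301, 301, 101, 101, 601, 601),
                     c(400, 400, 200, 200, 700, 700)),
    strand = "+", gene_id = c("gA", "gA", "gB", "gB", "gB", "gB"),
    type = c("exon", "CDS", "exon", "CDS", "exon", "CDS"))
  ann <- GeneAnnotation("sp", genes, feats, seqlengths = c(chr = 1000L))
  prof <- depthProfile(list(), c(chr = 1000L))
  fcd <- featureClassDepth(prof, ann)
  # per-base classification oracle: bases get one class globally by
  # precedence, then each gene sums the classified bases inside its span
  # (bases under two genes contribute to both genes' summaries)
  oracle <- rep("intergenic", 1000)
  oracle[101:700] <- "intron"
  oracle[c(101:200, 601:700)] <- "exon"
  oracle[301:400] <- "exon"
  spans <- list(gA = 301:400, gB = 101:700)
  for (cn in c("exon", "intron")) {
    perGene <- sum(vapply(spans, function(s) sum(oracle[s] == cn),
                          numeric(1)))
    expect_equal(sum(fcd$n_bases[fcd$class == cn]), perGene, info = cn)
  }
  expect_equal(sum(fcd$n_bases[fcd$class == "intergenic"]),
               sum(oracle == "intergenic"))
  # the precedence assertion proper: gene A's exon bases, though inside
  # gene B's intron, are classed exon for both genes
  expect_equal(sum(fcd$n_bases[fcd$unit_id == "gB" & fcd$class == "exon"]),
               300)
  expect_equal(sum(fcd$n_bases[fcd$unit_id == "gB" & fcd$class == "intron"]),
               300)
})

test_that("gene class depth summarises spans and flags unknown genes", {
  cl <- nullClade()
  refAnn <- cladeAnnotations(cl)[[cladeReference(cl)]]
  prof <- depthProfile(cladeRefPsl(cl),
                       GenomeInfoDb::seqlengths(annotatedGenes(refAnn)))
  ids <- annotatedGenes(refAnn)$gene_id
  gcd <- geneClassDepth(prof, list(all = ids), refAnn)
  # no duplications, no losses: every gene at depth n_species - 1
  expect_true(all(gcd$mean_depth == 4))
  expect_warning(
    gcd2 <- geneClassDepth(prof, list(all = c(ids[1], "ghost")), refAnn),
    "unknown gene")
  expect_equal(nrow(gcd2), 1)
})

test_that("bedgraph output reproduces the coverage runs", {
  sl <- c(chr = 100L)
  psl <- list(S2 = readPsl(mkPslLine(0, 40, qName = "chr", qStart = 10L,
                                     qSize = 100L)))
  prof <- depthProfile(psl, sl)
  f <- tempfile(fileext = ".bedgraph")
  writeBedGraph(prof, f)
  lines <- readLines(f)
  expect_match(lines[1], "bedGraph")
  df <- read.table(text = lines[-1], sep = "\t")
  expect_equal(df$V2, c(0L, 10L, 50L))      # 0-based starts
  expect_equal(df$V3, c(10L, 50L, 100L))
  expect_equal(df$V4, c(0L, 1L, 0L))
})
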