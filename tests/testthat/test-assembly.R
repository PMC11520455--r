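test_that("gap-value chaining merges fragments exactly at the threshold", {
  psl <- readPsl(c(mkPslLine(100, 200), mkPslLine(210, 300)))
  one <- assembleFragments(psl, gapValue = 10)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$t_start, one$t_end), c(101L, 300L))
  expect_equal(one$length, 200L)
  expect_equal(one$n_members, 2L)

  two <- assembleFragments(psl, gapValue = 9)
  expect_equal(nrow(two), 2)

  abut <- readPsl(c(mkPslLine(100, 200), mkPslLine(200, 300)))
  expect_equal(nrow(assembleFragments(abut, gapValue = 0)), 1)

  other <- readPsl(c(mkPslLine(100, 200),
                     mkPslLine(210, 300, tName = "t2")))
  expect_equal(nrow(assembleFragments(other, gapValue = 1e6)), 2)

  strands <- readPsl(c(mkPslLine(100, 200),
                       mkPslLine(210, 300, strand = "-")))
  expect_equal(nrow(assembleFragments(strands, gapValue = 1e6)), 2)

  mixed <- readPsl(c(mkPslLine(100, 200),
                     mkPslLine(210, 300, qName = "q2")))
  expect_error(assembleFragments(mixed, 10), "multiple query")
})

test_that("chain assembly equals the brute-force merge closure", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(1:8, 1)
    lines <- vapply(seq_len(n), function(i) {
      s <- sample(0:2000, 1)
      mkPslLine(s, s + sample(10:400, 1),
                tName = sample(c("t1", "t2"), 1),
                strand = sample(c("+", "-"), 1),
                qStart = sample(0:500, 1))
    }, character(1))
    psl <- readPsl(lines)
    gap <- sample(0:300, 1)
    got <- assembleFragments(psl, gap)
    got <- got[order(got$t_seq, got$strand, got$t_start), , drop = FALSE]
    oracle <- mergeClosureOracle(pslRecords(psl), gap)
    expect_equal(got$t_start, oracle$t_start)
    expect_equal(got$t_end, oracle$t_end)
    expect_equal(got$matches, oracle$matches)
    # conservation of aggregates
    expect_equal(sum(got$matches), sum(pslRecords(psl)$matches))
  }
})

test_that("length filtering uses an inclusive threshold on query percent", {
  psl <- readPsl(c(mkPslLine(0, 160), mkPslLine(1000, 1500),
                   mkPslLine(3000, 3100)))
  fr <- assembleFragments(psl, gapValue = 0)
  fl <- filterFragments(fr, queryLen = 1000, filteringPct = 16)
  expect_true(160 %in% fl$retained$length)      # boundary inclusive
  expect_setequal(fl$retained$length, c(500, 160))
  expect_setequal(fl$discarded$length, 100)

  all16 <- filterFragments(fr, 1000, 0)
  expect_equal(nrow(all16$retained), 3)
  expect_equal(nrow(all16$discarded), 0)
  expect_error(filterFragments(fr, 0, 16), "queryLen")
})

test_that("classification separates primary, co-gene and secondary", {
  ann <- toyAnnotation()
  one <- assembleFragments(readPsl(mkPslLine(150, 400)), 0, species = "sp")
  cl <- classifyFragments(one, ann)
  expect_equal(cl$class, "primary")

  # both fragments overlap gene gA ([100,500]): co-gene
  both <- assembleFragments(
    readPsl(c(mkPslLine(120, 420), mkPslLine(450, 490))), 0)
  cl2 <- classifyFragments(both, ann)
  expect_setequal(cl2$class, c("primary", "co_gene"))
  expect_equal(cl2$class[which.max(cl2$length)], "primary")

  # second fragment overlaps a different gene gB: secondary "(filtered)"
  sec <- assembleFragments(
    readPsl(c(mkPslLine(120, 420), mkPslLine(650, 800))), 0)
  cl3 <- classifyFragments(sec, ann)
  expect_equal(cl3$class[cl3$t_start == 651], "secondary")
  expect_equal(cl3$label[cl3$class == "secondary"], "(filtered)")

  empty <- classifyFragments(both[0, ], ann)
  expect_equal(nrow(empty), 0)
})

test_that("primary ties break by matches then target start", {
  lines <- c(mkPslLine(100, 300, misMatches = 50L), mkPslLine(600, 800))
  fr <- assembleFragments(readPsl(lines), 0)
  cl <- classifyFragments(fr, toyAnnotation())
  expect_equal(cl$t_start[cl$class == "primary"], 601)   # more matches
})

test_that("full gene extension reaches gene ends and is idempotent", {
  ann <- toyAnnotation()
  fr <- assembleFragments(readPsl(mkPslLine(150, 400)), 0)
  ext <- fullGeneExtension(fr, ann)
  expect_equal(c(ext$t_start, ext$t_end), c(100L, 500L))
  expect_equal(fullGeneExtension(ext, ann), ext)
  expect_equal(ext$matches, fr$matches)          # aggregates untouched

  # intergenic fragment unchanged
  ig <- assembleFragments(readPsl(mkPslLine(520, 580)), 0)
  expect_equal(fullGeneExtension(ig, ann)[, c("t_start", "t_end")],
               ig[, c("t_start", "t_end")])

  # fragment spanning two genes extends to the union span
  span2 <- assembleFragments(readPsl(mkPslLine(450, 650)), 0)
  e2 <- fullGeneExtension(span2, ann)
  expect_equal(c(e2$t_start, e2$t_end), c(100L, 900L))
})

test_that("queries resolve from gene names and coordinates with checks", {
  ann <- toyAnnotation()
  q <- resolveQuery("gA", ann)
  expect_equal(c(GenomicRanges::start(q), GenomicRanges::end(q)),
               c(100, 500))
  q2 <- resolveQuery("t:150-250", ann)
  expect_equal(IRanges::width(q2), 101)
  expect_equal(IRanges::width(resolveQuery("t:150..250", ann)), 101)
  expect_error(resolveQuery("t:100..50", ann), "start")
  expect_error(resolveQuery("nope", ann), "unknown gene")
  expect_error(resolveQuery("chrX:1-10", ann), "unknown sequence")
  expect_error(resolveQuery("t:1-99999999", ann), "beyond")
})
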