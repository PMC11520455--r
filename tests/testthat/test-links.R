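mkFrag <- function(species, t_seq, t_start, t_end) {
  data.frame(species = species, t_seq = t_seq, t_start = t_start,
             t_end = t_end, stringsAsFactors = FALSE)
}

test_that("links span identical fragments and respect clipping", {
  frags <- rbind(mkFrag("A", "chrA", 101, 400), mkFrag("B", "chrB", 201, 500))
  full <- readPsl(mkPslLine(200, 500, qName = "chrA", qStart = 100L,
                            tName = "chrB"))
  links <- buildLinks(frags, c("A", "B"), list(`A|B` = full), gapValue = 200)
  expect_equal(nrow(links), 1)
  expect_equal(c(links$start_a, links$end_a), c(101L, 400L))
  expect_equal(c(links$start_b, links$end_b), c(201L, 500L))
  expect_equal(links$orientation, "same")
  expect_gt(links$support, 0)

  # alignment wholly outside the displayed fragments: no link
  outside <- readPsl(mkPslLine(5000, 5300, qName = "chrA", qStart = 4000L,
                               tName = "chrB"))
  expect_equal(nrow(buildLinks(frags, c("A", "B"), list(`A|B` = outside),
                               200)), 0)

  # missing pairwise file warns and yields no links
  expect_warning(
    none <- buildLinks(frags, c("A", "B"), list(), 200),
    "no pairwise alignment")
  expect_equal(nrow(none), 0)
})

test_that("blocks further apart than the gap value give separate links", {
  frags <- rbind(mkFrag("A", "chrA", 1, 5000), mkFrag("B", "chrB", 1, 5000))
  psl <- readPsl(c(
    mkPslLine(100, 200, qName = "chrA", qStart = 100L, tName = "chrB"),
    mkPslLine(900, 1000, qName = "chrA", qStart = 900L, tName = "chrB")))
  near <- buildLinks(frags, c("A", "B"), list(`A|B` = psl), gapValue = 700)
  expect_equal(nrow(near), 1)
  far <- buildLinks(frags, c("A", "B"), list(`A|B` = psl), gapValue = 600)
  expect_equal(nrow(far), 2)
})

test_that("link sets are symmetric in the pair's query/target roles", {
  frags <- rbind(mkFrag("A", "chrA", 1, 5000), mkFrag("B", "chrB", 1, 5000))
  set.seed(5)
  lines <- vapply(1:6, function(i) {
    s <- sample(0:4000, 1)
    mkPslLine(s, s + sample(50:300, 1), qName = "chrA",
              qStart = sample(0:4000, 1), tName = "chrB",
              strand = sample(c("+", "-"), 1), qSize = 5000L,
              tSize = 5000L)
  }, character(1))
  psl <- readPsl(lines)
  fwd <- buildLinks(frags, c("A", "B"), list(`A|B` = psl), 150)
  rev <- buildLinks(rbind(frags[2, ], frags[1, ]), c("B", "A"),
                    list(`B|A` = transposePsl(psl)), 150)
  key <- function(df, a, b)
    sort(sprintf("%d-%d/%d-%d:%s", df[[paste0("start_", a)]],
                 df[[paste0("end_", a)]], df[[paste0("start_", b)]],
                 df[[paste0("end_", b)]], df$orientation))
  expect_identical(key(fwd, "a", "b"), key(rev, "b", "a"))

  # the same holds when the reverse file must be transposed on the fly
  rev2 <- buildLinks(frags, c("A", "B"),
                     list(`B|A` = transposePsl(psl)), 150)
  expect_identical(key(fwd, "a", "b"), key(rev2, "a", "b"))
})

test_that("total link support is bounded by the aligned bases", {
  cl <- goldenClade()
  g <- geneClasses(cl)$single_copy[1]
  res <- runSyntenyQuery(g, cladeReference(cl), cladeAnnotations(cl),
                         cladeRefPsl(cl), cladeTree(cl),
                         pairPsl = cladePairPsl(cl))
  links <- queryLinks(res)
  expect_gt(nrow(links), 0)
  for (i in seq_len(nrow(links))) {
    key <- paste(links$species_a[i], links$species_b[i], sep = "|")
    psl <- cladePairPsl(cl)[[key]]
    aligned <- sum(pslBlocks(psl)$size)
    expect_lte(links$support[i], aligned)
  }
  expect_true(all(links$support > 0))
})

test_that("inverted alignments carry the inverted orientation", {
  frags <- rbind(mkFrag("A", "chrA", 1, 2000), mkFrag("B", "chrB", 1, 2000))
  inv <- readPsl(mkPslLine(100, 400, qName = "chrA", qStart = 100L,
                           tName = "chrB", strand = "-", qSize = 2000L))
  links <- buildLinks(frags, c("A", "B"), list(`A|B` = inv), 200)
  expect_equal(links$orientation, "inverted")
})
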