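test_that("duplication size tables respect the minimum-size exclusion", {
  ev <- data.frame(species = "A", class = "duplication", size = c(40, 60))
  tab <- duplicationSizeTable(ev, minSize = 50)
  expect_equal(sum(tab$count), 1)
  expect_equal(attr(tab, "excluded"), 1)

  allSmall <- data.frame(species = c("A", "B"), class = "duplication",
                         size = c(10, 49))
  tab0 <- duplicationSizeTable(allSmall)
  expect_true(all(tab0$count == 0))
  expect_equal(attr(tab0, "excluded"), 2)

  # non-duplication classes are tolerated and ignored
  mixed <- rbind(ev, data.frame(species = "A", class = "insertion",
                                size = 500))
  expect_equal(sum(duplicationSizeTable(mixed)$count), 1)
  expect_error(duplicationSizeTable(ev, bins = c(100)), "bins")
})

test_that("binned counts match a brute-force histogram", {
  set.seed(3)
  ev <- data.frame(species = sample(c("A", "B"), 100, TRUE),
                   class = "duplication",
                   size = round(runif(100, 50, 999)))
  bins <- seq(50, 1000, by = 190)
  tab <- duplicationSizeTable(ev, minSize = 50, bins = bins)
  for (sp in c("A", "B")) {
    for (j in seq_len(length(bins) - 1)) {
      oracle <- sum(ev$species == sp & ev$size >= bins[j] &
                      ev$size < bins[j + 1])
      lab <- paste0("[", bins[j], ",", bins[j + 1], ")")
      expect_equal(tab$count[tab$species == sp & tab$bin == lab], oracle)
    }
  }
  expect_equal(sum(tab$count), 100)
})

test_that("paired t-tests handle regular and degenerate sister pairs", {
  mk <- function(a, b) {
    bins <- paste0("b", seq_along(a))
    rbind(data.frame(species = "self", bin = bins, count = a),
          data.frame(species = "out", bin = bins, count = b))
  }
  # identical vectors: t = 0, p = 1
  eq <- sisterPairComparison(mk(c(3, 5, 2), c(3, 5, 2)),
                             list(c("self", "out")))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  expect_false(eq$degenerate)

  # constant non-zero differences: the classic zero-variance case
  deg <- sisterPairComparison(mk(c(1, 2, 3), c(2, 3, 4)),
                              list(c("self", "out")))
  expect_equal(deg$t, -Inf)
  expect_equal(deg$p, 0)
  expect_true(deg$degenerate)
  expect_equal(deg$mean_diff, -1)

  # a regular case agrees with the closed-form paired t
  a <- c(4, 9, 1, 7); b <- c(2, 3, 5, 1)
  got <- sisterPairComparison(mk(a, b), list(c("self", "out")))
  d <- a - b
  tt <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(got$t, tt)
  expect_equal(got$df, length(d) - 1)
  expect_equal(got$p, 2 * pt(-abs(tt), length(d) - 1))
  expect_equal(got$total_selfing, sum(a))

  # swapping the pair flips the sign of t, p unchanged
  swp <- sisterPairComparison(mk(a, b), list(c("out", "self")))
  expect_equal(swp$t, -got$t)
  expect_equal(swp$p, got$p)

  # missing species reported as NA with a reason
  na <- sisterPairComparison(mk(a, b), list(c("self", "ghost")))
  expect_true(is.na(na$t))
  expect_match(na$reason, "ghost")
})

test_that("simulated event tables flow through the comparison", {
  cl <- goldenClade()
  ev <- cladeDupEvents(cl)
  expect_true(all(c("species", "class", "size") %in% names(ev)))
  f <- tempfile(fileext = ".tsv")
  write.table(ev, f, sep = "\t", quote = FALSE, row.names = FALSE)
  ev2 <- readDupEvents(f)
  expect_equal(nrow(ev2), nrow(ev))
  tab <- duplicationSizeTable(ev2, minSize = 50)
  cmp <- sisterPairComparison(tab, list(c("S1", "S2"), c("S3", "S4")))
  expect_equal(nrow(cmp), 2)
  expect_true(all(!is.na(cmp$total_selfing)))
})
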