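#' Read a mutation-event table
#'
#' TSV with columns `species`, `class`, `size` (bp), as emitted by an
#' upstream mutation summary or by [writeClade()].
#'
#' @param file path.
#' @return data.frame of events.
#' @export
readDupEvents <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("species", "class", "size") %in% names(df)))
    .formatError("event table needs species, class, size columns")
  if (any(df$size <= 0)) .formatError("event sizes must be > 0")
  df
}

#' Binned duplication-event counts per species
#'
#' Keeps duplication events of at least `minSize` bp (smaller events are
#' excluded, as in the duplication-size analysis; the exclusion count is
#' attached as the `"excluded"` attribute) and counts them per species in
#' half-open size bins `[b_i, b_{i+1})`.
#'
#' @param events event data.frame (see [readDupEvents()]); classes other
#'   than `"duplication"` are tolerated and ignored.
#' @param minSize minimum event size in bp (default 50).
#' @param bins strictly increasing bin breaks; the last may be `Inf`.
#' @return long data.frame `species`, `bin`, `count`, with attributes
#'   `excluded` (events below `minSize`) and `breaks`.
#' @export
duplicationSizeTable <- function(events, minSize = 50,
                                 bins = c(50, 100, 250, 500, 1000, 5000, Inf)) {
  if (length(bins) < 2L || any(diff(bins) <= 0))
    .userError("bins must be >= 2 strictly increasing breaks")
  ev <- events[events$class == "duplication", , drop = FALSE]
  excluded <- sum(ev$size < minSize)
  ev <- ev[ev$size >= minSize, , drop = FALSE]
  ev <- ev[ev$size >= bins[1] & ev$size < bins[length(bins)], , drop = FALSE]
  lab <- paste0("[", bins[-length(bins)], ",", bins[-1], ")")
  species <- sort(unique(events$species))
  out <- expand.grid(species = species, bin = lab, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  cnt <- table(factor(ev$species, levels = species),
               cut(ev$size, breaks = bins, right = FALSE, labels = lab))
  out$count <- as.integer(cnt[cbind(out$species, out$bin)])
  attr(out, "excluded") <- excluded
  attr(out, "breaks") <- bins
  out
}

#' Paired comparison of duplication counts between sister species
#'
#' For each (selfing, outcrossing) sister pair, a paired t-test over the
#' per-bin duplication counts (differences taken selfing minus
#' outcrossing), with descriptive totals. Degenerate cases are handled
#' explicitly: identical count vectors give `t = 0, p = 1`; constant
#' non-zero differences (zero variance) give `t = +/-Inf, p = 0` and are
#' flagged `degenerate`. A pair with a species missing from the table, or
#' fewer than two bins, yields `NA` with a reason.
#'
#' @param counts binned count table from [duplicationSizeTable()].
#' @param pairs list of length-2 character vectors `c(selfing, outcrossing)`.
#' @return data.frame, one row per pair: `selfing`, `outcrossing`,
#'   `total_selfing`, `total_outcrossing`, `mean_diff`, `t`, `df`, `p`,
#'   `degenerate`, `reason`.
#' @export
sisterPairComparison <- function(counts, pairs) {
  rows <- list()
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    row <- data.frame(selfing = a, outcrossing = b,
                      total_selfing = NA_integer_,
                      total_outcrossing = NA_integer_,
                      mean_diff = NA_real_, t = NA_real_, df = NA_real_,
                      p = NA_real_, degenerate = FALSE, reason = "",
                      stringsAsFactors = FALSE)
    bins <- unique(counts$bin)
    xa <- counts$count[counts$species == a][match(bins, counts$bin[counts$species == a])]
    xb <- counts$count[counts$species == b][match(bins, counts$bin[counts$species == b])]
    if (!a %in% counts$species || !b %in% counts$species) {
      row$reason <- sprintf("species missing from count table: %s",
                            paste(setdiff(c(a, b), counts$species),
                                  collapse = ", "))
      rows[[length(rows) + 1L]] <- row; next
    }
    if (length(bins) < 2L) {
      row$reason <- "fewer than two paired observations"
      rows[[length(rows) + 1L]] <- row; next
    }
    row$total_selfing <- sum(xa); row$total_outcrossing <- sum(xb)
    d <- xa - xb
    row$mean_diff <- mean(d)
    row$df <- length(d) - 1
    if (stats::sd(d) == 0) {
      if (all(d == 0)) {
        row$t <- 0; row$p <- 1
      } else {
        row$t <- sign(mean(d)) * Inf; row$p <- 0; row$degenerate <- TRUE
      }
    } else {
      tt <- stats::t.test(xa, xb, paired = TRUE)
      row$t <- unname(tt$statistic); row$p <- tt$p.value
      row$df <- unname(tt$parameter)
    }
    rows[[length(rows) + 1L]] <- row
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
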