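#' Read a PSL alignment file
#'
#' Parses 21-column PSL (the pairwise alignment export of a liftover step).
#' An optional `psLayout` header block is tolerated and skipped. Every
#' record is validated against the PSL invariants (field count, integer
#' fields, block-list lengths, interval consistency, block sums); a
#' violation raises a format error naming the offending line.
#'
#' @param file path, or a character vector of lines (useful for tests).
#' @return a [PslAlignments-class].
#' @examples
#' line <- paste(80, 0, 0, 0, 0, 0, 1, 10, "+", "chrQ", 500, 10, 90,
#'               "chrT", 600, 100, 190, 2, "50,30,", "10,60,", "100,160,",
#'               sep = "\t")
#' psl <- readPsl(line)
#' pslBlocks(psl)
#' @export
readPsl <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\t", file) && file.exists(file))
    readLines(file) else file
  offset <- 0L
  if (length(lines) && grepl("^psLayout", lines[1])) {
    dash <- grep("^-+\\s*$", lines)
    if (!length(dash))
      .formatError("PSL header block not terminated by a dashed line")
    offset <- dash[1]
    lines <- lines[-seq_len(offset)]
  }
  keep <- nzchar(trimws(lines))
  lineno <- which(keep) + offset
  lines <- lines[keep]
  n <- length(lines)
  if (!n) return(new("PslAlignments", records = .emptyPslDf()))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) != 21L)
      .formatError("PSL line %d: expected 21 fields, found %d",
                   lineno[i], length(f))
    ints <- suppressWarnings(as.integer(f[c(1:8, 11:13, 15:18)]))
    if (anyNA(ints))
      .formatError("PSL line %d: non-integer numeric field", lineno[i])
    lists <- lapply(f[19:21], function(x)
      suppressWarnings(as.integer(strsplit(sub(",$", "", x), ",",
                                           fixed = TRUE)[[1]])))
    if (any(vapply(lists, anyNA, logical(1))))
      .formatError("PSL line %d: non-integer block list entry", lineno[i])
    rows[[i]] <- data.frame(
      matches = ints[1], misMatches = ints[2], repMatches = ints[3],
      nCount = ints[4], qNumInsert = ints[5], qBaseInsert = ints[6],
      tNumInsert = ints[7], tBaseInsert = ints[8], strand = f[9],
      qName = f[10], qSize = ints[9], qStart = ints[10], qEnd = ints[11],
      tName = f[14], tSize = ints[12], tStart = ints[13], tEnd = ints[14],
      blockCount = ints[15],
      blockSizes = I(list(lists[[1]])), qStarts = I(list(lists[[2]])),
      tStarts = I(list(lists[[3]])), stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, rows)
  e <- .pslFirstError(df)
  if (!is.null(e))
    .formatError("PSL line %d: %s", lineno[e$idx], e$msg)
  new("PslAlignments", records = df)
}

.emptyPslDf <- function() {
  df <- data.frame(
    matches = integer(0), misMatches = integer(0), repMatches = integer(0),
    nCount = integer(0), qNumInsert = integer(0), qBaseInsert = integer(0),
    tNumInsert = integer(0), tBaseInsert = integer(0), strand = character(0),
    qName = character(0), qSize = integer(0), qStart = integer(0),
    qEnd = integer(0), tName = character(0), tSize = integer(0),
    tStart = integer(0), tEnd = integer(0), blockCount = integer(0),
    stringsAsFactors = FALSE
  )
  df$blockSizes <- I(list()); df$qStarts <- I(list()); df$tStarts <- I(list())
  df
}

#' Construct a PslAlignments object from a records data.frame
#'
#' @param records data.frame in the 21-column layout of
#'   [PslAlignments-class] (list columns for the block fields).
#' @return a validated [PslAlignments-class].
#' @export
PslAlignments <- function(records = .emptyPslDf()) {
  rownames(records) <- NULL
  new("PslAlignments", records = records)
}

#' @describeIn PslAlignments number of records.
#' @param x a `PslAlignments`.
#' @export
setMethod("length", "PslAlignments", function(x) nrow(x@records))

#' Access the raw PSL record table
#'
#' @param x a [PslAlignments-class].
#' @return the underlying data.frame (PSL-native 0-based coordinates).
#' @export
pslRecords <- function(x) x@records

setMethod("show", "PslAlignments", function(object) {
  df <- object@records
  cat(sprintf("PslAlignments with %d record(s)\n", nrow(df)))
  if (nrow(df)) {
    cat(sprintf("  queries: %s\n",
                paste(unique(df$qName), collapse = ", ")))
    cat(sprintf("  targets: %s\n",
                paste(unique(df$tName), collapse = ", ")))
    cat(sprintf("  aligned bases: %d\n",
                sum(df$matches + df$misMatches + df$repMatches + df$nCount)))
  }
})

setMethod("[", "PslAlignments", function(x, i, j, ..., drop = FALSE) {
  df <- x@records[i, , drop = FALSE]
  rownames(df) <- NULL
  new("PslAlignments", records = df)
})

#' Per-block alignment coordinates, forward strand, 1-based closed
#'
#' Expands every PSL record into its aligned blocks. Negative-strand query
#' starts (stored in reverse-complement coordinates, per PSL) are converted
#' to forward-strand intervals.
#'
#' @param x a [PslAlignments-class].
#' @return data.frame with columns `record`, `qName`, `tName`, `strand`,
#'   `q_start`, `q_end`, `t_start`, `t_end`, `size` (1-based closed).
#' @export
pslBlocks <- function(x) {
  df <- x@records
  if (!nrow(df)) {
    return(data.frame(record = integer(0), qName = character(0),
                      tName = character(0), strand = character(0),
                      q_start = integer(0), q_end = integer(0),
                      t_start = integer(0), t_end = integer(0),
                      size = integer(0), stringsAsFactors = FALSE))
  }
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    bs <- df$blockSizes[[i]]; qs <- df$qStarts[[i]]; ts <- df$tStarts[[i]]
    qf <- if (df$strand[i] == "+") qs else df$qSize[i] - (qs + bs)
    out[[i]] <- data.frame(
      record = i, qName = df$qName[i], tName = df$tName[i],
      strand = df$strand[i],
      q_start = qf + 1L, q_end = qf + bs,
      t_start = ts + 1L, t_end = ts + bs, size = bs,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# Forward-strand query span per record, 1-based closed.
.pslQuerySpans <- function(x) {
  df <- x@records
  data.frame(qName = df$qName, q_start = df$qStart + 1L, q_end = df$qEnd,
             stringsAsFactors = FALSE)
}

#' Write PSL records
#'
#' Inverse of [readPsl()]: emits tab-separated 21-column lines with
#' comma-terminated block lists, so `readPsl(writePsl(x))` is the identity
#' field-for-field and files written here round-trip byte-for-byte.
#'
#' @param x a [PslAlignments-class].
#' @param file output path, or `NULL` to return the lines.
#' @param header emit the 5-line `psLayout` header block first.
#' @return the lines, invisibly when `file` is given.
#' @export
writePsl <- function(x, file = NULL, header = FALSE) {
  df <- x@records
  fmtList <- function(v) paste0(paste(v, collapse = ","), ",")
  lines <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    lines[i] <- paste(
      df$matches[i], df$misMatches[i], df$repMatches[i], df$nCount[i],
      df$qNumInsert[i], df$qBaseInsert[i], df$tNumInsert[i],
      df$tBaseInsert[i], df$strand[i],
      df$qName[i], df$qSize[i], df$qStart[i], df$qEnd[i],
      df$tName[i], df$tSize[i], df$tStart[i], df$tEnd[i],
      df$blockCount[i], fmtList(df$blockSizes[[i]]),
      fmtList(df$qStarts[[i]]), fmtList(df$tStarts[[i]]),
      sep = "\t")
  }
  if (header) {
    hdr <- c(
      "psLayout version 3",
      "",
      paste("match", "mis-", "rep.", "N's", "Q gap", "Q gap", "T gap",
            "T gap", "strand", "Q", "Q", "Q", "Q", "T", "T", "T", "T",
            "block", "blockSizes", "qStarts", "tStarts", sep = "\t"),
      paste("", "match", "match", "", "count", "bases", "count", "bases",
            "", "name", "size", "start", "end", "name", "size", "start",
            "end", "count", "", "", "", sep = "\t"),
      strrep("-", 120)
    )
    lines <- c(hdr, lines)
  }
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Swap the query and target roles of PSL records
#'
#' Produces the PSL that a liftover run in the opposite direction would
#' emit for the same alignment: query and target fields are exchanged and,
#' for negative-strand records, block order and reverse-complement query
#' coordinates are recomputed so target blocks stay ascending.
#'
#' @param x a [PslAlignments-class].
#' @return a [PslAlignments-class] with roles exchanged.
#' @export
transposePsl <- function(x) {
  df <- x@records
  out <- df
  out$qName <- df$tName; out$qSize <- df$tSize
  out$qStart <- df$tStart; out$qEnd <- df$tEnd
  out$tName <- df$qName; out$tSize <- df$qSize
  out$tStart <- df$qStart; out$tEnd <- df$qEnd
  out$qNumInsert <- df$tNumInsert; out$qBaseInsert <- df$tBaseInsert
  out$tNumInsert <- df$qNumInsert; out$tBaseInsert <- df$qBaseInsert
  for (i in seq_len(nrow(df))) {
    bs <- df$blockSizes[[i]]; qs <- df$qStarts[[i]]; ts <- df$tStarts[[i]]
    if (df$strand[i] == "+") {
      out$qStarts[[i]] <- ts
      out$tStarts[[i]] <- qs
    } else {
      # old query forward starts, reversed so the new target ascends
      qf <- df$qSize[i] - (qs + bs)
      ord <- rev(seq_along(bs))
      out$blockSizes[[i]] <- bs[ord]
      out$tStarts[[i]] <- qf[ord]
      # new query (= old target) in reverse-complement coordinates
      out$qStarts[[i]] <- (df$tSize[i] - (ts + bs))[ord]
    }
  }
  new("PslAlignments", records = out)
}

# Build one PSL record from forward-coordinate block pairs.
# blocks: data.frame(q_start, q_end, t_start, t_end) 1-based closed, equal
# widths per row. strand '-' means the query aligns reverse-complemented.
.pslFromBlocks <- function(qName, qSize, tName, tSize, strand, blocks,
                           misMatches = 0L) {
  stopifnot(nrow(blocks) >= 1L)
  blocks <- blocks[order(blocks$t_start), , drop = FALSE]
  sizes <- blocks$t_end - blocks$t_start + 1L
  stopifnot(all(sizes == blocks$q_end - blocks$q_start + 1L))
  ts0 <- blocks$t_start - 1L
  qf0 <- blocks$q_start - 1L
  qs0 <- if (strand == "+") qf0 else qSize - (qf0 + sizes)
  # gaps between consecutive blocks, target order; query gaps measured on
  # the forward query axis irrespective of orientation
  if (nrow(blocks) > 1L) {
    qiv <- cbind(qf0, qf0 + sizes)           # half-open forward interval
    ord <- order(qiv[, 1])
    qgaps <- qiv[ord[-1], 1] - qiv[ord[-length(ord)], 2]
    tgaps <- ts0[-1] - (ts0[-length(ts0)] + sizes[-length(sizes)])
  } else {
    qgaps <- integer(0); tgaps <- integer(0)
  }
  total <- sum(sizes)
  mis <- as.integer(min(misMatches, total))
  df <- data.frame(
    matches = total - mis, misMatches = mis, repMatches = 0L, nCount = 0L,
    qNumInsert = sum(qgaps > 0L), qBaseInsert = sum(qgaps[qgaps > 0L]),
    tNumInsert = sum(tgaps > 0L), tBaseInsert = sum(tgaps[tgaps > 0L]),
    strand = strand, qName = qName, qSize = as.integer(qSize),
    qStart = min(qf0), qEnd = as.integer(max(qf0 + sizes)),
    tName = tName, tSize = as.integer(tSize),
    tStart = ts0[1], tEnd = as.integer(ts0[length(ts0)] + sizes[length(sizes)]),
    blockCount = nrow(blocks), stringsAsFactors = FALSE
  )
  df$blockSizes <- I(list(as.integer(sizes)))
  df$qStarts <- I(list(as.integer(qs0)))
  df$tStarts <- I(list(as.integer(ts0)))
  df
}
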