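#' Coordinate-level homology maps
#'
#' A homology map records how a gene copy relates to its ancestral
#' (root) coordinate system after indels: an ordered set of matched
#' segments (`M` rows, intervals of root coordinates still present in the
#' copy) and insertions (`I` rows, novel bases anchored at a root
#' position). Deletions are implicit as missing root intervals. Maps are
#' the simulator's only representation of sequence evolution -- no
#' nucleotides are ever materialised -- and two maps suffice to compute
#' the exact pairwise alignment of their copies.
#'
#' @param length length of the ancestral segment in bp.
#' @return a `homology_map` data.frame with columns `kind` ("M"/"I"),
#'   `rs`, `re` (root interval, 0-based half-open; `rs == re` for `I`) and
#'   `len`.
#' @examples
#' m <- homologyMap(100)
#' m <- mapInsertion(m, 40, 10)  # 10 novel bases after root position 40
#' m <- mapDeletion(m, 60, 5)    # root bases [60, 65) removed
#' mapLength(m)                  # 100 + 10 - 5
#' @export
homologyMap <- function(length) {
  stopifnot(length >= 1)
  structure(data.frame(kind = "M", rs = 0L, re = as.integer(length),
                       len = as.integer(length), stringsAsFactors = FALSE),
            class = c("homology_map", "data.frame"))
}

#' @rdname homologyMap
#' @param map a homology map.
#' @return `mapLength`: copy length in bp (matched plus inserted bases).
#' @export
mapLength <- function(map) sum(map$len)

# keep rows ordered by root position; an I row anchored at p sits between
# the M material ending at p and the M material starting at p
.mapSort <- function(map) {
  ord <- order(map$rs, ifelse(map$kind == "I", 0L, 1L), map$re)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  map
}

#' @rdname homologyMap
#' @param pos root position of the event (insertion anchor, or deletion
#'   start), must lie within or at the boundary of matched material.
#' @param len event length in bp.
#' @return `mapInsertion` / `mapDeletion`: the updated map.
#' @export
mapInsertion <- function(map, pos, len) {
  stopifnot(len >= 1)
  pos <- as.integer(pos); len <- as.integer(len)
  hasI <- which(map$kind == "I" & map$rs == pos)
  if (length(hasI)) {           # co-anchored insertions coalesce
    map$len[hasI[1]] <- map$len[hasI[1]] + len
    return(map)
  }
  hit <- which(map$kind == "M" & map$rs < pos & map$re > pos)
  if (length(hit)) {            # split the matched row at the anchor
    r <- map[hit, ]
    top <- data.frame(kind = c("M", "I", "M"),
                      rs = c(r$rs, pos, pos), re = c(pos, pos, r$re),
                      len = c(pos - r$rs, len, r$re - pos),
                      stringsAsFactors = FALSE)
    map <- rbind(map[-hit, , drop = FALSE], top)
  } else {
    if (!any(map$kind == "M" & (map$rs == pos | map$re == pos)))
      .userError("insertion anchor %d outside matched material", pos)
    map <- rbind(map, data.frame(kind = "I", rs = pos, re = pos, len = len,
                                 stringsAsFactors = FALSE))
  }
  .mapSort(structure(map, class = c("homology_map", "data.frame")))
}

#' @rdname homologyMap
#' @export
mapDeletion <- function(map, pos, len) {
  stopifnot(len >= 1)
  pos <- as.integer(pos); to <- pos + as.integer(len)
  keep <- list()
  for (i in seq_len(nrow(map))) {
    r <- map[i, ]
    if (r$kind == "I") {
      if (r$rs <= pos || r$rs >= to) keep[[length(keep) + 1L]] <- r
      next
    }
    if (r$re <= pos || r$rs >= to) { keep[[length(keep) + 1L]] <- r; next }
    if (r$rs < pos) {
      keep[[length(keep) + 1L]] <- data.frame(kind = "M", rs = r$rs,
        re = pos, len = pos - r$rs, stringsAsFactors = FALSE)
    }
    if (r$re > to) {
      keep[[length(keep) + 1L]] <- data.frame(kind = "M", rs = to,
        re = r$re, len = r$re - to, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, keep)
  if (is.null(out) || !any(out$kind == "M"))
    .userError("deletion would remove all matched material")
  .mapSort(structure(out, class = c("homology_map", "data.frame")))
}

# copy-local offset of the start of each map row (map order)
.mapOffsets <- function(map) {
  c(0L, cumsum(map$len))[seq_len(nrow(map))]
}

# matched intervals with their copy-local start offsets
.mapMatched <- function(map) {
  off <- .mapOffsets(map)
  m <- map$kind == "M"
  data.frame(rs = map$rs[m], re = map$re[m], local = off[m])
}

# copy-local position of a root position (must be matched)
.mapLocate <- function(map, rootPos) {
  mm <- .mapMatched(map)
  i <- which(mm$rs <= rootPos & mm$re > rootPos)[1]
  if (is.na(i)) return(NA_integer_)
  mm$local[i] + (rootPos - mm$rs[i])
}

# root positions covered by matched rows, for drawing event positions
.mapMatchedBases <- function(map) {
  mm <- .mapMatched(map)
  list(rs = mm$rs, re = mm$re, total = sum(mm$re - mm$rs))
}

#' Exact pairwise alignment of two copies of one ancestral segment
#'
#' Intersects the matched root intervals of two homology maps. Adjacent
#' shared intervals are merged when the alignment runs through
#' uninterrupted on both copies (no insertion anchored at the junction in
#' either map and contiguous local coordinates on both sides); every
#' remaining boundary is an indel in at least one copy, which is exactly
#' where a liftover breaks its alignment blocks.
#'
#' @param mapQ,mapT homology maps of the query-side and target-side copy.
#' @return data.frame with one aligned segment per row: root interval
#'   (`rs`, `re`), copy-local half-open starts (`q_local`, `t_local`) and
#'   `len`.
#' @export
alignedSegments <- function(mapQ, mapT) {
  mq <- .mapMatched(mapQ); mt <- .mapMatched(mapT)
  iq <- IRanges::IRanges(mq$rs + 1L, mq$re)
  it <- IRanges::IRanges(mt$rs + 1L, mt$re)
  ov <- IRanges::findOverlaps(iq, it)
  if (!length(ov)) {
    return(data.frame(rs = integer(0), re = integer(0),
                      q_local = integer(0), t_local = integer(0),
                      len = integer(0)))
  }
  qi <- S4Vectors::queryHits(ov); ti <- S4Vectors::subjectHits(ov)
  rs <- pmax(mq$rs[qi], mt$rs[ti])
  re <- pmin(mq$re[qi], mt$re[ti])
  seg <- data.frame(
    rs = rs, re = re,
    q_local = mq$local[qi] + (rs - mq$rs[qi]),
    t_local = mt$local[ti] + (rs - mt$rs[ti]),
    len = re - rs)
  seg <- seg[seg$len > 0L, , drop = FALSE]
  seg <- seg[order(seg$rs), , drop = FALSE]
  # merge segments contiguous on both copies and not split by an insertion
  insAt <- function(map, p) any(map$kind == "I" & map$rs == p)
  out <- list(); cur <- seg[1, ]
  for (i in seq_len(nrow(seg))[-1]) {
    nxt <- seg[i, ]
    contiguous <- nxt$rs == cur$re &&
      nxt$q_local == cur$q_local + cur$len &&
      nxt$t_local == cur$t_local + cur$len &&
      !insAt(mapQ, cur$re) && !insAt(mapT, cur$re)
    if (contiguous) {
      cur$re <- nxt$re; cur$len <- cur$len + nxt$len
    } else {
      out[[length(out) + 1L]] <- cur; cur <- nxt
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Emit liftover-style PSL records for one aligned copy pair
#'
#' Converts the exact alignment of two gene copies ([alignedSegments()])
#' into PSL records the way a liftover export fragments them: by default
#' one record per segment, broken at every indel, so that the
#' inter-record target gaps equal the sizes of the simulated indels (the
#' mechanism the gap-value re-assembly exploits). With
#' `breakAtIndels = FALSE` one multi-block record is emitted instead,
#' with query/target gap counts in the PSL insert fields. Segments
#' shorter than `minBlock` are dropped, emulating liftover minimum block
#' output.
#'
#' @param mapQ,mapT homology maps of the two copies.
#' @param qName,tName chromosome names of query and target genomes.
#' @param qSize,tSize chromosome lengths.
#' @param qOffset,tOffset 1-based genome start of each copy.
#' @param qStrand,tStrand orientation of each copy on its genome.
#' @param divergence substitution divergence of the pair; distributed as
#'   mismatches proportionally over the aligned bases.
#' @param breakAtIndels emit one record per segment (default) or one
#'   multi-block record.
#' @param minBlock drop aligned segments shorter than this many bp.
#' @return a [PslAlignments-class] (possibly empty).
#' @export
fragmentAlignments <- function(mapQ, mapT, qName, qSize, qOffset, qStrand,
                               tName, tSize, tOffset, tStrand,
                               divergence = 0, breakAtIndels = TRUE,
                               minBlock = 1) {
  recs <- .fragmentRecords(mapQ, mapT, qName, qSize, qOffset, qStrand,
                           tName, tSize, tOffset, tStrand, divergence,
                           breakAtIndels, minBlock)
  if (is.null(recs)) PslAlignments() else PslAlignments(recs)
}

# record-table core of fragmentAlignments (no S4 construction, so the
# simulator can batch thousands of copy pairs cheaply)
.fragmentRecords <- function(mapQ, mapT, qName, qSize, qOffset, qStrand,
                             tName, tSize, tOffset, tStrand,
                             divergence = 0, breakAtIndels = TRUE,
                             minBlock = 1) {
  seg <- alignedSegments(mapQ, mapT)
  seg <- seg[seg$len >= minBlock, , drop = FALSE]
  if (!nrow(seg)) return(NULL)
  qLen <- mapLength(mapQ); tLen <- mapLength(mapT)
  toGenome <- function(local, len, offset, strand, copyLen) {
    if (strand == "+") offset + local
    else offset + (copyLen - (local + len))
  }
  blocks <- data.frame(
    q_start = toGenome(seg$q_local, seg$len, qOffset, qStrand, qLen),
    t_start = toGenome(seg$t_local, seg$len, tOffset, tStrand, tLen))
  blocks$q_end <- blocks$q_start + seg$len - 1L
  blocks$t_end <- blocks$t_start + seg$len - 1L
  strand <- if (qStrand == tStrand) "+" else "-"
  if (breakAtIndels) {
    # one single-block record per segment; built vectorised
    sizes <- as.integer(seg$len)
    mis <- as.integer(pmin(sizes, round(sizes * divergence)))
    qf0 <- as.integer(blocks$q_start - 1L)
    ts0 <- as.integer(blocks$t_start - 1L)
    qs0 <- if (strand == "+") qf0 else as.integer(qSize - (qf0 + sizes))
    df <- data.frame(
      matches = sizes - mis, misMatches = mis, repMatches = 0L,
      nCount = 0L, qNumInsert = 0L, qBaseInsert = 0L, tNumInsert = 0L,
      tBaseInsert = 0L, strand = strand, qName = qName,
      qSize = as.integer(qSize), qStart = qf0, qEnd = qf0 + sizes,
      tName = tName, tSize = as.integer(tSize), tStart = ts0,
      tEnd = ts0 + sizes, blockCount = 1L, stringsAsFactors = FALSE)
    df$blockSizes <- I(as.list(sizes))
    df$qStarts <- I(as.list(qs0))
    df$tStarts <- I(as.list(ts0))
    df
  } else {
    .pslFromBlocks(qName, qSize, tName, tSize, strand, blocks,
                   misMatches = round(sum(seg$len) * divergence))
  }
}
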