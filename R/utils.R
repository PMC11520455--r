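# Error helpers: format errors (bad input files) are distinguished from
# usage errors so the CLI can map them to distinct exit codes.
.formatError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cladesynteny_format_error", "error")))
}

.userError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cladesynteny_user_error", "error")))
}

# Deterministic orthogroup colour: hash the id to a hue. Plain polynomial
# string hash so figures are reproducible across sessions and platforms.
#' Deterministic colour for an orthogroup id
#'
#' Hashes the orthogroup identifier to a hue so that the same orthogroup is
#' drawn in the same colour in every plot and every session.
#'
#' @param og_id character vector of orthogroup ids.
#' @return character vector of hex colours.
#' @export
orthogroupColor <- function(og_id) {
  vapply(as.character(og_id), function(s) {
    h <- 0
    for (cp in utf8ToInt(s)) h <- (h * 31 + cp) %% 360L
    grDevices::hsv(h / 360, s = 0.55, v = 0.85)
  }, character(1), USE.NAMES = FALSE)
}

.emptyFragmentDf <- function() {
  data.frame(
    species = character(0), t_seq = character(0), strand = character(0),
    t_start = integer(0), t_end = integer(0), length = integer(0),
    n_members = integer(0), matches = integer(0), misMatches = integer(0),
    repMatches = integer(0), nCount = integer(0), qNumInsert = integer(0),
    tNumInsert = integer(0), q_start = integer(0), q_end = integer(0),
    members = I(list()), stringsAsFactors = FALSE
  )
}

.emptyLinkDf <- function() {
  data.frame(
    species_a = character(0), seq_a = character(0),
    start_a = integer(0), end_a = integer(0),
    species_b = character(0), seq_b = character(0),
    start_b = integer(0), end_b = integer(0),
    orientation = character(0), support = integer(0),
    stringsAsFactors = FALSE
  )
}

# write.table wrapper used for all emitted TSVs: stable column order, no
# quoting, no row names -- byte-reproducible output.
.writeTsv <- function(df, file) {
  df <- df[, setdiff(names(df), "members"), drop = FALSE]
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
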