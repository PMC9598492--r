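#' Read an all-vs-all protein homology table (BLAST tabular, outfmt 6)
#'
#' Rows with `e_value` above `max_evalue` (strictly greater; the cutoff is
#' inclusive) and self-hits (query equals subject) are excluded.
#'
#' @param path path to a tab-separated file with at least the 12 standard
#'   columns: qseqid, sseqid, pident, length, mismatch, gapopen, qstart,
#'   qend, sstart, send, evalue, bitscore
#' @param max_evalue e-value cutoff applied on read (default `1e-10`)
#' @return a tibble of retained hits with the 12 standard columns
#' @export
read_homology_table <- function(path, max_evalue = 1e-10) {
  assert_scalar_string(path, "path")
  if (!file.exists(path)) abort(sprintf("homology table not found: %s", path))
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "e_value", "bit_score")
  if (file.size(path) == 0) {
    out <- as_tibble(stats::setNames(
      c(list(character(0), character(0)), rep(list(numeric(0)), 10)), cols
    ))
    return(out)
  }
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(raw) < 12) {
    abort(sprintf("homology table must have >= 12 columns, found %d", ncol(raw)))
  }
  raw <- raw[, 1:12]
  names(raw) <- cols
  num_cols <- cols[3:12]
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    if (anyNA(v) && !all(is.na(raw[[cc]]))) {
      bad <- which(is.na(v) & !is.na(raw[[cc]]))[1]
      abort(sprintf("unparsable value in column %s at line %d", cc, bad))
    }
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      abort(sprintf("unparsable row at line %d", bad))
    }
    raw[[cc]] <- v
  }
  if (any(raw$e_value < 0)) abort("negative e-value in homology table")
  raw %>%
    filter(.data$e_value <= max_evalue, .data$query_id != .data$subject_id)
}

#' Write a hit table in BLAST tabular (outfmt 6) layout
#' @param hits tibble as returned by [read_homology_table()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_homology_table <- function(hits, path) {
  readr::write_tsv(hits, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
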