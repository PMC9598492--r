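#' Read a multi-record FASTA file into a named sequence set
#'
#' Sequences are uppercased and RNA `U` is mapped to `T`. The result is a
#' named character vector restricted to the alphabet {A,C,G,T,N}.
#'
#' @param path path to a FASTA file
#' @return named character vector, one element per record
#' @details Duplicate headers and empty sequences are hard errors; anything
#'   outside the DNA alphabet (after U->T) is rejected with the offending
#'   record named.
#' @export
read_fasta <- function(path) {
  assert_scalar_string(path, "path")
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    abort(sprintf(
      "duplicate FASTA header(s): %s",
      paste(unique(nm[duplicated(nm)]), collapse = ", ")
    ))
  }
  seqs <- chartr("U", "T", toupper(as.character(set)))
  names(seqs) <- nm
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    abort(sprintf("empty sequence for record(s): %s",
                  paste(nm[empty], collapse = ", ")))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(sprintf("non-ACGTN symbols in record(s): %s",
                  paste(nm[bad], collapse = ", ")))
  }
  seqs
}

#' Write a named sequence set as FASTA
#'
#' @param seqs named character vector of sequences
#' @param path output path
#' @param width line-wrap width in bases
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}
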