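#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% mutate filter arrange select group_by ungroup summarise
#'   bind_rows bind_cols left_join distinct n row_number across
NULL

# Fourfold-degenerate codon families of the standard genetic code: any third
# base encodes the same amino acid.
FOURFOLD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Reverse complement of nucleotide strings
#' @param x character vector over {A,C,G,T,N}
#' @return character vector of the same length
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Split a coding sequence into codons
#' @param s a single nucleotide string with length divisible by 3
#' @keywords internal
split_codons <- function(s) {
  n <- nchar(s)
  stopifnot(n %% 3 == 0)
  if (n == 0) return(character(0))
  substring(s, seq(1, n, by = 3), seq(3, n, by = 3))
}

#' Translate a CDS under the standard genetic code
#'
#' Codons containing any symbol outside {A,C,G,T} (e.g. N) translate to `X`;
#' stop codons translate to `*`.
#' @param s a nucleotide string, length divisible by 3
#' @return single amino-acid string
#' @export
translate_cds <- function(s) {
  codons <- split_codons(toupper(s))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Is a codon a member of a fourfold-degenerate family?
#' @param codon character vector of 3-mers
#' @return logical vector; FALSE for codons containing non-ACGT symbols
#' @export
is_fourfold_codon <- function(codon) {
  ok <- !grepl("[^ACGT]", codon) & nchar(codon) == 3L
  ok & substr(codon, 1, 2) %in% FOURFOLD_PREFIXES
}

# deterministic seed derivation, kept below 2^31
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  as.integer((sum(parts * seq_along(parts) * 7919) + 13L) %% 2147483647)
}

assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single string", what))
  }
}
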