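#' Global protein alignment (Needleman-Wunsch, affine gaps)
#'
#' A thin wrapper over [Biostrings::pairwiseAlignment()] with BLOSUM62
#' scoring and affine gap penalties (open 10, extend 1 by default). Only the
#' choice of aligned columns depends on these settings; the 4DTv statistic's
#' definition does not.
#'
#' @param seq_a,seq_b amino-acid strings (no gaps); `*` and `X` are allowed
#' @param gap_open,gap_extend positive gap penalties
#' @param matrix substitution matrix name understood by Biostrings
#' @return list with aligned strings `a`, `b` (equal length, `-` gaps) and
#'   the alignment `score`
#' @export
align_proteins_global <- function(seq_a, seq_b, gap_open = 10, gap_extend = 1,
                                  matrix = "BLOSUM62") {
  for (s in c(seq_a, seq_b)) {
    if (!nzchar(s)) abort("empty protein sequence")
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", s)) {
      abort("non-amino-acid symbol in protein sequence")
    }
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  list(
    a = as.character(Biostrings::alignedPattern(aln)),
    b = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln)
  )
}

#' Back-translate a protein alignment to paired codon columns
#'
#' Each gapless aligned residue pair is mapped to its source codons; columns
#' aligned to a gap are dropped, as are columns where either codon contains a
#' non-ACGT symbol (e.g. N). A terminal stop codon on either CDS is trimmed
#' before validation.
#'
#' @param protein_aln alignment from [align_proteins_global()]
#' @param cds_a,cds_b the coding sequences whose translations equal the
#'   ungapped alignment rows
#' @param id_a,id_b identifiers used in error messages and the result
#' @return a `codon_alignment`: tibble with columns `codon_a`, `codon_b`,
#'   plus attributes `id_a`, `id_b`, `n_dropped_gap`, `n_dropped_n`
#' @export
backtranslate <- function(protein_aln, cds_a, cds_b,
                          id_a = "seq_a", id_b = "seq_b") {
  trim_stop <- function(cds) {
    aa <- translate_cds(cds)
    if (nchar(aa) > 0 && substr(aa, nchar(aa), nchar(aa)) == "*") {
      substr(cds, 1, nchar(cds) - 3)
    } else cds
  }
  cds_a <- trim_stop(toupper(cds_a))
  cds_b <- trim_stop(toupper(cds_b))
  check_row <- function(aligned, cds, id) {
    ungapped <- gsub("-", "", aligned)
    aa <- translate_cds(cds)
    if (!identical(aa, ungapped)) {
      av <- strsplit(aa, "")[[1]]
      uv <- strsplit(ungapped, "")[[1]]
      m <- min(length(av), length(uv))
      idx <- which(av[seq_len(m)] != uv[seq_len(m)])[1]
      if (is.na(idx)) idx <- m + 1L
      abort(sprintf(
        "translation of %s does not match its alignment row (residue %d)",
        id, idx
      ))
    }
  }
  check_row(protein_aln$a, cds_a, id_a)
  check_row(protein_aln$b, cds_b, id_b)

  col_a <- strsplit(protein_aln$a, "")[[1]]
  col_b <- strsplit(protein_aln$b, "")[[1]]
  codons_a <- split_codons(cds_a)
  codons_b <- split_codons(cds_b)
  ia <- cumsum(col_a != "-")
  ib <- cumsum(col_b != "-")
  gapless <- col_a != "-" & col_b != "-"
  ca <- codons_a[ia[gapless]]
  cb <- codons_b[ib[gapless]]
  clean <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  out <- tibble(codon_a = ca[clean], codon_b = cb[clean])
  attr(out, "id_a") <- id_a
  attr(out, "id_b") <- id_b
  attr(out, "n_dropped_gap") <- sum(!gapless)
  attr(out, "n_dropped_n") <- sum(!clean)
  class(out) <- c("codon_alignment", class(out))
  out
}

#' Is an aligned codon column a comparable fourfold-degenerate site?
#'
#' TRUE iff both codons belong to fourfold-degenerate families (third
#' position free) and their first two positions are identical, so the
#' degeneracy class is shared and any third-position difference is
#' synonymous.
#'
#' @param codon_a,codon_b character vectors of 3-mers (vectorised)
#' @return logical vector
#' @export
classify_fourfold_column <- function(codon_a, codon_b) {
  is_fourfold_codon(codon_a) & is_fourfold_codon(codon_b) &
    substr(codon_a, 1, 2) == substr(codon_b, 1, 2)
}

#' Is a base substitution a transversion?
#'
#' A transversion exchanges a purine (A/G) with a pyrimidine (C/T).
#'
#' @param base_a,base_b character vectors over {A,C,G,T} (vectorised)
#' @return logical vector; FALSE for identities and transitions
#' @export
is_transversion <- function(base_a, base_b) {
  (base_a %in% PURINES & base_b %in% PYRIMIDINES) |
    (base_a %in% PYRIMIDINES & base_b %in% PURINES)
}

#' Correct a raw 4D transversion proportion for multiple substitutions
#'
#' The default saturation correction is `d = -1/2 * log(1 - 2p)`: under
#' time-reversible models with symmetric base composition, the transversion
#' proportion saturates at 1/2, and this inverts that decay. The `"hky"`
#' alternative uses the observed purine/pyrimidine composition `g_R`, `g_Y`
#' at the compared sites: `d = -2 g_R g_Y log(1 - p / (2 g_R g_Y))`,
#' which reduces to the default at equal composition.
#'
#' @param p raw transversion proportion(s) in `[0, 1]`
#' @param method `"saturation"` (default) or `"hky"`
#' @param g_r,g_y purine and pyrimidine frequencies (only for `"hky"`)
#' @return corrected distance; `NA` where the argument of the logarithm is
#'   non-positive (saturated)
#' @export
correct_4dtv <- function(p, method = c("saturation", "hky"),
                         g_r = 0.5, g_y = 0.5) {
  method <- match.arg(method)
  arg <- switch(method,
    saturation = 1 - 2 * p,
    hky = 1 - p / (2 * g_r * g_y)
  )
  out <- ifelse(arg > 0,
                switch(method,
                       saturation = -0.5 * log(arg),
                       hky = -2 * g_r * g_y * log(arg)),
                NA_real_)
  unname(out) + 0  # avoid IEEE negative zero at p = 0
}

#' The 4DTv statistic for one codon alignment
#'
#' Over codon columns that are comparable fourfold-degenerate sites, the raw
#' statistic is the proportion of third-position transversions; the corrected
#' distance applies [correct_4dtv()]. Pairs with fewer than `min_4d`
#' comparable sites are flagged `"short"`; pairs at or beyond transversion
#' saturation (`p_raw >= 0.5` under the default correction) are flagged
#' `"saturated"` with an undefined distance.
#'
#' @param codon_aln a codon alignment from [backtranslate()]
#' @param min_4d minimum number of comparable 4D sites (default 10)
#' @param correction correction method passed to [correct_4dtv()]
#' @return one-row tibble: `id_a`, `id_b`, `n_4d`, `n_tv`, `p_raw`,
#'   `d_corr`, `status` in {"ok", "short", "saturated"}
#' @export
fourdtv <- function(codon_aln, min_4d = 10, correction = "saturation") {
  is4d <- classify_fourfold_column(codon_aln$codon_a, codon_aln$codon_b)
  third_a <- substr(codon_aln$codon_a[is4d], 3, 3)
  third_b <- substr(codon_aln$codon_b[is4d], 3, 3)
  n_4d <- sum(is4d)
  n_tv <- sum(is_transversion(third_a, third_b))
  p_raw <- if (n_4d > 0) n_tv / n_4d else NA_real_
  if (n_4d < min_4d) {
    status <- "short"
    d_corr <- NA_real_
  } else {
    thirds <- c(third_a, third_b)
    d_corr <- correct_4dtv(
      p_raw, method = correction,
      g_r = mean(thirds %in% PURINES), g_y = mean(thirds %in% PYRIMIDINES)
    )
    status <- if (is.na(d_corr)) "saturated" else "ok"
  }
  tibble(
    id_a = attr(codon_aln, "id_a") %||% "seq_a",
    id_b = attr(codon_aln, "id_b") %||% "seq_b",
    n_4d = n_4d, n_tv = n_tv, p_raw = p_raw, d_corr = d_corr, status = status
  )
}

#' 4DTv between two coding sequences
#'
#' Convenience wrapper: translate, align the proteins globally, back-translate
#' to codon columns, and compute [fourdtv()].
#'
#' @param cds_a,cds_b coding sequences (length divisible by 3)
#' @param id_a,id_b identifiers for the result row
#' @inheritParams fourdtv
#' @inheritParams align_proteins_global
#' @return one-row tibble as from [fourdtv()]
#' @export
fourdtv_pair <- function(cds_a, cds_b, id_a = "seq_a", id_b = "seq_b",
                         min_4d = 10, correction = "saturation",
                         gap_open = 10, gap_extend = 1) {
  trim <- function(cds) {
    aa <- translate_cds(cds)
    if (nchar(aa) > 0 && endsWith(aa, "*")) substr(cds, 1, nchar(cds) - 3) else cds
  }
  cds_a <- trim(toupper(cds_a)); cds_b <- trim(toupper(cds_b))
  aln <- align_proteins_global(translate_cds(cds_a), translate_cds(cds_b),
                               gap_open = gap_open, gap_extend = gap_extend)
  caln <- backtranslate(aln, cds_a, cds_b, id_a = id_a, id_b = id_b)
  fourdtv(caln, min_4d = min_4d, correction = correction)
}
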