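#' Construct a genotype matrix
#'
#' The container for biallelic SNP genotypes: samples x loci alt-allele
#' counts in {0, 1, 2, NA} plus per-genotype sequencing depth.
#'
#' @param g integer matrix, samples x loci, entries in {0,1,2,NA}
#' @param dp numeric matrix of per-genotype depths (NA where absent), same
#'   dimensions as `g`, or NULL when no depth information exists
#' @param loci data frame with columns `chrom`, `pos` (1-based), `ref`, `alt`
#' @param samples character vector of sample identifiers
#' @return a `geno_matrix` object
#' @export
geno_matrix <- function(g, dp = NULL, loci, samples = rownames(g)) {
  g <- as.matrix(g)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(g)))
  loci <- as_tibble(loci)
  stopifnot(
    ncol(g) == nrow(loci),
    all(c("chrom", "pos", "ref", "alt") %in% names(loci)),
    all(g %in% c(0L, 1L, 2L) | is.na(g))
  )
  # positions strictly increasing within chromosome
  by_chr <- split(loci$pos, loci$chrom)
  if (any(vapply(by_chr, function(p) is.unsorted(p, strictly = TRUE), TRUE))) {
    abort("locus positions must be strictly increasing within chromosome")
  }
  if (!is.null(dp)) {
    dp <- as.matrix(dp)
    stopifnot(all(dim(dp) == dim(g)))
    g[is.na(dp)] <- NA_integer_
  }
  dimnames(g) <- list(samples, paste(loci$chrom, loci$pos, sep = "_"))
  if (!is.null(dp)) dimnames(dp) <- dimnames(g)
  structure(
    list(g = g, dp = dp, loci = loci, samples = samples),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d samples x %d loci (%.1f%% missing calls, depth %s)\n",
    length(x$samples), nrow(x$loci), 100 * mean(is.na(x$g)),
    if (is.null(x$dp)) "absent" else "present"
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$g)

#' Read SNP genotypes from a VCF file
#'
#' Keeps biallelic SNP records only; multiallelic and non-SNP (indel) records
#' are skipped and counted. Genotypes are coded as alt-allele counts; half
#' calls (e.g. `./1`) are treated as missing. Depth is taken from the
#' per-sample `FORMAT/DP` field; if absent, depth is recorded as missing and
#' genotypes are kept, with a single warning.
#'
#' @param path path to a VCF v4.x file with GT (and ideally DP) FORMAT fields
#' @return a [geno_matrix()]; attribute `skipped` counts discarded records
#' @export
read_vcf <- function(path) {
  assert_scalar_string(path, "path")
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  alt <- fix$ALT
  ref <- fix$REF
  multi <- grepl(",", alt)
  snp <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  keep <- !multi & snp
  skipped <- c(multiallelic = sum(multi), non_snp = sum(!snp & !multi))
  if (!any(keep)) abort("no biallelic SNP records in VCF")

  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fmt <- if ("FORMAT" %in% colnames(v@gt)) v@gt[keep, "FORMAT"] else character(0)
  has_dp <- length(fmt) > 0 && all(vapply(
    strsplit(fmt, ":"), function(f) "DP" %in% f, TRUE
  ))
  dp <- if (has_dp) {
    suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[keep, , drop = FALSE]
    )
  } else {
    warn("FORMAT/DP absent; depths recorded as missing, genotypes kept")
    NULL
  }

  code_gt <- function(x) {
    x <- sub(":.*$", "", x)
    x <- chartr("|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    out
  }
  g <- apply(gt, 2, code_gt)
  if (is.null(dim(g))) g <- matrix(g, nrow = 1, dimnames = list(NULL, names(g)))

  loci <- tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = ref[keep],
    alt = alt[keep]
  )
  gm <- geno_matrix(t(g), dp = if (is.null(dp)) NULL else t(dp),
                    loci = loci, samples = colnames(gt))
  attr(gm, "skipped") <- skipped
  gm
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits GT and (when present) DP FORMAT fields, deterministically ordered by
#' chromosome then position.
#'
#' @param gm a [geno_matrix()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  ), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$g + 1L], nrow = nrow(gm$g))
  gt_str[is.na(gm$g)] <- "./."
  has_dp <- !is.null(gm$dp)
  ord <- order(gm$loci$chrom, gm$loci$pos)
  lines <- vapply(ord, function(l) {
    cells <- if (has_dp) {
      d <- gm$dp[, l]
      paste0(gt_str[, l], ":", ifelse(is.na(d), ".", format(d, trim = TRUE)))
    } else {
      gt_str[, l]
    }
    paste(c(gm$loci$chrom[l], gm$loci$pos[l], ".", gm$loci$ref[l],
            gm$loci$alt[l], ".", "PASS", ".",
            if (has_dp) "GT:DP" else "GT", cells), collapse = "\t")
  }, "")
  writeLines(lines, con)
  invisible(path)
}
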