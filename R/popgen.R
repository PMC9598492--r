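#' Apply the SNP filter cascade
#'
#' Three stages, in order: (I) genotypes whose depth lies outside
#' `[dp_min, dp_max]` are masked to missing; (II) loci with a missing-call
#' fraction of `max_missing` or more are dropped; (III) loci whose minor
#' allele frequency, computed on the remaining calls, is not strictly above
#' `maf_min` are dropped. Per-stage attrition is recorded.
#'
#' @param gm a [geno_matrix()]
#' @param dp_min,dp_max inclusive per-genotype depth bounds (default 20, 200)
#' @param maf_min strict lower bound on minor allele frequency (default 0.05)
#' @param max_missing loci with missing fraction `>= max_missing` are
#'   dropped (default 0.10, i.e. "less than 10% missing")
#' @return filtered [geno_matrix()]; attribute `attrition` is a tibble of
#'   per-stage locus counts and masked-genotype counts
#' @export
apply_filters <- function(gm, dp_min = 20, dp_max = 200, maf_min = 0.05,
                          max_missing = 0.10) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (dp_min > dp_max) abort("dp_min must not exceed dp_max")
  g <- gm$g
  n_start <- ncol(g)

  n_masked <- 0L
  if (!is.null(gm$dp)) {
    bad_depth <- !is.na(gm$dp) & (gm$dp < dp_min | gm$dp > dp_max)
    # depth absent => genotype already missing by construction
    mask <- bad_depth & !is.na(g)
    n_masked <- sum(mask)
    g[bad_depth] <- NA_integer_
  }

  miss_frac <- colMeans(is.na(g))
  keep_miss <- miss_frac < max_missing
  g2 <- g[, keep_miss, drop = FALSE]

  p_alt <- colMeans(g2, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  maf[is.nan(maf)] <- 0
  keep_maf <- maf > maf_min
  keep_idx <- which(keep_miss)[keep_maf]

  attrition <- tibble(
    stage = c("input", "depth_mask", "missingness", "maf"),
    loci = c(n_start, n_start, sum(keep_miss), length(keep_idx)),
    genotypes_masked = c(0L, n_masked, 0L, 0L)
  )
  if (length(keep_idx) == 0) {
    msg <- paste(utils::capture.output(print(as.data.frame(attrition))),
                 collapse = "\n")
    abort(paste0("all loci removed by the filter cascade:\n", msg))
  }
  out <- geno_matrix(
    g[, keep_idx, drop = FALSE],
    dp = if (is.null(gm$dp)) NULL else gm$dp[, keep_idx, drop = FALSE],
    loci = gm$loci[keep_idx, , drop = FALSE],
    samples = gm$samples
  )
  inform(sprintf(
    "apply_filters: %d -> %d loci (depth-masked %d genotypes; %d dropped by missingness, %d by MAF)",
    n_start, length(keep_idx), n_masked,
    n_start - sum(keep_miss), sum(keep_miss) - length(keep_idx)
  ))
  attr(out, "attrition") <- attrition
  out
}

#' Restrict loci to fourfold-degenerate coding sites
#'
#' Keeps loci whose genomic position is the third base of a codon of a
#' representative CDS whose codon family is fourfold degenerate (classified
#' on the reference codon, strand-aware), so both alleles are synonymous by
#' construction. Positions claimed as fourfold sites by genes on both
#' strands are excluded and counted; codons containing N are never
#' classified.
#'
#' @param gm a [geno_matrix()]
#' @param catalog a [gene_catalog()] on the same assembly
#' @param genome named character vector of chromosome sequences
#' @return filtered [geno_matrix()]; attribute `n_ambiguous` counts loci
#'   excluded for double-strand gene overlap
#' @export
restrict_to_4d_sites <- function(gm, catalog, genome) {
  sites <- fourfold_site_table(catalog, genome)
  key <- paste(gm$loci$chrom, gm$loci$pos)
  amb_key <- paste(sites$chrom[sites$ambiguous], sites$pos[sites$ambiguous])
  ok_key <- paste(sites$chrom[!sites$ambiguous], sites$pos[!sites$ambiguous])
  keep <- key %in% ok_key
  n_ambiguous <- sum(key %in% amb_key)
  if (!any(keep)) abort("no loci at fourfold-degenerate sites")
  out <- geno_matrix(
    gm$g[, keep, drop = FALSE],
    dp = if (is.null(gm$dp)) NULL else gm$dp[, keep, drop = FALSE],
    loci = gm$loci[keep, , drop = FALSE],
    samples = gm$samples
  )
  inform(sprintf(
    "restrict_to_4d_sites: %d -> %d loci (%d ambiguous double-strand sites excluded)",
    ncol(gm$g), sum(keep), n_ambiguous
  ))
  attr(out, "n_ambiguous") <- n_ambiguous
  out
}

#' Genomic positions of fourfold-degenerate third codon positions
#'
#' @inheritParams restrict_to_4d_sites
#' @return tibble `(chrom, pos, gene_id, strand, ref_codon, ambiguous)`;
#'   `ambiguous` marks positions claimed by genes on both strands
#' @export
fourfold_site_table <- function(catalog, genome) {
  cds <- extract_cds(catalog[catalog$valid, , drop = FALSE], genome)
  valid <- catalog[catalog$valid, , drop = FALSE]
  per_gene <- purrr::map(seq_len(nrow(valid)), function(i) {
    s <- cds[[valid$gene_id[i]]]
    codons <- split_codons(s)
    is4d <- is_fourfold_codon(codons)
    if (!any(is4d)) return(NULL)
    gpos <- cds_genomic_positions(valid$cds[[i]], valid$strand[i])
    third <- gpos[3 * which(is4d)]
    tibble(
      chrom = valid$chrom[i], pos = third, gene_id = valid$gene_id[i],
      strand = valid$strand[i], ref_codon = codons[is4d]
    )
  })
  sites <- bind_rows(per_gene)
  if (nrow(sites) == 0) {
    return(tibble(chrom = character(0), pos = integer(0),
                  gene_id = character(0), strand = character(0),
                  ref_codon = character(0), ambiguous = logical(0)))
  }
  sites %>%
    group_by(.data$chrom, .data$pos) %>%
    mutate(ambiguous = dplyr::n_distinct(.data$strand) > 1) %>%
    ungroup()
}

#' Per-locus diversity statistics
#'
#' With allele frequencies `p_i` over non-missing calls at a locus:
#' gene diversity (expected heterozygosity) `GD = 1 - sum(p_i^2)`;
#' polymorphism information content
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`; observed
#' heterozygosity `Ho` = fraction of heterozygous among non-missing
#' genotypes; `MAF = min(p, 1 - p)`.
#'
#' @param gm a [geno_matrix()]
#' @return tibble, one row per locus: `chrom`, `pos`, `n_called`, `p_alt`,
#'   `maf`, `gd`, `pic`, `ho`, `defined` (FALSE where no genotype is called)
#' @export
locus_stats <- function(gm) {
  g <- unname(gm$g)
  n_called <- colSums(!is.na(g))
  p <- colMeans(g, na.rm = TRUE) / 2
  q <- 1 - p
  gd <- 1 - (p^2 + q^2)
  pic <- gd - 2 * p^2 * q^2
  ho <- colMeans(g == 1L, na.rm = TRUE)
  out <- tibble(
    chrom = gm$loci$chrom, pos = gm$loci$pos,
    n_called = as.integer(n_called),
    p_alt = p, maf = pmin(p, q), gd = gd, pic = pic, ho = ho,
    defined = n_called > 0
  )
  if (any(!out$defined)) {
    warn(sprintf("%d locus/loci with zero called genotypes; stats undefined",
                 sum(!out$defined)))
    out$p_alt[!out$defined] <- NA_real_
    out$maf[!out$defined] <- NA_real_
    out$gd[!out$defined] <- NA_real_
    out$pic[!out$defined] <- NA_real_
    out$ho[!out$defined] <- NA_real_
  }
  out
}

#' Across-locus summary of diversity statistics
#'
#' @param stats tibble from [locus_stats()]
#' @return tibble `(statistic, mean, min, max)` over defined loci for
#'   `gd`, `pic`, `ho`, `maf`
#' @export
locus_stats_summary <- function(stats) {
  sel <- stats[stats$defined, c("gd", "pic", "ho", "maf")]
  tibble(
    statistic = c("gd", "pic", "ho", "maf"),
    mean = vapply(sel, mean, 0),
    min = vapply(sel, min, 0),
    max = vapply(sel, max, 0)
  )
}

#' Covariance-method principal component analysis of genotypes
#'
#' Missing genotypes are imputed to the locus mean; the sample x locus
#' matrix is locus-mean-centred and decomposed via the sample covariance
#' (no scaling). Eigenvalues are sorted descending and their proportions
#' sum to 1 over the returned components. Sign convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param gm a [geno_matrix()]
#' @return a `geno_pca`: list with `scores` (samples x k), `loadings`
#'   (loci x k), `eigenvalues`, `prop_var`, `samples`
#' @export
pca_covariance <- function(gm) {
  g <- gm$g
  if (nrow(g) < 2) abort("PCA requires at least 2 samples")
  mu <- colMeans(g, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  X <- g
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    v <- pc$rotation[, k]
    v[which.max(abs(v))] < 0
  }, TRUE)
  pc$rotation[, flip] <- -pc$rotation[, flip]
  pc$x[, flip] <- -pc$x[, flip]
  ev <- pc$sdev^2
  structure(
    list(
      scores = pc$x,
      loadings = pc$rotation,
      eigenvalues = ev,
      prop_var = ev / sum(ev),
      samples = gm$samples
    ),
    class = "geno_pca"
  )
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("<geno_pca> %d samples, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores), 100 * x$prop_var[1],
              100 * (x$prop_var[2] %||% NA)))
  invisible(x)
}

#' Allele-sharing distance matrix
#'
#' `d(i, j)` is the mean over co-called loci of `|g_i - g_j| / 2`;
#' symmetric with a zero diagonal. Pairs with no co-called locus get `NA`
#' with a warning.
#'
#' @param gm a [geno_matrix()]
#' @return numeric samples x samples matrix
#' @export
distance_matrix <- function(gm) {
  g <- gm$g
  n <- nrow(g)
  d <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      co <- !is.na(g[i, ]) & !is.na(g[j, ])
      d[i, j] <- d[j, i] <-
        if (any(co)) mean(abs(g[i, co] - g[j, co]) / 2) else NA_real_
    }
  }
  if (anyNA(d)) warn("sample pair(s) with zero co-called loci: distance undefined")
  d
}
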