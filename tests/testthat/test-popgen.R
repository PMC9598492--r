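filter_toy <- function() {
  p <- make_toy_fixtures(withr::local_tempdir(.local_envir = parent.frame()))
  read_vcf(p$filter_vcf)
}

test_that("the filter cascade masks depths, then drops missing and low-MAF loci", {
  gm <- filter_toy()
  out <- suppressMessages(apply_filters(gm))
  att <- attr(out, "attrition")
  # depths 10 and 250 masked for sample 1 (loci 1 and 3)
  expect_equal(att$genotypes_masked[att$stage == "depth_mask"], 2L)
  # locus 1: 2/10 missing (0.20 >= 0.10); locus 3: 1/10 (0.10 >= 0.10): dropped
  expect_equal(att$loci[att$stage == "missingness"], 3L)
  # locus 2 has a single alt allele: MAF 0.05 is not strictly > 0.05
  expect_equal(att$loci[att$stage == "maf"], 2L)
  expect_equal(out$loci$pos, c(400L, 500L))
})

test_that("apply_filters is idempotent", {
  gm <- filter_toy()
  once <- suppressMessages(apply_filters(gm))
  twice <- suppressMessages(apply_filters(once))
  expect_identical(once$g, twice$g)
  expect_identical(once$dp, twice$dp)
  expect_identical(once$loci, twice$loci)
})

test_that("removing every locus raises an error carrying the attrition table", {
  gm <- filter_toy()
  # depth bounds no genotype can satisfy mask every call
  expect_error(suppressMessages(apply_filters(gm, dp_min = 300, dp_max = 400)),
               "all loci removed")
})

test_that("dp_min above dp_max is rejected", {
  gm <- filter_toy()
  expect_error(apply_filters(gm, dp_min = 100, dp_max = 50), "dp_min")
})

test_that("fourfold-site restriction keeps third positions of 4D reference codons", {
  # plus-strand gene: ATG GGA TTT -> 4D codon GGA, third base at position 6
  genome <- c(c1 = "ATGGGATTTAAA")
  cat <- gene_catalog(tibble::tibble(
    gene_id = "gp", chrom = "c1", strand = "+",
    cds = list(data.frame(start = 1L, end = 9L))
  ))
  sites <- fourfold_site_table(cat, genome)
  expect_equal(sites$pos, 6L)
  expect_equal(sites$ref_codon, "GGA")

  g <- matrix(c(0L, 1L, 2L), 3, 3)
  gm <- geno_matrix(g, loci = data.frame(
    chrom = "c1", pos = c(5L, 6L, 7L), ref = "G", alt = "A"
  ))
  out <- suppressMessages(restrict_to_4d_sites(gm, cat, genome))
  expect_equal(out$loci$pos, 6L)  # positions 5 (2nd codon pos) and 7 dropped
})

test_that("fourfold positions on the minus strand map through the splice", {
  p <- make_toy_fixtures(withr::local_tempdir())
  genome <- read_fasta(p$splice_fasta)
  cat <- read_gff3(p$splice_gff3, genome)
  # spliced CDS CTT AAC CGG ATG CCA ATG: fourfold codons CTT, CGG, CCA.
  # Transcription order walks genomic 39..31 then 19..11, so their third
  # bases (CDS positions 3, 9, 15) sit at genomic 37, 31 and 14 by hand.
  sites <- fourfold_site_table(cat, genome)
  expect_equal(sites$pos, c(37L, 31L, 14L))
  expect_identical(sites$ref_codon, c("CTT", "CGG", "CCA"))
})

test_that("positions claimed by genes on both strands are excluded", {
  # plus gene 1..9: ATG GGA GGT (4D thirds at genomic 6 and 9);
  # minus gene 3..11: revcomp -> TTA CCT CCC (4D thirds at genomic 6 and 3).
  # Genomic position 6 is claimed by both strands.
  genome <- c(c1 = "ATGGGAGGTAA")
  cat <- gene_catalog(tibble::tibble(
    gene_id = c("gp", "gm2"), chrom = "c1", strand = c("+", "-"),
    cds = list(data.frame(start = 1L, end = 9L),
               data.frame(start = 3L, end = 11L))
  ))
  sites <- fourfold_site_table(cat, genome)
  expect_setequal(sites$pos[sites$ambiguous], 6L)
  g <- matrix(0:2, 3, 3)
  gm <- geno_matrix(g, loci = data.frame(
    chrom = "c1", pos = c(3L, 6L, 9L), ref = "G", alt = "A"
  ))
  out <- suppressMessages(restrict_to_4d_sites(gm, cat, genome))
  expect_equal(out$loci$pos, c(3L, 9L))
  expect_equal(attr(out, "n_ambiguous"), 1L)
})

test_that("diversity statistics match their closed forms", {
  # p = (0.5, 0.5): 10 samples, 10 alt alleles
  g <- matrix(c(rep(1L, 10)), 10, 1)
  gm <- geno_matrix(g, loci = data.frame(chrom = "c", pos = 1L, ref = "A", alt = "G"))
  s <- locus_stats(gm)
  expect_equal(s$gd, 0.5)
  expect_equal(s$pic, 0.375)
  expect_equal(s$ho, 1)

  # p = (0.95, 0.05): 10 samples, 1 alt allele
  g2 <- matrix(c(1L, rep(0L, 9)), 10, 1)
  gm2 <- geno_matrix(g2, loci = data.frame(chrom = "c", pos = 1L, ref = "A", alt = "G"))
  s2 <- locus_stats(gm2)
  expect_equal(s2$gd, 0.095)
  expect_equal(s2$pic, 0.0904875)
  expect_equal(s2$maf, 0.05)

  # Ho with a missing genotype: {0/1, 0/0, 0/1, NA} -> 2/3
  g3 <- matrix(c(1L, 0L, 1L, NA), 4, 1)
  gm3 <- geno_matrix(g3, loci = data.frame(chrom = "c", pos = 1L, ref = "A", alt = "G"))
  expect_equal(locus_stats(gm3)$ho, 2 / 3)
})

test_that("locus_stats equals a brute-force recomputation on random loci", {
  gm <- random_geno(12, 1000, miss = 0.1, seed = 31)
  s <- locus_stats(gm)
  want <- oracle_locus_stats(gm$g)
  expect_equal(s$gd, unname(want[, "gd"]))
  expect_equal(s$pic, unname(want[, "pic"]))
  expect_equal(s$ho, unname(want[, "ho"]))
  expect_equal(s$maf, unname(want[, "maf"]))
  # invariants: PIC <= GD, all in [0, 1], MAF <= 0.5
  expect_true(all(s$pic <= s$gd + 1e-12))
  expect_true(all(s$maf <= 0.5))
  # permutation invariance over samples
  perm <- sample(nrow(gm$g))
  gmp <- geno_matrix(gm$g[perm, ], loci = gm$loci, samples = gm$samples[perm])
  expect_equal(locus_stats(gmp)$gd, s$gd)
})

test_that("covariance PCA handles degenerate two-sample and duplicated inputs", {
  g <- rbind(rep(0L, 6), rep(2L, 6))
  gm <- geno_matrix(g, loci = data.frame(
    chrom = "c", pos = 1:6, ref = "A", alt = "G"
  ))
  pc <- pca_covariance(gm)
  expect_equal(pc$prop_var[1], 1)

  g2 <- rbind(g, g)  # duplicated samples: a zero-variance direction exists
  gm2 <- geno_matrix(g2, loci = gm$loci)
  pc2 <- pca_covariance(gm2)
  expect_true(any(pc2$eigenvalues < 1e-12))
  expect_equal(sum(pc2$prop_var), 1)

  expect_error(pca_covariance(geno_matrix(g[1, , drop = FALSE], loci = gm$loci)),
               "2 samples")
})

test_that("PCA scores are sample-order invariant up to component sign", {
  gm <- random_geno(10, 40, miss = 0, seed = 8)
  pc <- pca_covariance(gm)
  perm <- withr::with_seed(9, sample(10))
  gmp <- geno_matrix(gm$g[perm, ], loci = gm$loci, samples = gm$samples[perm])
  pcp <- pca_covariance(gmp)
  for (k in 1:3) {
    a <- pc$scores[perm, k]
    b <- pcp$scores[, k]
    expect_true(isTRUE(all.equal(a, b)) || isTRUE(all.equal(a, -b)))
  }
  expect_equal(sum(pc$prop_var), 1)
})

test_that("allele-sharing distances match hand computation", {
  g <- rbind(c(0L, 1L, 2L, 0L),
             c(0L, 1L, 2L, 0L),
             c(2L, 1L, 0L, NA))
  gm <- geno_matrix(g, loci = data.frame(
    chrom = "c", pos = 1:4, ref = "A", alt = "G"
  ), samples = c("s1", "s2", "s3"))
  d <- distance_matrix(gm)
  expect_equal(d["s1", "s2"], 0)
  # s1 vs s3 on 3 co-called loci: |0-2| + |1-1| + |2-0| = 4 halves over 3 loci
  expect_equal(d["s1", "s3"], (1 + 0 + 1) / 3)
  expect_equal(diag(d), c(s1 = 0, s2 = 0, s3 = 0))
  expect_true(isSymmetric(d))

  # opposite homozygotes at every locus
  g2 <- rbind(rep(0L, 4), rep(2L, 4))
  d2 <- distance_matrix(geno_matrix(g2, loci = gm$loci))
  expect_equal(d2[1, 2], 1)

  # a pair with no co-called locus is undefined
  g3 <- rbind(c(0L, NA), c(NA, 1L))
  expect_warning(
    d3 <- distance_matrix(geno_matrix(g3, loci = gm$loci[1:2, ])),
    "zero co-called"
  )
  expect_true(is.na(d3[1, 2]))
})
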