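test_that("global protein alignment matches an independent affine-gap DP", {
  # identity: no gaps
  aln <- align_proteins_global("MKV", "MKV")
  expect_identical(aln$a, "MKV")
  expect_identical(aln$b, "MKV")

  # one-gap case against the hand-checkable 3x2 DP
  aln <- align_proteins_global("MKV", "MV")
  expect_equal(nchar(aln$a), 3L)
  expect_equal(aln$score, oracle_nw_score("MKV", "MV"))

  # single substitution column
  aln <- align_proteins_global("A", "W")
  expect_identical(c(aln$a, aln$b), c("A", "W"))

  # random short peptides: score equals the oracle score
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(42, {
    for (i in 1:20) {
      a <- paste(sample(aas, sample(3:9, 1), replace = TRUE), collapse = "")
      b <- paste(sample(aas, sample(3:9, 1), replace = TRUE), collapse = "")
      expect_equal(align_proteins_global(a, b)$score, oracle_nw_score(a, b),
                   info = paste(a, b))
    }
  })

  expect_error(align_proteins_global("MK1", "MK"), "non-amino-acid")
  expect_error(align_proteins_global("", "MK"), "empty")
})

test_that("backtranslate maps aligned residues to source codons", {
  cds <- "ATGAAAGTA"  # MKV
  aln <- align_proteins_global("MKV", "MKV")
  caln <- backtranslate(aln, cds, cds)
  expect_equal(nrow(caln), 3L)
  expect_identical(caln$codon_a, c("ATG", "AAA", "GTA"))

  # internal gap in a: the facing codon of b is dropped
  aln2 <- align_proteins_global("MV", "MKV")
  caln2 <- backtranslate(aln2, "ATGGTA", "ATGAAAGTA")
  expect_equal(nrow(caln2), 2L)
  expect_equal(attr(caln2, "n_dropped_gap"), 1L)

  # codon containing N: column dropped and counted
  caln3 <- backtranslate(align_proteins_global("MXV", "MKV"),
                         "ATGAANGTA", "ATGAAAGTA")
  expect_equal(nrow(caln3), 2L)
  expect_equal(attr(caln3, "n_dropped_n"), 1L)

  # terminal stop trimmed; mismatch elsewhere errors with the residue index
  expect_equal(nrow(backtranslate(aln, paste0(cds, "TAA"), cds)), 3L)
  expect_error(backtranslate(aln, "ATGAAACTA", cds), "residue 3")
})

test_that("fourfold-column classification requires shared degeneracy class", {
  expect_true(classify_fourfold_column("GGA", "GGG"))   # Gly family
  expect_false(classify_fourfold_column("GGA", "GAA"))  # 2nd position differs
  expect_false(classify_fourfold_column("ATA", "ATG"))  # Ile/Met not fourfold
  expect_false(classify_fourfold_column("GGN", "GGA"))  # N never classified
  # all eight families classify against themselves
  fams <- c("CTA", "GTC", "TCG", "CCT", "ACA", "GCC", "CGG", "GGT")
  expect_true(all(classify_fourfold_column(fams, fams)))
})

test_that("transversions exchange a purine with a pyrimidine", {
  expect_false(is_transversion("A", "G"))  # transition
  expect_false(is_transversion("C", "C"))  # identity
  expect_true(all(is_transversion(c("A", "A", "G", "G"), c("C", "T", "C", "T"))))
  expect_true(all(is_transversion(c("C", "T"), c("G", "A"))))
})

test_that("4DTv statistic and saturation correction behave as specified", {
  mk_aln <- function(codons_a, codons_b) {
    structure(tibble::tibble(codon_a = codons_a, codon_b = codons_b),
              class = c("codon_alignment", "tbl_df", "tbl", "data.frame"))
  }
  # 100 fourfold sites, no transversions
  a <- rep("GGA", 100)
  r <- fourdtv(mk_aln(a, a))
  expect_equal(r$p_raw, 0)
  expect_equal(r$d_corr, 0)

  # p_raw = 0.1 corrects to -0.5 log(0.8)
  b <- c(rep("GGC", 10), rep("GGA", 90))  # A->C transversion at 10 sites
  r <- fourdtv(mk_aln(a, b))
  expect_equal(r$p_raw, 0.1)
  expect_equal(r$d_corr, 0.1115718, tolerance = 1e-6)

  # saturation boundary: p_raw >= 0.5 is undefined
  b <- c(rep("GGC", 50), rep("GGA", 50))
  r <- fourdtv(mk_aln(a, b))
  expect_equal(r$p_raw, 0.5)
  expect_identical(r$status, "saturated")
  expect_true(is.na(r$d_corr))

  # too few comparable sites
  r <- fourdtv(mk_aln(rep("GGA", 5), rep("GGA", 5)), min_4d = 10)
  expect_identical(r$status, "short")

  # symmetry: swapping the sequences changes nothing
  withr::with_seed(7, {
    ca <- paste0(sample(c("GG", "CC", "AC"), 60, TRUE), sample(c("A", "C", "G", "T"), 60, TRUE))
    cb <- paste0(substr(ca, 1, 2), sample(c("A", "C", "G", "T"), 60, TRUE))
  })
  r1 <- fourdtv(mk_aln(ca, cb))
  r2 <- fourdtv(mk_aln(cb, ca))
  expect_equal(r1[c("n_4d", "n_tv", "p_raw", "d_corr")],
               r2[c("n_4d", "n_tv", "p_raw", "d_corr")])
})

test_that("the correction is monotone, dominates p, and hky reduces at equal composition", {
  p <- seq(0, 0.49, by = 0.01)
  d <- correct_4dtv(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
  expect_equal(d[p == 0], 0)
  expect_true(all(d[-1] > p[-1]))
  expect_equal(correct_4dtv(p, method = "hky", g_r = 0.5, g_y = 0.5), d)
  expect_true(is.na(correct_4dtv(0.5)))
})

test_that("mean raw 4DTv over simulated alignments recovers the generating rate", {
  # two-state substitution at fourfold third positions with P(transversion) = p*
  p_star <- 0.15
  n_sites <- 400
  n_rep <- 25
  withr::with_seed(11, {
    p_hat <- replicate(n_rep, {
      pre <- sample(wgdpop:::FOURFOLD_PREFIXES, n_sites, TRUE)
      third <- sample(c("A", "C", "G", "T"), n_sites, TRUE)
      ca <- paste0(pre, third)
      tv <- runif(n_sites) < p_star
      third_b <- ifelse(
        tv,
        vapply(third, function(x) sample(wgdpop:::TRANSVERSIONS[[x]], 1), ""),
        third
      )
      r <- fourdtv(structure(tibble::tibble(codon_a = ca, codon_b = paste0(pre, third_b)),
                             class = c("codon_alignment", "tbl_df", "tbl", "data.frame")))
      r$p_raw
    })
  })
  se <- sqrt(p_star * (1 - p_star) / (n_sites * n_rep))
  expect_lt(abs(mean(p_hat) - p_star), 3 * se)
})

test_that("fourdtv_pair runs the full translate-align-backtranslate path", {
  cds_a <- "ATGGGAGGAGGAGGAGGAGGAGGAGGAGGAGGATAA"
  cds_b <- "ATGGGCGGAGGAGGAGGAGGAGGAGGAGGAGGATAA"
  r <- fourdtv_pair(cds_a, cds_b, id_a = "x", id_b = "y")
  expect_identical(r$id_a, "x")
  expect_equal(r$n_4d, 10L)
  expect_equal(r$n_tv, 1L)
})
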