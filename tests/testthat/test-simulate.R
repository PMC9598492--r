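test_that("the duplicated-genome simulator is reproducible from its spec", {
  spec <- wgd_sim_spec(n_chromosomes = 2, genes_per_chromosome = 12,
                       codons_per_gene = 40, seed = 5)
  s1 <- simulate_wgd_genome(spec)
  s2 <- simulate_wgd_genome(spec)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$cds, s2$cds)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$hits, s2$hits)
})

test_that("genome layout, catalog and CDS agree", {
  s <- simulate_wgd_genome(wgd_sim_spec(
    n_chromosomes = 2, genes_per_chromosome = 12, codons_per_gene = 40,
    seed = 2
  ))
  expect_setequal(names(s$genome), c("chr01", "chr01d", "chr02", "chr02d"))
  cds <- extract_cds(s$catalog, s$genome)
  expect_identical(unname(cds[names(s$cds)]), unname(s$cds))
  expect_true(all(s$catalog$valid))
  # truth counts are consistent with their realised proportions
  with(s$truth, expect_equal(p_realized, n_tv / n_4d))
})

test_that("zero divergence means identical homeologs and full-length blocks", {
  s <- simulate_wgd_genome(wgd_sim_spec(
    n_chromosomes = 2, genes_per_chromosome = 12, codons_per_gene = 40,
    p_tv = 0, ts_tv_ratio = 0, seed = 1
  ))
  expect_true(all(s$truth$p_realized == 0))
  expect_identical(unname(s$cds[s$truth$gene_a]), unname(s$cds[s$truth$gene_b]))
  blocks <- suppressMessages(synteny_blocks(s$hits, s$catalog))
  expect_equal(nrow(blocks), 2L)
  expect_equal(blocks$n_anchors, c(12L, 12L))
})

test_that("heavy gene loss leaves runs too short to chain", {
  s <- suppressWarnings(simulate_wgd_genome(wgd_sim_spec(
    n_chromosomes = 4, genes_per_chromosome = 12, codons_per_gene = 30,
    gene_loss_rate = 0.9, seed = 3
  )))
  expect_warning(
    simulate_wgd_genome(wgd_sim_spec(
      n_chromosomes = 1, genes_per_chromosome = 12, codons_per_gene = 30,
      gene_loss_rate = 0.9, seed = 3
    )),
    "below the default block threshold"
  )
  blocks <- suppressMessages(synteny_blocks(s$hits, s$catalog))
  expect_equal(nrow(blocks), 0L)
})

test_that("realised transversion proportions follow the target rate", {
  s <- simulate_wgd_genome(wgd_sim_spec(
    n_chromosomes = 3, genes_per_chromosome = 15, codons_per_gene = 120,
    p_tv = 0.2, seed = 7
  ))
  n4 <- sum(s$truth$n_4d)
  p_hat <- sum(s$truth$n_tv) / n4
  expect_lt(abs(p_hat - 0.2), 3 * sqrt(0.2 * 0.8 / n4))
})

test_that("the admixed-genotype simulator has the declared structure", {
  spec <- pop_sim_spec(n_individuals = c(15, 20), n_loci = 300,
                       missing_rate = 0.1, seed = 23)
  sim <- simulate_admixed_genotypes(spec)
  expect_equal(dim(sim$gm$g), c(35L, 300L))
  expect_equal(unname(rowSums(sim$Q)), rep(1, 35))
  expect_true(all(is.na(sim$gm$g[is.na(sim$gm$dp)])))
  # missingness close to its law (mask rate + zero-depth mass)
  expect_gt(mean(is.na(sim$gm$g)), 0.05)
  expect_lt(mean(is.na(sim$gm$g)), 0.2)
  # reproducible
  sim2 <- simulate_admixed_genotypes(spec)
  expect_identical(sim$gm$g, sim2$gm$g)
  expect_identical(sim$Q, sim2$Q)
})

test_that("half-missing panels are wiped out by the missingness filter", {
  sim <- simulate_admixed_genotypes(pop_sim_spec(
    n_individuals = c(10, 10), n_loci = 200, missing_rate = 0.5, seed = 29
  ))
  # P(locus keeps < 10% missing) is a tiny binomial tail at rate ~0.5
  expect_error(suppressMessages(apply_filters(sim$gm)), "all loci removed")
})

test_that("toy fixtures are byte-identical across invocations", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- make_toy_fixtures(d1)
  p2 <- make_toy_fixtures(d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]), info = nm)
  }
})

test_that("simulated VCF survives a write/read round trip", {
  sim <- simulate_admixed_genotypes(pop_sim_spec(
    n_individuals = c(5, 5), n_loci = 50, seed = 3
  ))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$gm, f)
  back <- read_vcf(f)
  expect_equal(unname(back$g), unname(sim$gm$g))
  expect_equal(unname(back$dp), unname(sim$gm$dp))
  expect_equal(back$loci$pos, sim$gm$loci$pos)
})
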