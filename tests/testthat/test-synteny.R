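# 12 genes on each of two chromosomes, one hit per (a_i, b_i)
toy_catalog <- function() {
  gene_catalog(tibble::tibble(
    gene_id = c(sprintf("a%02d", 1:12), sprintf("b%02d", 1:12)),
    chrom = rep(c("chrA", "chrB"), each = 12),
    strand = "+",
    cds = rep(lapply(seq(1, 340, by = 30),
                     function(s) data.frame(start = s, end = s + 29L)), 2)
  ))
}

toy_hits <- function(idx = 1:12, rank_b = idx) {
  tibble::tibble(
    query_id = sprintf("a%02d", idx), subject_id = sprintf("b%02d", rank_b),
    percent_identity = 100, alignment_length = 30, mismatches = 0,
    gap_opens = 0, q_start = 1, q_end = 30, s_start = 1, s_end = 30,
    e_value = 0, bit_score = 100 + idx
  )
}

test_that("tandem arrays collapse to their best-scoring representative", {
  cat <- toy_catalog()
  # a01 and a02 (ranks 0,1) hit each other; a02 carries the higher score
  h <- tibble::tibble(
    query_id = c("a01", "a02", "a02"), subject_id = c("a02", "a01", "b05"),
    percent_identity = 100, alignment_length = 30, mismatches = 0,
    gap_opens = 0, q_start = 1, q_end = 30, s_start = 1, s_end = 30,
    e_value = 0, bit_score = c(100, 100, 300)
  )
  out <- suppressMessages(collapse_tandem(h, cat))
  expect_identical(attr(out, "removed_genes"), "a01")
  expect_equal(nrow(out), 1L)  # the representative a02 keeps its b05 hit

  # rank gap 4 > 1: both kept
  h2 <- h[1, ]
  h2$subject_id <- "a06"
  expect_equal(nrow(collapse_tandem(h2, cat)), 1L)

  # three adjacent mutually-hitting genes form one array component
  h3 <- tibble::tibble(
    query_id = c("a01", "a02"), subject_id = c("a02", "a03"),
    percent_identity = 100, alignment_length = 30, mismatches = 0,
    gap_opens = 0, q_start = 1, q_end = 30, s_start = 1, s_end = 30,
    e_value = 0, bit_score = c(100, 120)
  )
  out3 <- suppressMessages(collapse_tandem(h3, cat))
  expect_setequal(attr(out3, "removed_genes"), c("a01", "a03"))
})

test_that("build_anchors attaches ranks and dedupes reciprocal intra hits", {
  cat <- toy_catalog()
  h <- dplyr::bind_rows(
    toy_hits(),
    toy_hits() |> dplyr::mutate(query_id = subject_id,
                                subject_id = sprintf("a%02d", 1:12))
  )
  anc <- build_anchors(h, cat)
  expect_equal(nrow(anc), 12L)  # 24 reciprocal rows -> 12 anchors
  expect_true(all(anc$chrom_a == "chrA" & anc$chrom_b == "chrB"))
  expect_equal(anc$rank_a, 0:11)

  expect_equal(nrow(build_anchors(toy_hits()[0, ], cat)), 0L)

  h_bad <- toy_hits(1)
  h_bad$subject_id <- "nosuchgene"
  expect_warning(anc2 <- build_anchors(h_bad, cat), "absent from the catalog")
  expect_equal(nrow(anc2), 0L)
})

test_that("chaining finds the single full-length block on the 12-anchor toy", {
  cat <- toy_catalog()
  blocks <- chain_anchors(build_anchors(toy_hits(), cat))
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$n_anchors, 12L)
  expect_identical(blocks$orientation, "same")
  expect_silent(validate_blocks(blocks))

  # 9 anchors: below the ten-gene threshold
  expect_equal(nrow(chain_anchors(build_anchors(toy_hits(1:9), cat))), 0L)
})

test_that("a gap of six intervening genes splits the chain", {
  # anchors at rank pairs {0..4} and {11..15} on both sides: the jump from
  # rank 4 to 11 leaves 6 intervening genes, one more than allowed
  anc <- tibble::tibble(
    gene_a = sprintf("x%02d", 1:10), gene_b = sprintf("y%02d", 1:10),
    chrom_a = "A", chrom_b = "B",
    rank_a = c(0:4, 11:15), rank_b = c(0:4, 11:15), bit_score = 100
  )
  expect_equal(nrow(chain_anchors(anc, min_block_genes = 10L)), 0L)
  # each fragment is found once the threshold admits it
  expect_equal(nrow(chain_anchors(anc, min_block_genes = 5L)), 2L)
})

test_that("chaining equals exhaustive enumeration on random small instances", {
  for (seed in 1:30) {
    anc <- random_anchor_instance(seed, n_max = 12)
    blocks <- chain_anchors(anc, min_block_genes = 1L, max_intervening = 5L)
    got <- blocks[order(-blocks$n_anchors, -blocks$score)[1], ]
    want <- rbind(
      oracle_best_chain(anc$rank_a, anc$rank_b, anc$bit_score, "same", 5),
      oracle_best_chain(anc$rank_a, anc$rank_b, anc$bit_score, "inverted", 5)
    )
    best <- want[order(-want[, "count"], -want[, "score"]), , drop = FALSE][1, ]
    expect_equal(got$n_anchors, unname(best["count"]), info = paste("seed", seed))
    expect_equal(got$score, unname(best["score"]), info = paste("seed", seed))
  }
})

test_that("reversing side-B gene order turns same-orientation blocks inverted", {
  cat <- toy_catalog()
  anc <- build_anchors(toy_hits(), cat)
  anc_rev <- dplyr::mutate(anc, rank_b = max(rank_b) - rank_b)
  b1 <- chain_anchors(anc)
  b2 <- chain_anchors(anc_rev)
  expect_identical(b2$orientation, "inverted")
  expect_setequal(b2$anchors[[1]]$gene_a, b1$anchors[[1]]$gene_a)
})

test_that("homeolog pairs are deduplicated across blocks and flagged", {
  cat <- toy_catalog()
  blocks <- chain_anchors(build_anchors(toy_hits(), cat))
  pairs <- homeolog_pairs(blocks)
  expect_equal(nrow(pairs), 12L)
  expect_true(all(pairs$n_blocks == 1L))

  # duplicate the block: same pairs reported once, flagged n_blocks = 2
  twice <- dplyr::bind_rows(blocks, blocks)
  p2 <- homeolog_pairs(twice)
  expect_equal(nrow(p2), 12L)
  expect_true(all(p2$n_blocks == 2L))
  expect_equal(nrow(homeolog_pairs(blocks[0, ])), 0L)
})

test_that("inter-genomic self-comparison yields one full-length block per chromosome", {
  cat <- toy_catalog()
  # identity pairs a_i -> a_i ... using two copies of the same catalog
  h <- toy_hits()
  h$subject_id <- h$query_id
  blocks <- synteny_blocks(h, cat, catalog_b = cat, min_block_genes = 10L)
  expect_equal(nrow(blocks), 1L)  # only chrA has 12 identity anchors here
  expect_equal(blocks$n_anchors, 12L)
  expect_identical(blocks$orientation, "same")
})
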