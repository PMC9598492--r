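STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

# non-stop codons outside the fourfold-degenerate families
non4d_codons <- function() {
  cc <- all_codons()
  cc[!is_fourfold_codon(cc) & !cc %in% STOP_CODONS]
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

#' Specification for the duplicated-genome simulator
#'
#' Defaults emulate a genome that underwent one whole-genome duplication:
#' every chromosome exists in two copies with conserved gene order, and
#' homeolog pairs have accumulated synonymous divergence at
#' fourfold-degenerate third codon positions with expected transversion
#' proportion `p_tv`.
#'
#' @param n_chromosomes number of ancestral chromosomes (default 20)
#' @param genes_per_chromosome genes per ancestral chromosome (default 60)
#' @param codons_per_gene codons per gene (default 200)
#' @param p_tv expected transversion proportion at fourfold sites between
#'   homeologs, in `[0, 0.5)` (default 0.12)
#' @param ts_tv_ratio transition events per transversion event (default 2)
#' @param gene_loss_rate fraction of duplicated genes deleted (default 0)
#' @param local_shuffle_rate adjacent-swap rate on the duplicated copy's
#'   gene order (default 0)
#' @param fourfold_frac fraction of codon positions drawn from
#'   fourfold-degenerate families (default 0.6)
#' @param seed integer seed
#' @return a `wgd_sim_spec` list
#' @export
wgd_sim_spec <- function(n_chromosomes = 20L, genes_per_chromosome = 60L,
                         codons_per_gene = 200L, p_tv = 0.12,
                         ts_tv_ratio = 2, gene_loss_rate = 0,
                         local_shuffle_rate = 0, fourfold_frac = 0.6,
                         seed = 1L) {
  stopifnot(p_tv >= 0, p_tv < 0.5,
            gene_loss_rate >= 0, gene_loss_rate <= 1,
            local_shuffle_rate >= 0, local_shuffle_rate <= 1,
            p_tv * (1 + ts_tv_ratio) <= 1)
  structure(as.list(environment()), class = "wgd_sim_spec")
}

#' Simulate a genome carrying a whole-genome duplication
#'
#' Ancestral genes are random codon sequences rich in fourfold-degenerate
#' families; each chromosome is then duplicated and, at every
#' fourfold-degenerate codon of each homeolog pair, the duplicate's third
#' base receives a transversion with probability `p_tv` and a transition
#' with probability `ts_tv_ratio * p_tv` (protein sequences stay
#' identical). A fraction of duplicates is deleted and local adjacent
#' swaps perturb the duplicate's gene order. The homology table lists the
#' surviving true homeolog pairs; the truth table records each pair's
#' realised fourfold-site and transversion counts.
#'
#' @param spec a [wgd_sim_spec()]
#' @return list: `genome` (named sequences), `catalog` ([gene_catalog()]),
#'   `cds` (named CDS), `hits` (homology tibble), `truth` (tibble
#'   `gene_a`, `gene_b`, `n_4d`, `n_tv`, `p_realized`), `spec`
#' @export
simulate_wgd_genome <- function(spec) {
  stopifnot(inherits(spec, "wgd_sim_spec"))
  n4 <- non4d_codons()
  withr::with_seed(spec$seed, {
    genes <- list()   # per gene: list(id, chrom, strand, cds)
    truth <- list()
    hit_rows <- list()
    for (ci in seq_len(spec$n_chromosomes)) {
      chrom_a <- sprintf("chr%02d", ci)
      chrom_b <- sprintf("chr%02dd", ci)
      a_list <- list()
      b_list <- list()
      for (gi in seq_len(spec$genes_per_chromosome)) {
        id_a <- sprintf("g%02d_%03d", ci, gi)
        id_b <- paste0(id_a, "d")
        use4d <- stats::runif(spec$codons_per_gene) < spec$fourfold_frac
        codons <- character(spec$codons_per_gene)
        codons[use4d] <- paste0(
          sample(FOURFOLD_PREFIXES, sum(use4d), replace = TRUE),
          sample(c("A", "C", "G", "T"), sum(use4d), replace = TRUE)
        )
        codons[!use4d] <- sample(n4, sum(!use4d), replace = TRUE)
        # duplicate: synonymous divergence at fourfold third positions
        dup <- codons
        i4 <- which(is_fourfold_codon(codons))
        u <- stats::runif(length(i4))
        tv <- u < spec$p_tv
        ts <- !tv & u < spec$p_tv * (1 + spec$ts_tv_ratio)
        for (j in which(tv)) {
          cd <- dup[i4[j]]
          third <- substr(cd, 3, 3)
          substr(dup[i4[j]], 3, 3) <- sample(TRANSVERSIONS[[third]], 1)
        }
        for (j in which(ts)) {
          cd <- dup[i4[j]]
          substr(dup[i4[j]], 3, 3) <- TRANSITION[[substr(cd, 3, 3)]]
        }
        a_list[[gi]] <- list(id = id_a, chrom = chrom_a,
                             strand = sample(c("+", "-"), 1),
                             cds = paste(codons, collapse = ""))
        b_list[[gi]] <- list(id = id_b, chrom = chrom_b,
                             strand = sample(c("+", "-"), 1),
                             cds = paste(dup, collapse = ""))
        truth[[length(truth) + 1L]] <- tibble(
          gene_a = id_a, gene_b = id_b,
          n_4d = length(i4), n_tv = sum(tv),
          p_realized = sum(tv) / max(length(i4), 1)
        )
      }
      # gene loss on the duplicated copy
      lost <- stats::runif(length(b_list)) < spec$gene_loss_rate
      b_list <- b_list[!lost]
      # local shuffling of the duplicate's gene order
      n_swaps <- round(spec$local_shuffle_rate * length(b_list))
      if (n_swaps > 0 && length(b_list) > 1) {
        for (s in seq_len(n_swaps)) {
          i <- sample(length(b_list) - 1L, 1)
          b_list[c(i, i + 1L)] <- b_list[c(i + 1L, i)]
        }
      }
      genes <- c(genes, a_list, b_list)
    }

    # lay genes on chromosomes with random intergenic spacers
    gene_tbl <- list()
    seqs <- character(0)
    by_chrom <- split(genes, vapply(genes, `[[`, "", "chrom"))
    for (chrom in names(by_chrom)) {
      pos <- 1L
      chunks <- character(0)
      for (g in by_chrom[[chrom]]) {
        spacer <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                        collapse = "")
        chunks <- c(chunks, spacer)
        pos <- pos + 30L
        len <- nchar(g$cds)
        chunks <- c(chunks, if (g$strand == "+") g$cds else revcomp(g$cds))
        gene_tbl[[length(gene_tbl) + 1L]] <- tibble(
          gene_id = g$id, chrom = chrom, strand = g$strand,
          cds = list(data.frame(start = pos, end = pos + len - 1L))
        )
        pos <- pos + len
      }
      seqs[chrom] <- paste(chunks, collapse = "")
    }
    catalog <- gene_catalog(bind_rows(gene_tbl))
    truth <- bind_rows(truth)
    surviving <- truth$gene_b %in% catalog$gene_id
    truth$surviving <- surviving

    hits <- tibble(
      query_id = truth$gene_a[surviving],
      subject_id = truth$gene_b[surviving],
      percent_identity = 100 * (1 - truth$p_realized[surviving] / 3),
      alignment_length = spec$codons_per_gene * 3,
      mismatches = 0, gap_opens = 0,
      q_start = 1, q_end = spec$codons_per_gene * 3,
      s_start = 1, s_end = spec$codons_per_gene * 3,
      e_value = 0,
      bit_score = round(stats::runif(sum(surviving), 800, 1200), 1)
    )
  })
  min_needed <- 10L
  if (spec$gene_loss_rate > 0 &&
      spec$genes_per_chromosome * (1 - spec$gene_loss_rate) < min_needed) {
    warn("expected surviving genes per chromosome below the default block threshold")
  }
  cds <- stats::setNames(
    vapply(genes, `[[`, "", "cds"),
    vapply(genes, `[[`, "", "id")
  )
  list(genome = seqs, catalog = catalog, cds = cds, hits = hits,
       truth = truth, spec = spec)
}

#' Write a simulated duplicated genome to standard files
#'
#' @param sim result of [simulate_wgd_genome()]
#' @param dir output directory (created if needed)
#' @return named paths (`fasta`, `gff3`, `hits`, `truth`), invisibly
#' @export
write_wgd_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "genes.gff3"),
    hits = file.path(dir, "hits.tsv"),
    truth = file.path(dir, "truth_pairs.tsv")
  )
  write_fasta(sim$genome, paths[["fasta"]])
  write_gff3(sim$catalog, paths[["gff3"]])
  write_homology_table(sim$hits, paths[["hits"]])
  readr::write_tsv(sim$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}

#' Specification for the admixed-genotype simulator
#'
#' Defaults mirror a RAD-seq diversity panel: 85 accessions from two
#' ancestral populations (40 + 45), ~2500 biallelic loci, moderate
#' differentiation (Fst 0.1), negative-binomial depths around 60x and a
#' few percent missing calls, so the depth/missingness/MAF filter cascade
#' is exercised.
#'
#' @param n_individuals individuals per population (default `c(40, 45)`)
#' @param n_loci number of biallelic loci (default 2500)
#' @param fst differentiation of each population from the common ancestor,
#'   in (0, 1) (default 0.1)
#' @param admixture_alpha Dirichlet parameters for an individual's ancestry:
#'   `alpha_own` for its population of origin, `alpha_other` for each other
#'   population (default 5 and 0.5, i.e. mostly-assigned individuals with
#'   visible admixture)
#' @param depth_mean,depth_dispersion negative-binomial depth law
#'   (default mean 60, size 8)
#' @param missing_rate extra fraction of genotypes masked missing
#'   (default 0.03)
#' @param seed integer seed
#' @return a `pop_sim_spec` list
#' @export
pop_sim_spec <- function(n_individuals = c(40L, 45L), n_loci = 2500L,
                         fst = 0.1, admixture_alpha = c(5, 0.5),
                         depth_mean = 60, depth_dispersion = 8,
                         missing_rate = 0.03, seed = 13L) {
  stopifnot(fst > 0, fst < 1, n_loci > 0, length(n_individuals) >= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "pop_sim_spec")
}

#' Simulate admixed genotypes under the Balding-Nichols model
#'
#' Ancestral allele frequencies are Uniform(0.1, 0.9); each population's
#' frequencies are Beta-distributed around the ancestral value with
#' variance `p (1 - p) Fst` (Balding-Nichols). Individual ancestry
#' proportions are Dirichlet draws biased toward the population of origin;
#' alt-allele counts are Binomial(2, Q P). Depths are negative binomial;
#' genotypes with zero depth and an extra `missing_rate` fraction are
#' missing.
#'
#' @param spec a [pop_sim_spec()]
#' @return list: `gm` ([geno_matrix()]), `Q` (truth ancestry), `P` (truth
#'   cluster frequencies), `origin` (population of origin per sample),
#'   `spec`
#' @export
simulate_admixed_genotypes <- function(spec) {
  stopifnot(inherits(spec, "pop_sim_spec"))
  K <- length(spec$n_individuals)
  n <- sum(spec$n_individuals)
  L <- spec$n_loci
  withr::with_seed(spec$seed, {
    p0 <- stats::runif(L, 0.1, 0.9)
    shape_scale <- (1 - spec$fst) / spec$fst
    P <- t(vapply(seq_len(K), function(k) {
      stats::rbeta(L, p0 * shape_scale, (1 - p0) * shape_scale)
    }, numeric(L)))
    origin <- rep(seq_len(K), times = spec$n_individuals)
    alpha <- matrix(spec$admixture_alpha[2], n, K)
    alpha[cbind(seq_len(n), origin)] <- spec$admixture_alpha[1]
    Q <- matrix(stats::rgamma(n * K, shape = alpha), n, K)
    Q <- Q / rowSums(Q)
    FF <- Q %*% P
    g <- matrix(stats::rbinom(n * L, 2, FF), n, L)
    dp <- matrix(stats::rnbinom(n * L, mu = spec$depth_mean,
                                size = spec$depth_dispersion), n, L)
    miss <- matrix(stats::runif(n * L) < spec$missing_rate, n, L) | dp == 0
    g[miss] <- NA_integer_
    dp_na <- dp
    dp_na[miss] <- NA_real_
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, L, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  })
  samples <- sprintf("acc%03d", seq_len(n))
  loci <- tibble(chrom = "chr01", pos = 137L * seq_len(L),
                 ref = ref, alt = unname(alt))
  gm <- geno_matrix(g, dp = dp_na, loci = loci, samples = samples)
  dimnames(Q) <- list(samples, paste0("K", seq_len(K)))
  list(gm = gm, Q = Q, P = P, origin = origin, spec = spec)
}

#' Deterministic toy fixtures used by the documented examples
#'
#' Writes byte-identical tiny files on every invocation: a 12-gene
#' two-chromosome chaining toy (FASTA + GFF3 + hits), a two-part
#' minus-strand splice gene, and a 10-sample x 5-locus filter-cascade VCF
#' in which one sample's depths are {10, 30, 250, 100, 60} and locus 2
#' carries exactly one alt allele (MAF 0.05).
#'
#' @param dir output directory (created if needed)
#' @return named list of file paths
#' @export
make_toy_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  # --- chaining toy: chrA/chrB each 12 genes, anchors (a_i, b_i) ---
  codon_bank <- c("GCA", "GGC", "CTG", "ACA", "TCG", "CCT", "GTA", "CGC")
  toy_cds <- vapply(seq_len(12), function(i) {
    paste(rep(codon_bank[(i %% 8) + 1], 10), collapse = "")
  }, "")
  mk_chrom <- function(prefix) {
    pos <- 1L
    rows <- list()
    chunks <- character(0)
    for (i in seq_len(12)) {
      chunks <- c(chunks, "ACGTACGTAC")  # 10-nt spacer
      pos <- pos + 10L
      chunks <- c(chunks, toy_cds[i])
      rows[[i]] <- tibble(
        gene_id = sprintf("%s%02d", prefix, i), chrom = paste0("chr", toupper(prefix)),
        strand = "+",
        cds = list(data.frame(start = pos, end = pos + nchar(toy_cds[i]) - 1L))
      )
      pos <- pos + nchar(toy_cds[i])
    }
    list(seq = paste(chunks, collapse = ""), rows = bind_rows(rows))
  }
  ca <- mk_chrom("a")
  cb <- mk_chrom("b")
  toy_catalog <- gene_catalog(bind_rows(ca$rows, cb$rows))
  toy_genome <- c(chrA = ca$seq, chrB = cb$seq)
  hits <- tibble(
    query_id = sprintf("a%02d", 1:12), subject_id = sprintf("b%02d", 1:12),
    percent_identity = 100, alignment_length = 30, mismatches = 0,
    gap_opens = 0, q_start = 1, q_end = 30, s_start = 1, s_end = 30,
    e_value = 0, bit_score = seq(100, 210, by = 10)
  )
  paths <- list(
    chain_fasta = file.path(dir, "chain_toy.fa"),
    chain_gff3 = file.path(dir, "chain_toy.gff3"),
    chain_hits = file.path(dir, "chain_toy_hits.tsv"),
    splice_fasta = file.path(dir, "splice_toy.fa"),
    splice_gff3 = file.path(dir, "splice_toy.gff3"),
    filter_vcf = file.path(dir, "filter_toy.vcf")
  )
  write_fasta(toy_genome, paths$chain_fasta)
  write_gff3(toy_catalog, paths$chain_gff3)
  write_homology_table(hits, paths$chain_hits)

  # --- minus-strand splice gene: CDS parts (31,39) then (11,19) ---
  # genomic: positions 11..19 and 31..39 of a fixed 50-nt sequence
  splice_seq <- c(sp1 = "AAAAAAAAAACATTGGCATAAAAAAAAAAACCGGTTAAGAAAAAAAAAAA")
  splice_cat <- gene_catalog(tibble(
    gene_id = "ms1", chrom = "sp1", strand = "-",
    cds = list(data.frame(start = c(11L, 31L), end = c(19L, 39L)))
  ))
  write_fasta(splice_seq, paths$splice_fasta)
  write_gff3(splice_cat, paths$splice_gff3)

  # --- filter-cascade VCF: 10 samples x 5 loci ---
  g <- matrix(0L, 10, 5)
  dp <- matrix(60, 10, 5)
  dp[1, ] <- c(10, 30, 250, 100, 60)   # depths straddling [20, 200]
  g[2, 1] <- NA_integer_               # explicit missing call at locus 1
  dp[2, 1] <- NA_real_
  g[3, 2] <- 1L                        # locus 2: single alt allele, MAF 0.05
  g[, 4] <- c(0L, 1L, 1L, 2L, 0L, 1L, 0L, 2L, 1L, 0L)  # polymorphic, kept
  g[, 5] <- c(2L, 2L, 1L, 0L, 0L, 1L, 1L, 0L, 2L, 1L)  # polymorphic, kept
  gm <- geno_matrix(
    g, dp = dp,
    loci = tibble(chrom = "chr01", pos = c(100L, 200L, 300L, 400L, 500L),
                  ref = c("A", "C", "G", "T", "A"),
                  alt = c("G", "T", "A", "C", "C")),
    samples = sprintf("S%02d", 1:10)
  )
  write_vcf(gm, paths$filter_vcf)
  paths
}
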