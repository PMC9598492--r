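#' Build and validate a pipeline run configuration
#'
#' Houses every tunable of the two analysis tracks. Defaults are the
#' stated operating points of the method: homology e-value cutoff 1e-10,
#' blocks of at least 10 colinear genes with fewer than six intervening
#' genes, per-genotype depth 20-200x, MAF > 0.05, missing fraction < 10%,
#' admixture over K = 1..4 with 5 replicate fits.
#'
#' @param genome_fasta,gff3,hits paths for the duplication track
#' @param vcf path for the population track
#' @param out_dir output directory for stage artifacts
#' @param max_evalue homology e-value cutoff
#' @param min_block_genes,max_intervening colinearity criteria
#' @param min_4d minimum comparable fourfold sites per pair
#' @param correction 4DTv correction method
#' @param dp_min,dp_max,maf_min,max_missing SNP filter cascade
#' @param fourfold_only restrict loci to fourfold-degenerate coding sites
#'   (requires `gff3` and `genome_fasta`)
#' @param k_range,n_replicates admixture model-selection grid
#' @param seed master seed for all randomised stages
#' @return a validated `run_config` list
#' @export
run_config <- function(genome_fasta = NULL, gff3 = NULL, hits = NULL,
                       vcf = NULL, out_dir = tempfile("wgdpop_run_"),
                       max_evalue = 1e-10, min_block_genes = 10L,
                       max_intervening = 5L, min_4d = 10L,
                       correction = "saturation",
                       dp_min = 20, dp_max = 200, maf_min = 0.05,
                       max_missing = 0.10, fourfold_only = FALSE,
                       k_range = 1:4, n_replicates = 5L, seed = 1L) {
  cfg <- as.list(environment())
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  if (cfg$dp_min > cfg$dp_max) abort("config error: dp_min exceeds dp_max")
  if (cfg$maf_min < 0 || cfg$maf_min >= 0.5) abort("config error: maf_min outside [0, 0.5)")
  if (cfg$max_missing <= 0 || cfg$max_missing > 1) abort("config error: max_missing outside (0, 1]")
  if (cfg$min_block_genes < 1) abort("config error: min_block_genes < 1")
  if (cfg$max_intervening < 0) abort("config error: max_intervening < 0")
  if (cfg$max_evalue < 0) abort("config error: max_evalue < 0")
  if (isTRUE(cfg$fourfold_only) && (is.null(cfg$gff3) || is.null(cfg$genome_fasta))) {
    abort("config error: fourfold_only requires gff3 and genome_fasta")
  }
  invisible(TRUE)
}

#' Write / read a run configuration as JSON (lossless round trip)
#' @param cfg a [run_config()]
#' @param path JSON path
#' @return `path` / the restored `run_config`
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$k_range <- as.integer(raw$k_range)
  do.call(run_config, raw)
}

manifest_json <- function(cfg, stages, path) {
  jsonlite::write_json(
    list(
      package = "wgdpop",
      version = as.character(utils::packageVersion("wgdpop")),
      seed = cfg$seed,
      parameters = unclass(cfg)[setdiff(names(cfg), "out_dir")],
      stages = stages
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
}

flatten_blocks <- function(blocks) {
  blocks %>% select(-"anchors")
}

# CIRCOS-style link coordinates from block rank spans
block_links <- function(blocks, catalog) {
  if (nrow(blocks) == 0) {
    return(tibble(chrom_a = character(0), start_a = integer(0),
                  end_a = integer(0), chrom_b = character(0),
                  start_b = integer(0), end_b = integer(0)))
  }
  span <- function(chrom, r1, r2) {
    genes <- catalog[catalog$chrom == chrom &
                       catalog$rank >= min(r1, r2) &
                       catalog$rank <= max(r1, r2), ]
    c(min(genes$gene_start), max(genes$gene_end))
  }
  purrr::map_dfr(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    sa <- span(b$chrom_a, b$start_a, b$end_a)
    sb <- span(b$chrom_b, b$start_b, b$end_b)
    tibble(chrom_a = b$chrom_a, start_a = sa[1], end_a = sa[2],
           chrom_b = b$chrom_b, start_b = sb[1], end_b = sb[2])
  })
}

#' Run the whole-genome-duplication track
#'
#' Genome + annotation + homology hits -> tandem collapse -> anchor
#' chaining -> homeolog pairs -> 4DTv distribution -> peak report.
#' Stage artifacts (TSV/JSON) and a manifest are written to
#' `config$out_dir`.
#'
#' @param config a [run_config()] with `genome_fasta`, `gff3`, `hits` set
#' @return list: `blocks`, `pairs`, `distribution`, `peaks` (NULL when too
#'   few pairs for density estimation), `paths`
#' @export
run_wgd_track <- function(config) {
  validate_config(config)
  inputs <- c(genome_fasta = config$genome_fasta, gff3 = config$gff3,
              hits = config$hits)
  if (length(inputs) < 3 || any(!file.exists(inputs))) {
    missing <- if (length(inputs) < 3) {
      setdiff(c("genome_fasta", "gff3", "hits"), names(inputs))
    } else names(inputs)[!file.exists(inputs)]
    abort(sprintf("stage 0 (inputs): missing %s", paste(missing, collapse = ", ")))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  genome <- read_fasta(config$genome_fasta)
  catalog <- read_gff3(config$gff3, genome = genome)
  hits <- read_homology_table(config$hits, max_evalue = config$max_evalue)
  blocks <- synteny_blocks(hits, catalog,
                           min_block_genes = config$min_block_genes,
                           max_intervening = config$max_intervening)
  pairs <- homeolog_pairs(blocks)
  cds <- extract_cds(catalog[catalog$valid, , drop = FALSE], genome)
  dist <- dtv_distribution(pairs, cds, label = "intra",
                           min_4d = config$min_4d,
                           correction = config$correction)
  peaks <- if (length(dist$values) >= 30) detect_mode(dist) else NULL

  paths <- list(
    blocks = file.path(config$out_dir, "blocks.tsv"),
    anchors = file.path(config$out_dir, "anchors.tsv"),
    links = file.path(config$out_dir, "links.tsv"),
    pairs = file.path(config$out_dir, "dtv_pairs.tsv"),
    peaks = file.path(config$out_dir, "peaks.json"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  readr::write_tsv(flatten_blocks(blocks), paths$blocks, progress = FALSE)
  anchor_tbl <- if (nrow(blocks)) {
    bind_rows(purrr::map2(blocks$block_id, blocks$anchors,
                          ~ mutate(.y, block_id = .x)))
  } else {
    tibble(block_id = integer(0))
  }
  readr::write_tsv(anchor_tbl, paths$anchors, progress = FALSE)
  readr::write_tsv(block_links(blocks, catalog), paths$links, progress = FALSE)
  readr::write_tsv(dist$pairs, paths$pairs, progress = FALSE)
  jsonlite::write_json(
    list(
      label = "intra",
      n_pairs = nrow(pairs),
      n_blocks = nrow(blocks),
      n_values = length(dist$values),
      exclusions = as.list(dist$exclusions),
      mode = peaks$mode,
      bandwidth = peaks$bandwidth,
      secondary_modes = peaks$secondary_modes
    ),
    paths$peaks, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  manifest_json(config, c("read", "synteny", "pairs", "fourdtv", "peaks"),
                paths$manifest)
  list(blocks = blocks, pairs = pairs, distribution = dist, peaks = peaks,
       paths = paths)
}

#' Run the population track
#'
#' VCF -> (optional fourfold-site restriction) -> depth/missingness/MAF
#' filter cascade -> diversity statistics -> covariance PCA -> replicated
#' admixture fits -> delta-K selection. Stage artifacts and a manifest are
#' written to `config$out_dir`.
#'
#' @param config a [run_config()] with `vcf` set (plus `gff3` and
#'   `genome_fasta` when `fourfold_only = TRUE`)
#' @return list: `gm` (filtered matrix), `stats`, `stats_summary`, `pca`,
#'   `replicates`, `deltak`, `paths`
#' @export
run_pop_track <- function(config) {
  validate_config(config)
  if (is.null(config$vcf) || !file.exists(config$vcf)) {
    abort("stage 0 (inputs): missing vcf")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  gm <- read_vcf(config$vcf)
  if (isTRUE(config$fourfold_only)) {
    genome <- read_fasta(config$genome_fasta)
    catalog <- read_gff3(config$gff3, genome = genome)
    gm <- restrict_to_4d_sites(gm, catalog, genome)
  }
  gm <- apply_filters(gm, dp_min = config$dp_min, dp_max = config$dp_max,
                      maf_min = config$maf_min,
                      max_missing = config$max_missing)
  stats <- locus_stats(gm)
  stats_sum <- locus_stats_summary(stats)
  pca <- pca_covariance(gm)
  reps <- admixture_replicates(gm, k_range = config$k_range,
                               n_replicates = config$n_replicates,
                               seed = config$seed)
  dk <- evanno_delta_k(reps)

  paths <- list(
    attrition = file.path(config$out_dir, "attrition.tsv"),
    stats = file.path(config$out_dir, "locus_stats.tsv"),
    stats_summary = file.path(config$out_dir, "stats_summary.tsv"),
    pca_scores = file.path(config$out_dir, "pca_scores.tsv"),
    pca_eigen = file.path(config$out_dir, "pca_eigenvalues.tsv"),
    qmatrix = file.path(config$out_dir, "qmatrix.tsv"),
    deltak = file.path(config$out_dir, "deltak.json"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  readr::write_tsv(attr(gm, "attrition"), paths$attrition, progress = FALSE)
  readr::write_tsv(stats, paths$stats, progress = FALSE)
  readr::write_tsv(stats_sum, paths$stats_summary, progress = FALSE)
  scores <- as_tibble(pca$scores[, seq_len(min(10, ncol(pca$scores))),
                                 drop = FALSE])
  scores <- bind_cols(tibble(sample = pca$samples), scores)
  readr::write_tsv(scores, paths$pca_scores, progress = FALSE)
  readr::write_tsv(
    tibble(component = seq_along(pca$eigenvalues),
           eigenvalue = pca$eigenvalues, prop_var = pca$prop_var),
    paths$pca_eigen, progress = FALSE
  )
  # best replicate (highest loglik) at the selected K
  sel_k <- attr(dk, "selected_k")
  q_out <- if (!is.na(sel_k)) {
    sel <- reps$summary$K == sel_k
    best <- which(sel)[which.max(reps$summary$loglik[sel])]
    q <- reps$fits[[best]]$Q
    bind_cols(tibble(sample = rownames(q)), as_tibble(q))
  } else {
    tibble(sample = character(0))
  }
  readr::write_tsv(q_out, paths$qmatrix, progress = FALSE)
  jsonlite::write_json(
    list(
      table = as.data.frame(dk),
      selected_k = sel_k,
      reliable = attr(dk, "reliable")
    ),
    paths$deltak, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  manifest_json(config,
                c("read", if (isTRUE(config$fourfold_only)) "fourfold_sites",
                  "filters", "stats", "pca", "admixture", "delta_k"),
                paths$manifest)
  list(gm = gm, stats = stats, stats_summary = stats_sum, pca = pca,
       replicates = reps, deltak = dk, paths = paths)
}
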