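#' Construct a gene catalog
#'
#' A gene catalog is the ordered gene-model backbone used by synteny detection
#' and fourfold-degenerate site classification: one representative transcript
#' per gene, CDS parts stored in transcription order (1-based inclusive
#' genomic coordinates), and a dense per-chromosome rank.
#'
#' @param genes a data frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `cds` (list column of data frames with `start`, `end`),
#'   and optionally `gene_start`
#' @return a `gene_catalog`: a tibble with columns `gene_id`, `chrom`,
#'   `strand`, `gene_start`, `gene_end`, `cds` (transcription order),
#'   `cds_len`, `valid` (length divisible by 3), `rank`
#' @export
gene_catalog <- function(genes) {
  stopifnot(all(c("gene_id", "chrom", "strand", "cds") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) {
    abort("gene_id values must be unique in a gene catalog")
  }
  if (!all(genes$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")

  genes <- as_tibble(genes)
  genes$cds <- purrr::map2(genes$cds, genes$strand, function(parts, strand) {
    parts <- as.data.frame(parts)[, c("start", "end")]
    parts <- parts[order(parts$start), , drop = FALSE]
    if (nrow(parts) > 1 &&
        any(parts$start[-1] <= parts$end[-nrow(parts)])) {
      abort("overlapping CDS parts within one gene")
    }
    if (any(parts$end < parts$start)) abort("CDS part with end < start")
    if (strand == "-") parts <- parts[rev(seq_len(nrow(parts))), , drop = FALSE]
    rownames(parts) <- NULL
    parts
  })
  genes$cds_len <- vapply(genes$cds, function(p) sum(p$end - p$start + 1L), 0)
  genes$gene_start <- vapply(genes$cds, function(p) min(p$start), 0)
  genes$gene_end <- vapply(genes$cds, function(p) max(p$end), 0)
  genes$valid <- genes$cds_len %% 3 == 0
  genes <- genes %>%
    arrange(.data$chrom, .data$gene_start, .data$gene_id) %>%
    group_by(.data$chrom) %>%
    mutate(rank = row_number() - 1L) %>%
    ungroup() %>%
    select("gene_id", "chrom", "strand", "gene_start", "gene_end",
           "cds", "cds_len", "valid", "rank")
  class(genes) <- c("gene_catalog", class(genes))
  genes
}

#' Read a GFF3 gene annotation into a gene catalog
#'
#' One representative transcript is kept per gene: the mRNA with the longest
#' summed CDS, ties broken by the lexicographically smallest transcript ID.
#' Genes whose chromosome is absent from `genome` are dropped with a warning;
#' genes whose CDS length is not divisible by 3 are retained but flagged
#' invalid (they are excluded from codon-level analyses).
#'
#' @param path path to a GFF3 file with gene/mRNA/CDS features linked by
#'   `Parent` attributes
#' @param genome optional named character vector of chromosome sequences used
#'   to drop genes on unknown chromosomes
#' @return a [gene_catalog()]
#' @export
read_gff3 <- function(path, genome = NULL) {
  assert_scalar_string(path, "path")
  if (!file.exists(path)) abort(sprintf("GFF3 file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  first_parent <- function(x) {
    vapply(as.list(x), function(p) if (length(p)) p[[1]] else NA_character_, "")
  }

  mrna <- gr[type == "mRNA"]
  mrna_tbl <- tibble(
    tx_id = as.character(mrna$ID),
    gene_id = first_parent(mrna$Parent)
  )

  cds <- gr[type == "CDS"]
  cds_tbl <- tibble(
    tx_id = first_parent(cds$Parent),
    chrom = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(BiocGenerics::strand(cds)),
    start = BiocGenerics::start(cds),
    end = BiocGenerics::end(cds)
  )
  orphan <- !cds_tbl$tx_id %in% mrna_tbl$tx_id
  if (any(orphan)) {
    warn(sprintf("%d CDS feature(s) reference unknown mRNA parents; skipped",
                 sum(orphan)))
    cds_tbl <- cds_tbl[!orphan, , drop = FALSE]
  }

  per_tx <- cds_tbl %>%
    group_by(.data$tx_id) %>%
    summarise(
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      cds = list(data.frame(start = .data$start, end = .data$end)),
      cds_len = sum(.data$end - .data$start + 1L),
      .groups = "drop"
    ) %>%
    left_join(mrna_tbl, by = "tx_id")

  # representative transcript: longest summed CDS, then smallest tx_id
  rep_tx <- per_tx %>%
    arrange(.data$gene_id, dplyr::desc(.data$cds_len), .data$tx_id) %>%
    group_by(.data$gene_id) %>%
    dplyr::slice(1) %>%
    ungroup()

  if (!is.null(genome)) {
    off <- !rep_tx$chrom %in% names(genome)
    if (any(off)) {
      warn(sprintf("%d gene(s) on chromosomes absent from the genome; dropped",
                   sum(off)))
      rep_tx <- rep_tx[!off, , drop = FALSE]
    }
  }
  if (nrow(rep_tx) == 0) abort("no gene models could be constructed")

  cat <- gene_catalog(rep_tx[, c("gene_id", "chrom", "strand", "cds")])
  if (any(!cat$valid)) {
    warn(sprintf(
      "%d gene(s) with CDS length not divisible by 3; flagged invalid",
      sum(!cat$valid)
    ))
  }
  cat
}

#' Write a gene catalog as GFF3
#'
#' Emits gene/mRNA/CDS features with `ID`/`Parent` links in deterministic
#' order (chromosome, then start).
#'
#' @param catalog a [gene_catalog()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gff3 <- function(catalog, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  ord <- order(catalog$chrom, catalog$gene_start, catalog$gene_id)
  for (i in ord) {
    g <- catalog[i, ]
    tx <- paste0(g$gene_id, ".t1")
    writeLines(sprintf("%s\twgdpop\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$gene_start, g$gene_end, g$strand,
                       g$gene_id), con)
    writeLines(sprintf("%s\twgdpop\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$chrom, g$gene_start, g$gene_end, g$strand,
                       tx, g$gene_id), con)
    parts <- g$cds[[1]]
    parts <- parts[order(parts$start), , drop = FALSE]
    phase <- 0L  # phases recomputed for completeness
    if (g$strand == "-") parts <- parts[rev(seq_len(nrow(parts))), , drop = FALSE]
    for (j in seq_len(nrow(parts))) {
      writeLines(sprintf(
        "%s\twgdpop\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
        g$chrom, parts$start[j], parts$end[j], g$strand, phase, tx, tx
      ), con)
      phase <- (3L - ((parts$end[j] - parts$start[j] + 1L - phase) %% 3L)) %% 3L
    }
  }
  invisible(path)
}

#' Extract spliced coding sequences from a genome
#'
#' Parts are concatenated in transcription order; minus-strand genes are
#' reverse-complemented. The result length equals the summed part lengths.
#'
#' @param catalog a [gene_catalog()]
#' @param genome named character vector of chromosome sequences
#' @return named character vector of CDS, one per gene in `catalog`
#' @export
extract_cds <- function(catalog, genome) {
  missing_chrom <- setdiff(unique(catalog$chrom), names(genome))
  if (length(missing_chrom)) {
    abort(sprintf("catalog chromosomes absent from genome: %s",
                  paste(missing_chrom, collapse = ", ")))
  }
  out <- vapply(seq_len(nrow(catalog)), function(i) {
    parts <- catalog$cds[[i]]
    chrom_seq <- genome[[catalog$chrom[i]]]
    if (max(parts$end) > nchar(chrom_seq) || min(parts$start) < 1L) {
      abort(sprintf("CDS interval out of bounds for gene %s",
                    catalog$gene_id[i]))
    }
    asc <- parts[order(parts$start), , drop = FALSE]
    s <- paste(substring(chrom_seq, asc$start, asc$end), collapse = "")
    if (catalog$strand[i] == "-") s <- revcomp(s) else s
  }, "")
  names(out) <- catalog$gene_id
  out
}

#' Map CDS positions to genomic coordinates
#'
#' Returns the genomic position of each base of the spliced CDS, in
#' transcription order (position 1 is the first transcribed base).
#'
#' @param parts CDS parts in transcription order (as stored in the catalog)
#' @param strand `"+"` or `"-"`
#' @return integer vector of genomic positions, length = summed part lengths
#' @keywords internal
cds_genomic_positions <- function(parts, strand) {
  unlist(lapply(seq_len(nrow(parts)), function(j) {
    if (strand == "+") seq.int(parts$start[j], parts$end[j])
    else seq.int(parts$end[j], parts$start[j])
  }), use.names = FALSE)
}
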