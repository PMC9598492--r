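#' Collapse tandem arrays before colinearity detection
#'
#' Adjacent homologous gene copies on one chromosome (tandem duplicates) can
#' masquerade as colinear blocks. Among mutually-hitting genes on the same
#' chromosome within `max_tandem_rank_gap` ranks of each other, only one
#' representative — the gene with the highest bit score among its hits —
#' retains its hits; all hit rows touching the other array members are
#' removed.
#'
#' @param hits homology tibble (see [read_homology_table()])
#' @param catalog a [gene_catalog()] resolving both hit columns
#' @param max_tandem_rank_gap maximum rank separation within an array
#'   (default 1, i.e. adjacent genes)
#' @return filtered hits tibble; attribute `removed_genes` lists collapsed
#'   array members
#' @export
collapse_tandem <- function(hits, catalog, max_tandem_rank_gap = 1L) {
  if (nrow(hits) == 0) return(hits)
  look <- stats::setNames(seq_len(nrow(catalog)), catalog$gene_id)
  qi <- look[hits$query_id]
  si <- look[hits$subject_id]
  known <- !is.na(qi) & !is.na(si)
  tandem <- known &
    catalog$chrom[qi] == catalog$chrom[si] &
    abs(catalog$rank[qi] - catalog$rank[si]) <= max_tandem_rank_gap
  if (!any(tandem)) return(hits)

  edges <- unique(rbind(
    cbind(hits$query_id[tandem], hits$subject_id[tandem])
  ))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)
  members <- split(igraph::V(g)$name, comp$membership)

  best_bit <- tapply(
    c(hits$bit_score, hits$bit_score),
    c(hits$query_id, hits$subject_id),
    max
  )
  removed <- unlist(lapply(members, function(ids) {
    ids <- sort(ids)
    rep_id <- ids[order(-best_bit[ids], ids)][1]
    setdiff(ids, rep_id)
  }), use.names = FALSE)
  out <- hits %>%
    filter(!.data$query_id %in% removed, !.data$subject_id %in% removed)
  if (length(removed)) {
    inform(sprintf("collapse_tandem: removed %d tandem array member(s)",
                   length(removed)))
  }
  attr(out, "removed_genes") <- removed
  out
}

#' Build synteny anchors from homology hits
#'
#' Each retained (query, subject) hit becomes an anchor carrying the two
#' genes' chromosomes and ranks. In intra-genomic mode (no `catalog_b`) each
#' unordered gene pair appears once, oriented by lexicographic gene id and
#' keeping the best bit score among reciprocal rows, and the two sides are
#' then canonicalised by (chromosome, rank) so anchors of one chromosome
#' pair group together.
#'
#' @param hits homology tibble, already e-value filtered
#' @param catalog_a gene catalog for the query side
#' @param catalog_b gene catalog for the subject side; omit for
#'   intra-genomic mode
#' @return anchors tibble: `gene_a`, `gene_b`, `chrom_a`, `chrom_b`,
#'   `rank_a`, `rank_b`, `bit_score`
#' @export
build_anchors <- function(hits, catalog_a, catalog_b = NULL) {
  intra <- is.null(catalog_b)
  if (intra) catalog_b <- catalog_a
  empty <- tibble(
    gene_a = character(0), gene_b = character(0),
    chrom_a = character(0), chrom_b = character(0),
    rank_a = integer(0), rank_b = integer(0), bit_score = numeric(0)
  )
  if (nrow(hits) == 0) return(empty)
  ia <- match(hits$query_id, catalog_a$gene_id)
  ib <- match(hits$subject_id, catalog_b$gene_id)
  unknown <- is.na(ia) | is.na(ib)
  if (any(unknown)) {
    warn(sprintf("build_anchors: %d hit(s) reference genes absent from the catalog; dropped",
                 sum(unknown)))
    hits <- hits[!unknown, , drop = FALSE]
    ia <- ia[!unknown]; ib <- ib[!unknown]
  }
  if (nrow(hits) == 0) return(empty)
  anc <- tibble(
    gene_a = hits$query_id, gene_b = hits$subject_id,
    chrom_a = catalog_a$chrom[ia], chrom_b = catalog_b$chrom[ib],
    rank_a = catalog_a$rank[ia], rank_b = catalog_b$rank[ib],
    bit_score = hits$bit_score
  )
  if (intra) {
    anc <- anc[anc$gene_a != anc$gene_b, , drop = FALSE]
    flip <- anc$gene_a > anc$gene_b
    anc[flip, c("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b")] <-
      anc[flip, c("gene_b", "gene_a", "chrom_b", "chrom_a", "rank_b", "rank_a")]
    anc <- anc %>%
      group_by(.data$gene_a, .data$gene_b) %>%
      summarise(
        chrom_a = .data$chrom_a[1], chrom_b = .data$chrom_b[1],
        rank_a = .data$rank_a[1], rank_b = .data$rank_b[1],
        bit_score = max(.data$bit_score), .groups = "drop"
      )
    # canonical sides per chromosome pair
    flip <- anc$chrom_a > anc$chrom_b |
      (anc$chrom_a == anc$chrom_b & anc$rank_a > anc$rank_b)
    anc[flip, c("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b")] <-
      anc[flip, c("gene_b", "gene_a", "chrom_b", "chrom_a", "rank_b", "rank_a")]
  }
  anc %>% arrange(.data$chrom_a, .data$chrom_b, .data$rank_a, .data$rank_b)
}

# best monotone chain by DP on one chromosome pair and one orientation;
# returns integer indices into the anchor subset (chain order), or NULL
chain_dp <- function(ra, rb, bit, orientation, max_intervening) {
  n <- length(ra)
  gapmax <- max_intervening + 1L
  ord <- order(ra, rb)
  ra <- ra[ord]; rb <- rb[ord]; bit <- bit[ord]
  cnt <- rep(1L, n); sc <- bit; prev <- rep(0L, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      da <- ra[j] - ra[i]
      if (da <= 0L || da > gapmax) next
      db <- if (orientation == "same") rb[j] - rb[i] else rb[i] - rb[j]
      if (db <= 0L || db > gapmax) next
      better <- (cnt[i] + 1L > cnt[j]) ||
        (cnt[i] + 1L == cnt[j] && sc[i] + bit[j] > sc[j])
      if (better) {
        cnt[j] <- cnt[i] + 1L
        sc[j] <- sc[i] + bit[j]
        prev[j] <- i
      }
    }
  }
  trace <- function(j) {
    path <- integer(0)
    while (j != 0L) { path <- c(j, path); j <- prev[j] }
    path
  }
  ends <- which(cnt == max(cnt))
  ends <- ends[sc[ends] == max(sc[ends])]
  paths <- lapply(ends, trace)
  starts <- vapply(paths, function(p) ra[p[1]], 0L)
  best <- paths[[order(starts)[1]]]
  list(idx = ord[best], n = length(best), score = sum(bit[best]),
       start_a = ra[best[1]])
}

#' Chain anchors into colinear synteny blocks
#'
#' For each chromosome pair and each orientation (same or inverted), finds
#' maximal colinear chains by dynamic programming: anchor j may follow i iff
#' its rank on side A is strictly larger and its rank on side B strictly
#' follows the orientation, with at most `max_intervening` intervening genes
#' between consecutive anchors on *both* sides. Chains are scored by anchor
#' count, then summed bit score, then smallest start rank; overlapping chains
#' are resolved greedily best-first with used anchors removed. Chains with
#' fewer than `min_block_genes` anchors are discarded.
#'
#' @param anchors anchors tibble from [build_anchors()]
#' @param min_block_genes minimum anchors per reported block (default 10)
#' @param max_intervening maximum intervening genes between consecutive
#'   anchors on each side (default 5, i.e. "fewer than six")
#' @return blocks tibble: `block_id`, `chrom_a`, `chrom_b`, `orientation`,
#'   `n_anchors`, `score`, rank spans `start_a`/`end_a`/`start_b`/`end_b`,
#'   and an `anchors` list column (chain order)
#' @export
chain_anchors <- function(anchors, min_block_genes = 10L, max_intervening = 5L) {
  empty <- tibble(
    block_id = integer(0), chrom_a = character(0), chrom_b = character(0),
    orientation = character(0), n_anchors = integer(0), score = numeric(0),
    start_a = integer(0), end_a = integer(0),
    start_b = integer(0), end_b = integer(0), anchors = list()
  )
  if (nrow(anchors) == 0) return(empty)
  groups <- split(seq_len(nrow(anchors)),
                  paste(anchors$chrom_a, anchors$chrom_b, sep = "\r"))
  blocks <- list()
  for (key in sort(names(groups))) {
    sub <- anchors[groups[[key]], , drop = FALSE]
    repeat {
      if (nrow(sub) == 0) break
      cands <- lapply(c("same", "inverted"), function(o) {
        c(chain_dp(sub$rank_a, sub$rank_b, sub$bit_score, o, max_intervening),
          list(orientation = o))
      })
      pick <- order(
        -vapply(cands, `[[`, 0L, "n"),
        -vapply(cands, `[[`, 0, "score"),
        vapply(cands, `[[`, 0L, "start_a"),
        vapply(cands, `[[`, "", "orientation")  # "inverted" < "same"; stable
      )[1]
      best <- cands[[pick]]
      if (best$n < min_block_genes) break
      chain <- sub[best$idx, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <- tibble(
        chrom_a = chain$chrom_a[1], chrom_b = chain$chrom_b[1],
        orientation = best$orientation, n_anchors = nrow(chain),
        score = sum(chain$bit_score),
        start_a = min(chain$rank_a), end_a = max(chain$rank_a),
        start_b = min(chain$rank_b), end_b = max(chain$rank_b),
        anchors = list(chain)
      )
      sub <- sub[-best$idx, , drop = FALSE]
    }
  }
  if (!length(blocks)) return(empty)
  out <- bind_rows(blocks) %>%
    arrange(.data$chrom_a, .data$chrom_b, -.data$n_anchors, .data$start_a) %>%
    mutate(block_id = row_number()) %>%
    select("block_id", dplyr::everything())
  out
}

#' Validate synteny-block invariants
#'
#' Checks, for every block: anchor count above threshold, strict rank
#' monotonicity per orientation, and intervening-gene gaps within bounds on
#' both sides. Errors on the first violation.
#'
#' @inheritParams chain_anchors
#' @param blocks blocks tibble from [chain_anchors()]
#' @return `TRUE`, invisibly
#' @export
validate_blocks <- function(blocks, min_block_genes = 10L, max_intervening = 5L) {
  gapmax <- max_intervening + 1L
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    a <- b$anchors[[1]]
    if (nrow(a) < min_block_genes) abort(sprintf("block %d below size threshold", b$block_id))
    da <- diff(a$rank_a)
    db <- diff(a$rank_b)
    if (any(da <= 0 | da > gapmax)) abort(sprintf("block %d violates side-A colinearity", b$block_id))
    ok_b <- if (b$orientation == "same") all(db > 0 & db <= gapmax)
            else all(-db > 0 & -db <= gapmax)
    if (!ok_b) abort(sprintf("block %d violates side-B colinearity", b$block_id))
  }
  invisible(TRUE)
}

#' Homeologous gene pairs from synteny blocks
#'
#' Concatenates anchor pairs across blocks and deduplicates; pairs reachable
#' in more than one block are reported once and flagged.
#'
#' @param blocks blocks tibble from [chain_anchors()]
#' @return tibble: `gene_a`, `gene_b`, `n_blocks`
#' @export
homeolog_pairs <- function(blocks) {
  if (nrow(blocks) == 0) {
    return(tibble(gene_a = character(0), gene_b = character(0),
                  n_blocks = integer(0)))
  }
  bind_rows(blocks$anchors) %>%
    group_by(.data$gene_a, .data$gene_b) %>%
    summarise(n_blocks = dplyr::n(), .groups = "drop")
}

#' End-to-end colinearity detection
#'
#' Intra-genomic mode (one catalog): tandem arrays are collapsed and
#' reciprocal hits deduplicated before chaining. Inter-genomic mode (two
#' catalogs): the identical chaining machinery with no self-pair dedup and
#' no tandem collapse.
#'
#' @inheritParams chain_anchors
#' @inheritParams build_anchors
#' @param max_tandem_rank_gap see [collapse_tandem()] (intra mode only)
#' @return blocks tibble from [chain_anchors()]
#' @export
synteny_blocks <- function(hits, catalog_a, catalog_b = NULL,
                           min_block_genes = 10L, max_intervening = 5L,
                           max_tandem_rank_gap = 1L) {
  if (is.null(catalog_b)) {
    hits <- collapse_tandem(hits, catalog_a, max_tandem_rank_gap)
  }
  anchors <- build_anchors(hits, catalog_a, catalog_b)
  chain_anchors(anchors, min_block_genes, max_intervening)
}
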