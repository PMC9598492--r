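# Independent oracles used to cross-check the implementation.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Gotoh affine-gap global alignment score (oracle for the alignment wrapper).
# A gap of length L costs gap_open + L * gap_extend.
oracle_nw_score <- function(a, b, gap_open = 10, gap_extend = 1,
                            mat = blosum62) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gap_open + i * gap_extend)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gap_open + j * gap_extend)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[a[i], b[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive best monotone chain (count, then summed bit score) by DFS over
# every valid chain; oracle for the chaining dynamic programme.
oracle_best_chain <- function(ra, rb, bit, orientation, max_intervening) {
  n <- length(ra)
  gapmax <- max_intervening + 1
  ok_step <- function(i, j) {
    da <- ra[j] - ra[i]
    if (da <= 0 || da > gapmax) return(FALSE)
    db <- if (orientation == "same") rb[j] - rb[i] else rb[i] - rb[j]
    db > 0 && db <= gapmax
  }
  best <- c(count = 0, score = -Inf)
  dfs <- function(last, count, score) {
    if (count > best[["count"]] ||
        (count == best[["count"]] && score > best[["score"]])) {
      best <<- c(count = count, score = score)
    }
    for (j in seq_len(n)) {
      if (ok_step(last, j)) dfs(j, count + 1, score + bit[j])
    }
  }
  for (s in seq_len(n)) dfs(s, 1, bit[s])
  best
}

# Brute-force per-locus diversity statistics with explicit loops.
oracle_locus_stats <- function(g) {
  t(apply(g, 2, function(col) {
    called <- col[!is.na(col)]
    n2 <- 2 * length(called)
    p <- sum(called) / n2
    q <- 1 - p
    gd <- 1 - p^2 - q^2
    c(gd = gd,
      pic = gd - 2 * p^2 * q^2,
      ho = mean(called == 1),
      maf = min(p, q))
  }))
}

# random genotype matrix helper
random_geno <- function(n, L, miss = 0.05, seed = 1) {
  withr::with_seed(seed, {
    g <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
    g[matrix(runif(n * L) < miss, n, L)] <- NA_integer_
    # guarantee at least one call per locus
    for (j in which(colSums(!is.na(g)) == 0)) g[1, j] <- 1L
    geno_matrix(g, loci = data.frame(
      chrom = "c1", pos = seq_len(L), ref = "A", alt = "G"
    ))
  })
}

# random anchor instance for chaining tests
random_anchor_instance <- function(seed, n_max = 15) {
  withr::with_seed(seed, {
    n <- sample(4:n_max, 1)
    span <- n + sample(0:6, 1)
    tibble::tibble(
      gene_a = sprintf("ga%02d", seq_len(n)),
      gene_b = sprintf("gb%02d", seq_len(n)),
      chrom_a = "A", chrom_b = "B",
      rank_a = sort(sample(0:span, n)),
      rank_b = sample(0:span, n),
      bit_score = round(runif(n, 50, 500), 1)
    )
  })
}
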