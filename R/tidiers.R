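#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an admixture fit into long ancestry proportions
#' @param x an `admixture_fit`
#' @param ... unused
#' @return tibble `(sample, cluster, proportion)`
#' @method tidy admixture_fit
#' @export
tidy.admixture_fit <- function(x, ...) {
  as_tibble(x$Q, rownames = "sample") %>%
    tidyr::pivot_longer(-"sample", names_to = "cluster",
                        values_to = "proportion")
}

#' One-row summary of an admixture fit
#' @param x an `admixture_fit`
#' @param ... unused
#' @method glance admixture_fit
#' @export
glance.admixture_fit <- function(x, ...) {
  tibble(K = x$K, loglik = x$loglik, iterations = x$iterations,
         converged = x$converged, seed = x$seed)
}

#' Tidy PCA scores
#' @param x a `geno_pca`
#' @param n_components number of leading components to keep
#' @param ... unused
#' @return tibble with `sample` and one column per component
#' @method tidy geno_pca
#' @export
tidy.geno_pca <- function(x, n_components = 2L, ...) {
  k <- min(n_components, ncol(x$scores))
  bind_cols(tibble(sample = x$samples),
            as_tibble(x$scores[, seq_len(k), drop = FALSE]))
}

#' One-row summary of a genotype PCA
#' @param x a `geno_pca`
#' @param ... unused
#' @method glance geno_pca
#' @export
glance.geno_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores), n_components = ncol(x$scores),
         pc1_prop = x$prop_var[1],
         pc2_prop = if (length(x$prop_var) > 1) x$prop_var[2] else NA_real_)
}

#' Per-pair rows of a 4DTv distribution
#' @param x a `dtv_distribution`
#' @param ... unused
#' @method tidy dtv_distribution
#' @export
tidy.dtv_distribution <- function(x, ...) x$pairs

#' One-row summary of a 4DTv distribution
#' @param x a `dtv_distribution`
#' @param ... unused
#' @method glance dtv_distribution
#' @export
glance.dtv_distribution <- function(x, ...) {
  tibble(label = x$label, n = length(x$values), n_excluded = x$n_excluded,
         mean = mean(x$values), median = stats::median(x$values))
}
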