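#' Maximum-likelihood admixture model fitted by EM
#'
#' Fits the binomial admixture model: individual i carries ancestry
#' proportions `q_i` over K clusters with cluster allele frequencies
#' `p_k`, and its alt-allele count at locus l is Binomial(2, sum_k q_ik
#' p_kl). The log-likelihood (up to the genotype-independent binomial
#' coefficient) is
#' `sum_il [ g_il log(f_il) + (2 - g_il) log(1 - f_il) ]` with
#' `f = Q P`; missing genotypes contribute nothing. The E-step computes
#' per-allele-copy cluster responsibilities; the M-step renormalises Q rows
#' and updates P as responsibility-weighted allele fractions. EM guarantees
#' a non-decreasing log-likelihood trace.
#'
#' Convergence is declared when the accepted log-likelihood changes by less
#' than `tol`. With `accelerate = TRUE` (default) each recorded step is a
#' guarded SQUAREM cycle: two EM map evaluations plus a monotone
#' extrapolation that is rejected in favour of the plain EM result whenever
#' it fails to improve the likelihood, so the trace stays non-decreasing.
#'
#' @param gm a [geno_matrix()] (filtered)
#' @param K number of ancestral clusters (1 <= K <= samples)
#' @param seed integer seed for the random initialisation
#' @param max_iter maximum EM map evaluations (default 2000)
#' @param tol absolute log-likelihood change at convergence (default 1e-6)
#' @param accelerate use guarded SQUAREM extrapolation (default TRUE)
#' @return an `admixture_fit`: list with `K`, `Q` (samples x K), `P`
#'   (K x loci), `loglik`, `trace`, `iterations`, `converged`, `seed`
#' @export
admixture_em <- function(gm, K, seed = 1L, max_iter = 2000L, tol = 1e-6,
                         accelerate = TRUE) {
  stopifnot(inherits(gm, "geno_matrix"))
  n <- nrow(gm$g); L <- ncol(gm$g)
  if (K < 1) abort("K must be at least 1")
  if (K > n) abort(sprintf("K = %d exceeds the number of samples (%d)", K, n))
  G <- gm$g
  M <- !is.na(G)
  G0 <- ifelse(M, G, 0)
  C0 <- ifelse(M, 2 - G, 0)
  eps <- 1e-6
  clamp <- function(p) pmin(pmax(p, eps), 1 - eps)
  obs_freq <- colSums(G0) / pmax(2 * colSums(M), 1)

  if (K == 1L) {
    P <- matrix(clamp(obs_freq), nrow = 1)
    F1 <- matrix(P, n, L, byrow = TRUE)
    ll <- sum((G0 * log(F1) + C0 * log(1 - F1))[M])
    return(structure(list(
      K = 1L, Q = matrix(1, n, 1, dimnames = list(gm$samples, "K1")),
      P = P, loglik = ll, trace = ll, iterations = 0L, converged = TRUE,
      seed = seed
    ), class = "admixture_fit"))
  }

  withr::with_seed(seed, {
    Q <- matrix(stats::rgamma(n * K, shape = 1), n, K)
    Q <- Q / rowSums(Q)
    P <- matrix(clamp(rep(obs_freq, each = K) *
                        stats::runif(K * L, 0.6, 1.4)), K, L)
  })

  n_copies <- 2 * rowSums(M)
  loglik_at <- function(Q, P) {
    FF <- pmin(pmax(Q %*% P, eps), 1 - eps)
    # missing genotypes have G0 = C0 = 0, so they contribute nothing
    sum(G0 * log(FF) + C0 * log(1 - FF))
  }
  # one EM map evaluation. Responsibility-weighted copy counts are computed
  # without n x L per-cluster temporaries: E[alt copies from k at (i,l)] =
  # (G0/FF) q_ik p_kl, whose row and column sums are matrix-vector products
  # with W1 = G0/FF (W2 analogous for ref copies).
  em_step <- function(Q, P) {
    FF <- pmin(pmax(Q %*% P, eps), 1 - eps)
    W1 <- G0 / FF
    W2 <- C0 / (1 - FF)
    Qn <- Q
    Pn <- P
    for (k in seq_len(K)) {
      alt_row <- drop(W1 %*% P[k, ])
      ref_row <- drop(W2 %*% (1 - P[k, ]))
      alt_col <- drop(crossprod(W1, Q[, k])) * P[k, ]
      ref_col <- drop(crossprod(W2, Q[, k])) * (1 - P[k, ])
      Qn[, k] <- Q[, k] * (alt_row + ref_row) / n_copies
      Pn[k, ] <- clamp(alt_col / pmax(alt_col + ref_col,
                                      .Machine$double.xmin))
    }
    list(Q = Qn / rowSums(Qn), P = Pn)
  }
  project <- function(Q, P) {
    Q <- pmax(Q, 1e-12)
    list(Q = Q / rowSums(Q), P = clamp(P))
  }

  trace <- numeric(0)
  ll <- loglik_at(Q, P)
  trace[1] <- ll
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    if (accelerate) {
      s1 <- em_step(Q, P)
      s2 <- em_step(s1$Q, s1$P)
      it <- it + 2L
      rQ <- s1$Q - Q; rP <- s1$P - P
      vQ <- s2$Q - s1$Q - rQ; vP <- s2$P - s1$P - rP
      vnorm <- sum(vQ^2) + sum(vP^2)
      accepted <- FALSE
      if (vnorm > 0) {
        alpha <- -sqrt((sum(rQ^2) + sum(rP^2)) / vnorm)
        ext <- project(Q - 2 * alpha * rQ + alpha^2 * vQ,
                       P - 2 * alpha * rP + alpha^2 * vP)
        ll_ext <- loglik_at(ext$Q, ext$P)
        it <- it + 1L
        ll2 <- loglik_at(s2$Q, s2$P)
        if (is.finite(ll_ext) && ll_ext >= ll2) {
          Q <- ext$Q; P <- ext$P; ll_new <- ll_ext
          accepted <- TRUE
        }
      }
      if (!accepted) {
        Q <- s2$Q; P <- s2$P
        ll_new <- loglik_at(Q, P)
      }
    } else {
      s1 <- em_step(Q, P)
      it <- it + 1L
      Q <- s1$Q; P <- s1$P
      ll_new <- loglik_at(Q, P)
    }
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < tol) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  dimnames(Q) <- list(gm$samples, paste0("K", seq_len(K)))
  structure(list(
    K = K, Q = Q, P = P, loglik = trace[length(trace)], trace = trace,
    iterations = it, converged = converged, seed = seed
  ), class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("<admixture_fit> K = %d, loglik = %.2f, %d iterations (%s)\n",
              x$K, x$loglik, x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Replicate admixture fits across K values
#'
#' Runs [admixture_em()] for each K in `k_range`, `n_replicates` times with
#' distinct derived seeds, as input for [evanno_delta_k()].
#'
#' @inheritParams admixture_em
#' @param k_range integer vector of K values (e.g. `1:4`)
#' @param n_replicates fits per K (default 5)
#' @param seed master seed; per-fit seeds are derived deterministically
#' @return list with `fits` (list of `admixture_fit`) and `summary`
#'   tibble `(K, replicate, seed, loglik, iterations, converged)`
#' @export
admixture_replicates <- function(gm, k_range = 1:4, n_replicates = 5L,
                                 seed = 1L, max_iter = 2000L, tol = 1e-6) {
  grid <- expand.grid(replicate = seq_len(n_replicates), K = k_range)
  fits <- purrr::map(seq_len(nrow(grid)), function(i) {
    admixture_em(gm, K = grid$K[i],
                 seed = derive_seed(seed, grid$K[i], grid$replicate[i]),
                 max_iter = max_iter, tol = tol)
  })
  summary <- tibble(
    K = grid$K, replicate = grid$replicate,
    seed = vapply(fits, `[[`, 0L, "seed"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    iterations = vapply(fits, `[[`, 0L, "iterations"),
    converged = vapply(fits, `[[`, TRUE, "converged")
  )
  list(fits = fits, summary = summary)
}

#' Evanno delta-K model selection over replicate likelihoods
#'
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`,
#' defined only for interior K with positive replicate standard deviation.
#' The selected K maximises deltaK among defined values. When the mean
#' likelihood is essentially flat across K the selection is flagged
#' unreliable.
#'
#' @param replicates result of [admixture_replicates()], or its `summary`
#'   tibble with columns `K` and `loglik`
#' @return a `deltak_report`: tibble `(K, mean_loglik, sd_loglik, delta_k)`
#'   with attributes `selected_k` and `reliable`
#' @export
evanno_delta_k <- function(replicates) {
  s <- if (is.data.frame(replicates)) replicates else replicates$summary
  stopifnot(all(c("K", "loglik") %in% names(s)))
  per_k <- s %>%
    group_by(.data$K) %>%
    summarise(mean_loglik = mean(.data$loglik),
              sd_loglik = stats::sd(.data$loglik),
              n_rep = dplyr::n(), .groups = "drop") %>%
    arrange(.data$K)
  ks <- per_k$K
  if (length(ks) < 3 || any(diff(ks) != 1)) {
    abort("delta-K needs at least 3 consecutive K values")
  }
  if (any(per_k$n_rep < 3)) abort("delta-K needs at least 3 replicates per K")
  m <- per_k$mean_loglik
  dk <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)[-c(1, length(ks))]) {
    num <- abs(m[i + 1] - 2 * m[i] + m[i - 1])
    sdv <- per_k$sd_loglik[i]
    dk[i] <- if (is.na(sdv) || sdv == 0) NA_real_ else num / sdv
  }
  per_k$delta_k <- dk
  interior <- which(!is.na(dk))
  selected <- if (length(interior)) ks[interior[which.max(dk[interior])]] else NA_integer_
  curvature <- abs(diff(m, differences = 2))
  reliable <- length(interior) > 0 &&
    max(curvature) > 1e-6 * max(1, abs(mean(m)))
  structure(per_k, class = c("deltak_report", class(per_k)),
            selected_k = selected, reliable = reliable)
}

#' Align cluster labels of an estimated Q matrix to a reference
#'
#' Admixture clusters are identifiable only up to label permutation; this
#' finds the column permutation of `Q_hat` minimising the mean absolute
#' difference to `Q_ref`.
#'
#' @param Q_hat,Q_ref samples x K matrices with equal dimensions
#' @return list with the permuted `Q` and the `mean_abs_error`
#' @export
align_q <- function(Q_hat, Q_ref) {
  stopifnot(all(dim(Q_hat) == dim(Q_ref)))
  K <- ncol(Q_hat)
  perms <- perm_matrix(K)
  errs <- apply(perms, 1, function(p) mean(abs(Q_hat[, p] - Q_ref)))
  best <- perms[which.min(errs), ]
  list(Q = Q_hat[, best, drop = FALSE], mean_abs_error = min(errs))
}

perm_matrix <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, ifelse(sub >= i, sub + 1L, sub))
  }))
}
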