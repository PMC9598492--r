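#' Build a 4DTv distance distribution over gene pairs
#'
#' Computes one corrected 4DTv distance per admissible pair; pairs excluded
#' by alignment failure, too few comparable 4D sites, or transversion
#' saturation are counted by reason.
#'
#' @param pairs data frame with columns `gene_a`, `gene_b`
#' @param cds named character vector of coding sequences resolving every
#'   gene id
#' @param label distribution label (e.g. `"intra"`)
#' @inheritParams fourdtv_pair
#' @return a `dtv_distribution`: list with `label`, `pairs` (per-pair
#'   tibble), `values` (finite corrected distances), `n_excluded`,
#'   `exclusions` (named counts)
#' @export
dtv_distribution <- function(pairs, cds, label = "intra", min_4d = 10,
                             correction = "saturation",
                             gap_open = 10, gap_extend = 1) {
  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    if (!ga %in% names(cds) || !gb %in% names(cds)) {
      abort(sprintf("pair (%s, %s) not resolvable to CDS", ga, gb))
    }
    tryCatch(
      fourdtv_pair(cds[[ga]], cds[[gb]], id_a = ga, id_b = gb,
                   min_4d = min_4d, correction = correction,
                   gap_open = gap_open, gap_extend = gap_extend),
      error = function(e) tibble(
        id_a = ga, id_b = gb, n_4d = NA_integer_, n_tv = NA_integer_,
        p_raw = NA_real_, d_corr = NA_real_, status = "unalignable"
      )
    )
  })
  per_pair <- bind_rows(rows)
  if (nrow(per_pair) == 0) {
    per_pair <- tibble(id_a = character(0), id_b = character(0),
                       n_4d = integer(0), n_tv = integer(0),
                       p_raw = numeric(0), d_corr = numeric(0),
                       status = character(0))
  }
  excl <- table(per_pair$status[per_pair$status != "ok"])
  structure(
    list(
      label = label,
      pairs = per_pair,
      values = per_pair$d_corr[per_pair$status == "ok"],
      n_excluded = sum(per_pair$status != "ok"),
      exclusions = stats::setNames(as.integer(excl), names(excl))
    ),
    class = "dtv_distribution"
  )
}

#' @export
print.dtv_distribution <- function(x, ...) {
  cat(sprintf("<dtv_distribution '%s'> %d values, %d excluded\n",
              x$label, length(x$values), x$n_excluded))
  invisible(x)
}

# local maxima with topographic prominence on a density grid
density_peaks <- function(y) {
  n <- length(y)
  locmax <- which(diff(sign(diff(y))) < 0) + 1L
  if (y[1] > y[2]) locmax <- c(1L, locmax)
  if (y[n] > y[n - 1]) locmax <- c(locmax, n)
  prominence <- vapply(locmax, function(i) {
    h <- y[i]
    higher <- which(y > h)
    left <- higher[higher < i]
    right <- higher[higher > i]
    col_left <- if (length(left)) min(y[max(left):i]) else NA_real_
    col_right <- if (length(right)) min(y[i:min(right)]) else NA_real_
    key_col <- suppressWarnings(max(col_left, col_right, na.rm = TRUE))
    if (!is.finite(key_col)) h else h - key_col
  }, 0)
  tibble(index = locmax, height = y[locmax], prominence = prominence)
}

#' Detect the mode(s) of a 4DTv distribution
#'
#' Gaussian kernel density with Silverman's rule-of-thumb bandwidth,
#' evaluated on a fixed grid of 512 points over `[0, max + bandwidth]`; the
#' reported mode is the density argmax rounded to 3 decimals. Secondary
#' modes are local maxima whose topographic prominence exceeds
#' `prominence_frac` of the density at the global mode.
#'
#' @param dist a `dtv_distribution` or a numeric vector of distances
#' @param min_n minimum number of values (default 30); below this an error
#'   advises a histogram fallback
#' @param prominence_frac prominence threshold for secondary modes, as a
#'   fraction of the maximum density (default 0.5)
#' @param n_grid number of density grid points (default 512)
#' @return a `peak_report`: list with `label`, `mode`, `density_at_mode`,
#'   `bandwidth`, `secondary_modes` (numeric), `n`
#' @export
detect_mode <- function(dist, min_n = 30L, prominence_frac = 0.5,
                        n_grid = 512L) {
  values <- if (inherits(dist, "dtv_distribution")) dist$values else as.numeric(dist)
  label <- if (inherits(dist, "dtv_distribution")) dist$label else "values"
  values <- values[is.finite(values)]
  if (length(values) < min_n) {
    abort(sprintf(
      "only %d values (< %d): too few for density mode detection; use a histogram",
      length(values), min_n
    ))
  }
  if (length(unique(values)) == 1L) {
    # a point mass needs no density estimate; report the value itself
    return(structure(
      list(label = label, mode = round(values[1], 3),
           density_at_mode = Inf, bandwidth = 0,
           secondary_modes = numeric(0), n = length(values),
           density = tibble(x = values[1], y = Inf)),
      class = "peak_report"
    ))
  }
  bw <- stats::bw.nrd0(values)
  if (bw <= 0) bw <- max(1e-6, stats::sd(values), na.rm = TRUE)
  den <- stats::density(values, bw = bw, kernel = "gaussian", n = n_grid,
                        from = 0, to = max(values) + bw)
  i_mode <- which.max(den$y)
  peaks <- density_peaks(den$y)
  secondary <- peaks %>%
    filter(.data$index != i_mode,
           .data$prominence >= prominence_frac * den$y[i_mode])
  structure(
    list(
      label = label,
      mode = round(den$x[i_mode], 3),
      density_at_mode = den$y[i_mode],
      bandwidth = bw,
      secondary_modes = round(den$x[secondary$index], 3),
      n = length(values),
      density = tibble(x = den$x, y = den$y)
    ),
    class = "peak_report"
  )
}

#' @export
print.peak_report <- function(x, ...) {
  cat(sprintf("<peak_report '%s'> mode %.3f (bw %.4g, n %d)", x$label,
              x$mode, x$bandwidth, x$n))
  if (length(x$secondary_modes)) {
    cat(sprintf("; secondary: %s", paste(x$secondary_modes, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Summarise and compare modes across 4DTv distributions
#'
#' Used to contrast intra-genomic (duplication) with inter-genomic
#' (speciation) distance distributions: modes closer than `overlap_tol`
#' are flagged as overlapping, the signature of a duplication coincident
#' with a speciation.
#'
#' @param dists list of `dtv_distribution` objects (length >= 1)
#' @param overlap_tol mode-distance threshold for the overlap flag
#'   (default 0.02)
#' @param ... passed to [detect_mode()]
#' @return tibble `(label, mode, n, overlaps_with)`; attribute `overlaps`
#'   is a tibble of flagged pairs with their mode difference
#' @export
overlay_report <- function(dists, overlap_tol = 0.02, ...) {
  stopifnot(length(dists) >= 1)
  reports <- purrr::map(dists, detect_mode, ...)
  tab <- tibble(
    label = vapply(reports, `[[`, "", "label"),
    mode = vapply(reports, `[[`, 0, "mode"),
    n = vapply(reports, `[[`, 0L, "n")
  )
  overlaps <- tibble(label_1 = character(0), label_2 = character(0),
                     delta = numeric(0))
  if (nrow(tab) >= 2) {
    cmb <- utils::combn(nrow(tab), 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      d <- abs(tab$mode[i] - tab$mode[j])
      if (d < overlap_tol) {
        overlaps <- bind_rows(overlaps, tibble(
          label_1 = tab$label[i], label_2 = tab$label[j], delta = d
        ))
      }
    }
  }
  tab$overlaps_with <- vapply(tab$label, function(l) {
    partners <- c(overlaps$label_2[overlaps$label_1 == l],
                  overlaps$label_1[overlaps$label_2 == l])
    if (length(partners)) paste(partners, collapse = ",") else NA_character_
  }, "", USE.NAMES = FALSE)
  attr(tab, "overlaps") <- overlaps
  tab
}
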