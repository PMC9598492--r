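#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_vline geom_point
#'   geom_col labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Density plot of one or more 4DTv distributions
#'
#' @param object a `dtv_distribution` (or list of them)
#' @param ... passed to [detect_mode()]
#' @return a ggplot
#' @method autoplot dtv_distribution
#' @export
autoplot.dtv_distribution <- function(object, ...) {
  plot_dtv(list(object), ...)
}

#' @rdname autoplot.dtv_distribution
#' @param dists list of `dtv_distribution` objects
#' @export
plot_dtv <- function(dists, ...) {
  dat <- purrr::map_dfr(dists, function(d) {
    rep <- detect_mode(d, ...)
    mutate(rep$density, label = d$label, mode = rep$mode)
  })
  modes <- distinct(dat, .data$label, .data$mode)
  ggplot(dat, aes(x = .data$x, y = .data$y, colour = .data$label)) +
    geom_line() +
    geom_vline(data = modes,
               aes(xintercept = .data$mode, colour = .data$label),
               linetype = "dashed") +
    labs(x = "corrected 4DTv distance", y = "density", colour = NULL) +
    theme_minimal()
}

#' Scatter plot of the first two principal components
#'
#' @param object a `geno_pca`
#' @param groups optional factor colouring the samples (e.g. population)
#' @param ... unused
#' @return a ggplot
#' @method autoplot geno_pca
#' @export
autoplot.geno_pca <- function(object, groups = NULL, ...) {
  dat <- tidy(object, n_components = 2L)
  names(dat)[2:3] <- c("PC1", "PC2")
  if (!is.null(groups)) dat$group <- as.factor(groups)
  p <- ggplot(dat, aes(x = .data$PC1, y = .data$PC2)) +
    labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$prop_var[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$prop_var[2])
    ) +
    theme_minimal()
  if (is.null(groups)) p + geom_point()
  else p + geom_point(aes(colour = .data$group))
}

#' Stacked ancestry bar plot of an admixture fit
#'
#' @param object an `admixture_fit`
#' @param order_by cluster whose proportion orders the samples (default 1)
#' @param ... unused
#' @return a ggplot
#' @method autoplot admixture_fit
#' @export
autoplot.admixture_fit <- function(object, order_by = 1L, ...) {
  dat <- tidy(object)
  lev <- rownames(object$Q)[order(object$Q[, order_by])]
  dat$sample <- factor(dat$sample, levels = lev)
  ggplot(dat, aes(x = .data$sample, y = .data$proportion,
                  fill = .data$cluster)) +
    geom_col(width = 1) +
    labs(x = NULL, y = "ancestry proportion", fill = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Delta-K curve across K
#'
#' @param object a `deltak_report`
#' @param ... unused
#' @return a ggplot
#' @method autoplot deltak_report
#' @export
autoplot.deltak_report <- function(object, ...) {
  dat <- as_tibble(object)
  ggplot(dat[!is.na(dat$delta_k), ],
         aes(x = .data$K, y = .data$delta_k)) +
    geom_line() + geom_point() +
    geom_vline(xintercept = attr(object, "selected_k"), linetype = "dashed") +
    labs(y = expression(Delta * K)) +
    theme_minimal()
}
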