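#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's result objects: a p-value
#' heatmap for the host-genotype grid, a biplot-style score plot for PCA
#' results, a Manhattan plot for GWAS scans, and a degree-by-kingdom plot
#' for networks.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-methods
NULL

#' @rdname autoplot-methods
#' @export
autoplot.host_grid <- function(object, ...) {
  dat <- object$grid
  ggplot2::ggplot(dat, ggplot2::aes(
    x = factor(100 * .data$frac_fungi),
    y = factor(100 * .data$frac_bacteria),
    fill = .data$p_value)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(.data$p_value > 1 / (object$n_perm + 1),
                                  sprintf("%.3f", .data$p_value), "")),
      size = 2.6) +
    ggplot2::scale_fill_gradient(low = "#1b7837", high = "white",
                                 limits = c(0, 1), name = "P") +
    ggplot2::labs(x = "top % of fungal taxa", y = "top % of bacterial taxa",
                  title = sprintf("Accession clustering (first %d PCs, %d permutations)",
                                  object$n_pcs, object$n_perm)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @param pcs Pair of PCs to display (default `c(1, 2)`).
#' @export
autoplot.pca_result <- function(object, pcs = c(1, 2), ...) {
  dat <- tibble::tibble(
    x = object$scores[, pcs[1]],
    y = object$scores[, pcs[2]]
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", pcs[1],
                  100 * object$explained_fraction[pcs[1]]),
      y = sprintf("PC%d (%.1f%%)", pcs[2],
                  100 * object$explained_fraction[pcs[2]])) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @param threshold Optional genome-wide p-value threshold drawn as a line.
#' @export
autoplot.gwas_result <- function(object, threshold = NULL, ...) {
  dat <- dplyr::filter(object$snps, !is.na(.data$p_value))
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$pos / 1e6, -log10(.data$p_value),
                                         color = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](italic(P)))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed")
  }
  p
}

#' @rdname autoplot-methods
#' @export
autoplot.microbiome_network <- function(object, ...) {
  cent <- centrality(object)
  ggplot2::ggplot(cent, ggplot2::aes(.data$kingdom, .data$degree,
                                     fill = .data$kingdom)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(bacteria = "#d6604d",
                                          fungi = "#4393c3")) +
    ggplot2::labs(y = "node degree") +
    ggplot2::theme_minimal()
}
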