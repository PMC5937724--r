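#' Plot the AUC distribution of a guilt-by-association fit
#'
#' Histogram of per-term mean cross-validated AUCs with the good/optimal
#' thresholds marked.
#'
#' @param object a [gba_predict()] fit.
#' @param binwidth histogram bin width.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.gba_fit <- function(object, binwidth = 0.05, ...) {
  stopifnot(nrow(object$terms) > 0)
  ggplot2::ggplot(object$terms, ggplot2::aes(x = .data$mean_auc)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = c(object$params$good,
                                       object$params$optimal),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "mean cross-validated AUC", y = "GO terms",
                  title = "Neighbor-voting AUC across gene sets") +
    ggplot2::theme_minimal()
}

#' Bar chart of the network weight distribution
#'
#' @param histogram tibble from [weight_histogram()].
#' @return A ggplot showing edge share per weight bin.
#' @export
plot_weight_distribution <- function(histogram) {
  h <- histogram[!histogram$bin %in% c("underflow", "overflow"), ]
  ggplot2::ggplot(h, ggplot2::aes(x = factor(.data$bin, levels = .data$bin),
                                  y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "edge weight |Spearman rho|", y = "% of edges",
                  title = "Co-expression network weight distribution") +
    ggplot2::theme_minimal()
}

#' Volcano plot of the differential-expression results
#'
#' @param deg_table tibble from [call_degs()] (columns `logFC`, `fdr`,
#'   `passes`).
#' @param fdr_max,min_abs_logfc thresholds to mark.
#' @return A ggplot.
#' @export
plot_deg_volcano <- function(deg_table, fdr_max = 0.001,
                             min_abs_logfc = 2) {
  ggplot2::ggplot(deg_table,
                  ggplot2::aes(x = .data$logFC, y = -log10(.data$fdr),
                               colour = .data$passes)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(fdr_max), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * min_abs_logfc,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60"),
                                 name = "DEG") +
    ggplot2::labs(x = "log2 fold change (tumor - normal)",
                  y = "-log10 FDR") +
    ggplot2::theme_minimal()
}
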