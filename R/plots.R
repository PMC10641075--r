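#' Volcano plot of differential-activity results
#'
#' Significance against effect size for a [differential_activity()] table,
#' with guides at the FDR threshold and at an effect magnitude of interest
#' (default |log2FC| = log2(1.25), a 25% change in expression).
#'
#' @param results Tibble from [differential_activity()].
#' @param fdr FDR guide line (default 0.05).
#' @param fc_threshold Effect-magnitude guide, log2 units.
#' @returns A ggplot.
#' @export
plot_volcano <- function(results, fdr = 0.05, fc_threshold = log2(1.25)) {
  p <- ggplot2::ggplot(results,
                       ggplot2::aes(.data$log2FC, -log10(.data$p_value),
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-fc_threshold, fc_threshold),
                        linetype = "dashed", colour = "grey50")
  sig_p <- results$p_value[results$q_value < fdr]
  if (length(sig_p)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(max(sig_p)),
                                 linetype = "dashed", colour = "grey50")
  }
  p +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold-change", y = "-log10 p",
                  colour = sprintf("FDR < %.2g", fdr)) +
    ggplot2::theme_minimal()
}

#' GC-recovery profile plot
#'
#' @param gc Tibble from [gc_recovery()].
#' @returns A ggplot of mean DNA CPM per GC bin.
#' @export
plot_gc_recovery <- function(gc) {
  gc$gc_mid <- (gc$gc_lo + gc$gc_hi) / 2
  ggplot2::ggplot(gc[gc$n_elements > 0, ],
                  ggplot2::aes(.data$gc_mid, .data$mean_dna_cpm)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "element GC fraction", y = "mean DNA CPM") +
    ggplot2::theme_minimal()
}
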