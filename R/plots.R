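#' Volcano plot of differential-expression records
#'
#' log10 fold change against -log10 p, coloured by status, with the
#' class-specific thresholds drawn as dashed lines. One panel per RNA
#' class.
#'
#' @param de_records Tibble from [de_test()].
#' @param thresholds As [de_thresholds()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(de_records, thresholds = de_thresholds()) {
  dat <- de_records |> filter(!is.na(.data$p))
  cuts <- tibble(rna_class = names(thresholds$p_cut),
                 p_cut = unname(thresholds$p_cut))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log10_fc,
                                    y = -log10(.data$p),
                                    colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * thresholds$lfc_cut,
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(data = cuts,
                        ggplot2::aes(yintercept = -log10(.data$p_cut)),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$rna_class)) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b",
                                            down = "#2980b9",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log10 fold change (cold / control)",
                  y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Sample PCA plot
#'
#' @param x A `cerna_pca` from [pca_samples()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cerna_pca <- function(x, ...) {
  ve <- x$variance_explained
  ggplot2::ggplot(x$scores, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                         colour = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[2])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bubble chart of enrichment results
#'
#' Terms ranked by gene ratio, point size showing the overlap `k` and
#' colour the BH-adjusted p-value — the usual over-representation bubble
#' chart.
#'
#' @param records Tibble from [enrich_terms()] or [top_terms()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(records) {
  dat <- records |>
    mutate(term = stats::reorder(paste(.data$term_name), .data$gene_ratio))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$gene_ratio, y = .data$term,
                                    size = .data$k,
                                    colour = .data$p_adj)) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(ggplot2::vars(.data$namespace), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_colour_gradient(low = "#c0392b", high = "#2980b9") +
    ggplot2::labs(x = "gene ratio", y = NULL) +
    ggplot2::theme_minimal()
}

#' Detection-power curve
#'
#' @param power_table Tibble from [power_simulation()].
#' @return A ggplot object.
#' @export
plot_power <- function(power_table) {
  ggplot2::ggplot(power_table, ggplot2::aes(x = .data$effect,
                                            y = .data$detection_fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "planted |log10 fold change|",
                  y = "fraction detected with true direction") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
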