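#' Topographic-style z map of paired results
#'
#' Electrode-by-band tile map of the Wilcoxon z statistics for one metric
#' (negative z = increase after the intervention); FDR-significant cells are
#' outlined. A tabular stand-in for scalp colormaps that keeps the full
#' z information.
#'
#' @param table Output of [run_paired_analysis()].
#' @param metric Metric to display (e.g. `"QSE"`).
#' @param montage Electrode ordering.
#' @return A ggplot object.
#' @export
plot_zmap <- function(table, metric, montage = montage_1020()) {
  tb <- dplyr::filter(table, .data$metric == !!metric,
                      .data$feature %in% montage) |>
    dplyr::mutate(feature = factor(.data$feature, levels = rev(montage)))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$band, y = .data$feature,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(tb, .data$sig_fdr),
                       fill = NA, colour = "black", linewidth = 0.8) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "z",
                  title = paste0(metric, ": paired z map (z < 0 = increase)")) +
    ggplot2::theme_minimal()
}

#' Ordination scatter plot
#'
#' First two principal coordinates, optionally colored by condition via the
#' sample manifest.
#'
#' @param object A `gb_pcoa` from [pcoa_ord()].
#' @param manifest Optional manifest tibble (`sample`, `subject`,
#'   `condition`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot gb_pcoa
autoplot.gb_pcoa <- function(object, manifest = NULL, ...) {
  df <- object$coordinates
  lab <- sprintf("PC%d (%.1f%%)", 1:2, 100 * object$explained[1:2])
  if (!is.null(manifest)) {
    df <- dplyr::inner_join(df, manifest, by = "sample")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                          colour = .data$condition))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
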