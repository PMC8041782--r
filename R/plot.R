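# Plain ggplot2 views of the main result types: expected-vs-observed
# abundances per pool, the index-pair grid, locus overlap, and a
# sample-by-taxon abundance heatmap.

#' @importFrom ggplot2 autoplot ggplot aes
#' @export
ggplot2::autoplot

#' Expected vs observed abundance per pool
#'
#' @param object A `detection_report`.
#' @param ... Unused.
#' @return A ggplot: one panel per pool, expected and observed relative
#'   abundance side by side per taxon, FP/FN status in colour.
#' @method autoplot detection_report
#' @export
autoplot.detection_report <- function(object, ...) {
  d <- object$results |>
    tidyr::pivot_longer(c("expected_abundance", "observed_abundance"),
                        names_to = "kind", values_to = "abundance") |>
    dplyr::mutate(kind = sub("_abundance", "", .data$kind))
  ggplot(d, aes(x = .data$taxon, y = .data$abundance,
                fill = .data$kind, colour = .data$status)) +
    ggplot2::geom_col(position = "dodge", linewidth = 0.6) +
    ggplot2::scale_colour_manual(values = c(
      detected = "grey30", false_negative = "#d73027",
      false_positive = "#fc8d59")) +
    ggplot2::facet_wrap(~pool_id) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Relative abundance", fill = NULL,
                  colour = NULL)
}

#' Heatmap of the index-pair grid
#'
#' @param pairs Grid tibble from [tally_index_pairs()].
#' @return A ggplot tile map of log10 reads per (i5, i7) pair, valid pairs
#'   outlined.
#' @export
plot_index_pairs <- function(pairs) {
  ggplot(pairs, aes(x = .data$i7, y = .data$i5)) +
    ggplot2::geom_tile(aes(fill = log10(.data$reads + 1))) +
    ggplot2::geom_tile(data = dplyr::filter(pairs, .data$valid),
                       fill = NA, colour = "red", linewidth = 0.6) +
    ggplot2::scale_fill_viridis_c(name = "log10(reads + 1)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Locus-overlap bar chart
#'
#' @param overlap Tibble from [locus_overlap()].
#' @return A ggplot: labels counted per locus subset.
#' @export
plot_locus_overlap <- function(overlap) {
  ggplot(overlap, aes(x = stats::reorder(.data$loci, -.data$n), y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Detected by loci", y = "Distinct labels")
}

#' Sample-by-taxon abundance heatmap
#'
#' @param combined Tibble from [combine_loci()].
#' @return A ggplot tile map of log10 combined relative abundance.
#' @export
plot_abundance_heatmap <- function(combined) {
  d <- dplyr::filter(combined, .data$abundance > 0)
  ggplot(d, aes(x = .data$sample, y = .data$taxon,
                fill = log10(.data$abundance))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10(abundance)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL)
}
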