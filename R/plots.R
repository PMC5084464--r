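#' Plot the per-release growth of the compendium
#'
#' Transcript and gene counts per release, with the transcribed-genome
#' percentage on a free secondary panel when available.
#'
#' @param growth Output of [growth_table()].
#' @return A ggplot object.
#' @export
plot_growth <- function(growth) {
  long <- growth |>
    dplyr::mutate(release = factor(.data$release, levels = .data$release)) |>
    tidyr::pivot_longer(c("n_transcripts", "n_genes", "pct_transcribed"),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$release, y = .data$value,
                                     group = .data$metric,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "release", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none",
                   axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot the biotype presence/absence heatmap
#'
#' @param comp A `compendium`.
#' @return A ggplot object (tiles: biotype x release presence).
#' @export
plot_presence <- function(comp) {
  pm <- presence_matrix(comp)$presence
  long <- pm |>
    tidyr::pivot_longer(-c("biotype", "code"), names_to = "release",
                        values_to = "present") |>
    dplyr::mutate(release = factor(.data$release, levels = comp$labels))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$release, y = .data$biotype,
                                     fill = .data$present)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "white"),
                               guide = "none") +
    ggplot2::labs(x = "release", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot a Sankey flow as a stacked state-composition chart
#'
#' A faithful ribboned Sankey needs an interactive canvas; for a static
#' overview this draws the per-release state composition (node sizes), which
#' shares its data with the exported nodes/links tables.
#'
#' @param flow A `sankey_flow`.
#' @return A ggplot object.
#' @export
plot_sankey <- function(flow) {
  nodes <- flow$nodes |>
    dplyr::mutate(release = factor(.data$release,
                                   levels = unique(.data$release)))
  ggplot2::ggplot(nodes, ggplot2::aes(x = .data$release, y = .data$size,
                                      fill = .data$state,
                                      group = .data$state)) +
    ggplot2::geom_area(position = "stack", alpha = 0.85) +
    ggplot2::labs(x = "release", y = "transcripts", fill = "state") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
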