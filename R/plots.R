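#' Volcano plot of a differential-abundance result
#'
#' Log2 fold change (positive = higher in skin biopsy) against -log10 FDR,
#' colored by call direction.
#'
#' @param object A `de_result` from [run_contrast()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_result <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(.data$log2_fc, -log10(.data$fdr),
                                    colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      biopsy_higher = "#2166ac", plucked_higher = "#b2182b", none = "grey70"
    )) +
    ggplot2::labs(
      x = "log2 fold change (biopsy / plucked)",
      y = "-log10 FDR",
      colour = NULL,
      title = object$contrast
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.de_result
#' @export
plot_volcano <- function(object, ...) autoplot.de_result(object, ...)

#' Marker-direction plot of a cell-enrichment result
#'
#' One bar per population showing how many of its markers are higher in each
#' source; the fill encodes direction and the label the resulting call.
#'
#' @param object A `cell_enrichment` from [project_markers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cell_enrichment <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$calls,
    c("n_biopsy_higher", "n_plucked_higher"),
    names_to = "direction", values_to = "n"
  ) |>
    mutate(direction = ifelse(.data$direction == "n_biopsy_higher",
                              "higher in biopsy", "higher in plucked"))
  ggplot2::ggplot(long, ggplot2::aes(.data$population, .data$n, fill = .data$direction)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::geom_text(
      data = object$calls,
      ggplot2::aes(.data$population, .data$n_markers, label = .data$call),
      inherit.aes = FALSE, vjust = -0.3, size = 3
    ) +
    ggplot2::scale_fill_manual(values = c(
      "higher in biopsy" = "#2166ac", "higher in plucked" = "#b2182b"
    )) +
    ggplot2::labs(x = NULL, y = "marker genes", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname autoplot.cell_enrichment
#' @export
plot_enrichment <- function(object, ...) autoplot.cell_enrichment(object, ...)
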