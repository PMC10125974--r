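# ggplot2 displays for the main result types.

#' Plot chemical ratio profiles coloured by category
#'
#' Scatter of foci-intensity vs nuclei ratios with the category calls,
#' summarising the screen the way the category definitions read: hypo
#' agents lower-right (foci down, nuclei up), hyper agents upper-left.
#'
#' @param table Screen ratio tibble.
#' @param categories Tibble from [assign_categories()].
#' @return A ggplot object.
#' @export
plot_screen_categories <- function(table, categories) {
  df <- dplyr::left_join(table, categories, by = "chemical_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nuclei, y = .data$foci_intensity,
                                   colour = .data$category)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(A = "#2e7d32", B = "#c62828", C = "grey45"),
      na.value = "grey80") +
    ggplot2::labs(x = "nuclei ratio to control",
                  y = "foci intensity ratio to control",
                  colour = "category") +
    ggplot2::theme_minimal()
}

#' Bar chart of the top-ranked activities for one imaging parameter
#'
#' @param importance An `igem_importance` from [rf_importance()].
#' @param top_n Number of activities shown (defaults to the stored 30).
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, top_n = NULL) {
  stopifnot(inherits(importance, "igem_importance"))
  top_n <- top_n %||% attr(importance, "top_n")
  df <- utils::head(dplyr::arrange(importance, .data$rank), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$activity, .data$importance))) +
    ggplot2::geom_col(fill = "#455a64") +
    ggplot2::labs(x = "increase in node purity", y = NULL,
                  title = paste("response:", attr(importance, "response"))) +
    ggplot2::theme_minimal()
}

#' Stacked genome-context distribution of called sites per treatment
#'
#' @param region Long region tibble (columns `treatment`, `axis`, `level`,
#'   `proportion`) as written by the pipeline's methylome stage.
#' @param axis `"cpg_context"` or `"refgene_group"`.
#' @return A ggplot object.
#' @export
plot_region_distribution <- function(region, axis = "cpg_context") {
  df <- dplyr::filter(region, .data$axis == !!axis)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$treatment,
                                   y = .data$proportion,
                                   fill = .data$level)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "proportion of called sites", fill = axis) +
    ggplot2::theme_minimal()
}

#' Scatter of a t-SNE embedding
#'
#' @param embedding Tibble from [tsne_embed()].
#' @return A ggplot object.
#' @export
plot_tsne <- function(embedding) {
  ggplot2::ggplot(embedding, ggplot2::aes(x = .data$tsne1, y = .data$tsne2,
                                          label = .data$sample)) +
    ggplot2::geom_point(colour = "#455a64") +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
}
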