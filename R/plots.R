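#' Heatmap of a directional proximity matrix
#'
#' @param object A `proximity_matrix`.
#' @param ... Unused.
#' @return A ggplot: source types in rows, target types in columns.
#' @method autoplot proximity_matrix
#' @export
autoplot.proximity_matrix <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$target_type,
                                 y = .data$source_type,
                                 fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = "target cell type", y = "source cell type",
                  fill = "proximity",
                  title = sprintf("Directional spatial proximity (bw = %g um%s)",
                                  object$bandwidth_um,
                                  if (object$normalized) ", normalized" else "")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of one ligand-receptor pair's scores across all directions
#'
#' @param object An `lr_score_result`.
#' @param pair_id Pair to display (default: the first pair).
#' @param ... Unused.
#' @return A ggplot tile map, source types x target types.
#' @method autoplot lr_score_result
#' @export
autoplot.lr_score_result <- function(object, pair_id = NULL, ...) {
  pair_id <- pair_id %||% object$pair_id[1]
  df <- dplyr::filter(tibble::as_tibble(object), .data$pair_id == !!pair_id)
  if (nrow(df) == 0) stop("pair_id '", pair_id, "' not in result", call. = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target_type,
                                   y = .data$source_type,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(title = paste("Spatial LR score:", pair_id),
                  x = "target cell type", y = "source cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of the top ligand-receptor pairs for one direction
#'
#' @param result An `lr_score_result`.
#' @param source_type,target_type Direction to rank.
#' @param top_n Pairs shown (default 20).
#' @return A ggplot horizontal bar chart, highest score on top.
#' @export
plot_lr_ranking <- function(result, source_type, target_type, top_n = 20) {
  rank_lr_pairs(result, source_type, target_type, top_n) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$score,
                                 y = stats::reorder(.data$pair_id,
                                                    .data$score))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(title = paste0("Top LR pairs: ", source_type, " → ",
                                 target_type),
                  x = "spatial LR score", y = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked composition bars for a niche model
#'
#' @param object A `niche_model`.
#' @param ... Unused.
#' @return A ggplot of each niche's centroid cell-type composition.
#' @method autoplot niche_model
#' @export
autoplot.niche_model <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$niche,
                                 y = .data$center_proportion,
                                 fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "neighborhood proportion",
                  fill = "cell type") +
    ggplot2::theme_minimal()
}

#' Histogram of per-cell distances or neighbor counts
#'
#' @param object A `spax_distances` result.
#' @param ... Unused.
#' @return A ggplot histogram of the per-cell values.
#' @method autoplot spax_distances
#' @export
autoplot.spax_distances <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$value)),
                  ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue") +
    ggplot2::labs(x = attr(object, "measure"), y = "cells") +
    ggplot2::theme_minimal()
}

#' Spatial map of cells colored by type or niche
#'
#' @param cells Validated cell table; an optional `niche` column (e.g.
#'   joined from a niche model) can be used as the color.
#' @param color Column to color by (default `"cell_type"`).
#' @return A ggplot scatter map, faceted by FOV.
#' @export
plot_cells <- function(cells, color = "cell_type") {
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                      color = .data[[color]])) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~ fov_id, scales = "free") +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}
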