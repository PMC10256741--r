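#' Distribution of the five language metrics by phenotype
#'
#' Violin + boxplot panels of each metric within each phenotype group.
#'
#' @param features Feature table with `subject_id`.
#' @param phenotype Tibble with `subject_id` and `phenotype`.
#' @return A ggplot object.
#' @export
plot_feature_groups <- function(features, phenotype) {
  dat <- dplyr::left_join(features, phenotype, by = "subject_id") |>
    tidyr::pivot_longer(-c("subject_id", "phenotype"),
                        names_to = "metric", values_to = "value")
  dat$phenotype <- factor(dat$phenotype, levels = PHENOTYPE_LEVELS)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$phenotype, y = .data$value,
                                    fill = .data$phenotype)) +
    ggplot2::geom_violin(alpha = 0.5, colour = NA) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.4) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Gradient-by-network grid of typicality t statistics
#'
#' Tile plot of the post-hoc t statistic per (gradient, network) cell;
#' cells surviving Bonferroni correction are starred.
#'
#' @param grid Result of [asymmetry_ancova()].
#' @return A ggplot object.
#' @export
plot_asymmetry_grid <- function(grid) {
  grid$network <- factor(grid$network, levels = CANONICAL_NETWORKS)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$gradient, y = .data$network,
                                     fill = .data$t_statistic)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$significant, "*", "")), size = 6) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", high = "#B2182B",
                                  mid = "white", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "t") +
    ggplot2::theme_minimal()
}

#' Gradient-by-network grid of heritability estimates
#'
#' @param grid Result of [heritability_grid()] (gradient-asymmetry rows).
#' @return A ggplot object.
#' @export
plot_heritability_grid <- function(grid) {
  grid <- grid[grid$trait == "gradient_asymmetry", ]
  grid$network <- factor(grid$network, levels = CANONICAL_NETWORKS)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$gradient, y = .data$network,
                                     fill = .data$h2)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$significant, "*", "")), size = 6) +
    ggplot2::scale_fill_gradient(low = "white", high = "#B2182B",
                                 limits = c(0, NA)) +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(h^2)) +
    ggplot2::theme_minimal()
}

#' Dendrogram-style merge-height profile of a clustering
#'
#' @param object A `langlat_clust`.
#' @param ... Unused.
#' @return A ggplot object showing the last merge heights.
#' @method autoplot langlat_clust
#' @export
autoplot.langlat_clust <- function(object, ...) {
  h <- object$merge_heights
  dat <- tibble::tibble(merge = seq_along(h), height = h)
  ggplot2::ggplot(utils::tail(dat, 20),
                  ggplot2::aes(x = .data$merge, y = .data$height)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "agglomeration step", y = "Ward merge height") +
    ggplot2::theme_minimal()
}
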