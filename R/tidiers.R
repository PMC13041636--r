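# broom-style accessors and ggplot2 autoplot methods for fitted objects.

#' Tidy a genotype PCA
#' @param x A [genotype_pca()] result.
#' @param ... Unused.
#' @return Sample coordinates as a tibble.
#' @export
tidy.genotype_pca <- function(x, ...) x$scores

#' @rdname tidy.genotype_pca
#' @export
glance.genotype_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_markers_used = x$n_markers_used,
    pc1_var_explained = unname(x$var_explained["PC1"]),
    pc2_var_explained = unname(x$var_explained["PC2"])
  )
}

#' Tidy a relationship-class PCA
#' @param x A [classify_relationships()] result.
#' @param ... Unused.
#' @return Pair coordinates as a tibble.
#' @export
tidy.relationship_pca <- function(x, ...) x$pairs

#' @rdname tidy.relationship_pca
#' @export
glance.relationship_pca <- function(x, ...) {
  tibble::tibble(
    n_active_pairs = sum(!x$pairs$supplementary),
    n_supplementary_pairs = sum(x$pairs$supplementary),
    pc1_var_explained = unname(x$var_explained["PC1"]),
    pc2_var_explained = unname(x$var_explained["PC2"])
  )
}

#' Plot a genotype PCA
#'
#' @param object A [genotype_pca()] result.
#' @param data Optional tibble with `sample_id` and a grouping column.
#' @param colour Name of the grouping column in `data`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genotype_pca <- function(object, data = NULL, colour = "species", ...) {
  df <- object$scores
  if (!is.null(data)) {
    df <- dplyr::left_join(df, data, by = "sample_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained["PC1"]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained["PC2"])
    ) +
    ggplot2::theme_minimal()
  if (!is.null(data) && colour %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), alpha = 0.8)
  } else {
    p + ggplot2::geom_point(alpha = 0.8)
  }
}

#' Plot a relationship-class PCA
#'
#' Active relationship classes are drawn as filled points; supplementary
#' (OTHER) pairs as hollow points on the same coordinate system.
#'
#' @param object A [classify_relationships()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.relationship_pca <- function(object, ...) {
  df <- object$pairs
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$class)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$supplementary), alpha = 0.8) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained["PC1"]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained["PC2"]),
      shape = "supplementary"
    ) +
    ggplot2::theme_minimal()
}

#' Plot observed heterozygosity by species
#'
#' @param het_summary Output of [species_het_summary()].
#' @return A ggplot object.
#' @export
plot_species_het <- function(het_summary) {
  ggplot2::ggplot(
    het_summary,
    ggplot2::aes(
      x = stats::reorder(.data$species, .data$mean_obs_het),
      y = .data$mean_obs_het
    )
  ) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$min_obs_het, ymax = .data$max_obs_het)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "observed heterozygosity") +
    ggplot2::theme_minimal()
}
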