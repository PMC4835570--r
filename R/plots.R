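#' Plot a classified UPGMA dendrogram
#'
#' Segment-based dendrogram with leaves coloured by multifunctional class;
#' the y axis is Euclidean distance in standardized variable space.
#'
#' @param object A `multifunc_classification`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot multifunc_classification
#' @export
autoplot.multifunc_classification <- function(object, ...) {
  tree <- object$tree
  n <- length(tree$order)
  leaf_x <- setNames(seq_len(n), tree$order)
  pos <- function(node) {
    if (node < 0) c(x = unname(leaf_x[as.character(-node)]), h = 0)
    else node_pos[[node]]
  }
  node_pos <- vector("list", n - 1)
  segs <- list()
  for (k in seq_len(n - 1)) {
    a <- pos(tree$merge[k, 1]); b <- pos(tree$merge[k, 2])
    h <- tree$height[k]
    node_pos[[k]] <- c(x = (a["x"] + b["x"]) / 2, h = h)
    segs[[k]] <- tibble(
      x = c(a["x"], b["x"], a["x"]), xend = c(a["x"], b["x"], b["x"]),
      y = c(a["h"], b["h"], h), yend = c(h, h, h)
    )
  }
  leaves <- tibble(
    x = seq_len(n),
    label = tree$labels[tree$order],
    class = object$classes$class[match(tree$labels[tree$order],
                                       object$classes$composite_id)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = bind_rows(segs),
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = -0.02,
                                    label = .data$label,
                                    colour = .data$class),
                       angle = 90, hjust = 1, size = 3) +
    ggplot2::scale_y_continuous("Euclidean distance") +
    ggplot2::labs(colour = "Class", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' PCA biplot with the equilibrium circle of descriptors
#'
#' @param object A `soil_pca` object.
#' @param axes Which two axes to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot soil_pca
#' @export
autoplot.soil_pca <- function(object, axes = c(1, 2), ...) {
  sc <- object$scores
  ax <- paste0("PC", axes)
  load <- object$loadings
  circle <- tibble(theta = seq(0, 2 * pi, length.out = 200)) |>
    mutate(x = object$equilibrium_radius * cos(.data$theta),
           y = object$equilibrium_radius * sin(.data$theta))
  ggplot2::ggplot() +
    ggplot2::geom_path(data = circle,
                       ggplot2::aes(.data$x, .data$y), linetype = 2) +
    ggplot2::geom_segment(data = load,
                          ggplot2::aes(x = 0, y = 0,
                                       xend = .data[[ax[1]]],
                                       yend = .data[[ax[2]]]),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "grey40") +
    ggplot2::geom_text(data = load,
                       ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]],
                                    label = .data$variable),
                       vjust = -0.6, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", ax[1], 100 * object$prop_variance[axes[1]]),
      y = sprintf("%s (%.1f%%)", ax[2], 100 * object$prop_variance[axes[2]])
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of indicator OTU abundances by class
#'
#' Class-ordered samples against the significant indicator OTUs.
#'
#' @param results Tibble from [indval()] / [select_representatives()].
#' @param data Wide OTU tibble.
#' @param classes Tibble (`composite_id`, `class`).
#' @return A ggplot.
#' @export
plot_indicator_heatmap <- function(results, data, classes) {
  sig <- results |> filter(.data$significant)
  m <- otu_counts(data)
  long <- as_tibble(m[, sig$otu_id, drop = FALSE]) |>
    mutate(composite_id = rownames(m)) |>
    tidyr::pivot_longer(-"composite_id", names_to = "otu_id",
                        values_to = "count") |>
    left_join(classes, by = "composite_id") |>
    left_join(sig |> select("otu_id", indicator_class = "class"),
              by = "otu_id")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = stats::reorder(.data$composite_id,
                                                  .data$class),
                               y = stats::reorder(.data$otu_id,
                                                  .data$indicator_class),
                               fill = log10(.data$count + 1))) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(~ .data$class, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_viridis_c(name = "log10(count+1)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}
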