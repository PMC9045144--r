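#' Plot an ordination
#'
#' Scatter of the first two principal coordinates, with axis labels
#' carrying the proportion of (positive-eigenvalue) variance explained.
#'
#' @param object `pcoa_result`.
#' @param colour_by Optional vector (or single-column data frame) of
#'   sample annotations, in coordinate order, mapped to colour.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pcoa_result
#' @export
autoplot.pcoa_result <- function(object, colour_by = NULL, ...) {
  df <- object$coordinates
  if (ncol(df) < 3) abort("need at least 2 axes to plot; rerun pcoa() with n_axes >= 2")
  lab <- function(i) sprintf("Axis %d (%.1f%%)", i,
                             100 * object$proportion_explained[i])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis1, y = .data$Axis2))
  if (!is.null(colour_by)) {
    df$colour_by <- if (is.data.frame(colour_by)) colour_by[[1]] else colour_by
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis1, y = .data$Axis2,
                                          colour = .data$colour_by)) +
      ggplot2::labs(colour = NULL)
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}

#' Plot the silhouette model-selection trace
#'
#' Mean silhouette width against the candidate number of clusters, with
#' the selected k marked.
#'
#' @param object `cst_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cst_result
#' @export
autoplot.cst_result <- function(object, ...) {
  df <- object$silhouette_by_k
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$mean_silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters k", y = "mean silhouette width") +
    ggplot2::theme_minimal()
}

#' Plot a co-occurrence network
#'
#' Nodes placed by the Fruchterman-Reingold layout (seeded, so the figure
#' is reproducible), sized by mean relative abundance, optionally coloured
#' by module; edges coloured by correlation sign in the field's
#' green/positive, red/negative convention.
#'
#' @param object `cooccur_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cooccur_network
#' @export
autoplot.cooccur_network <- function(object, seed = 1L, ...) {
  g <- as_igraph(object)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- object$nodes
  nodes$x <- xy[, 1]
  nodes$y <- xy[, 2]
  p <- ggplot2::ggplot()
  if (nrow(object$edges) > 0) {
    ed <- object$edges
    ed$x <- nodes$x[match(ed$taxon_a, nodes$species)]
    ed$y <- nodes$y[match(ed$taxon_a, nodes$species)]
    ed$xend <- nodes$x[match(ed$taxon_b, nodes$species)]
    ed$yend <- nodes$y[match(ed$taxon_b, nodes$species)]
    p <- p + ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$sign),
      alpha = 0.6) +
      ggplot2::scale_colour_manual(
        values = c(positive = "darkgreen", negative = "firebrick"))
  }
  aes_nodes <- if (all(is.na(nodes$module))) {
    ggplot2::aes(x = .data$x, y = .data$y, size = .data$mean_abundance)
  } else {
    ggplot2::aes(x = .data$x, y = .data$y, size = .data$mean_abundance,
                 fill = factor(.data$module))
  }
  p + ggplot2::geom_point(data = nodes, aes_nodes, shape = 21) +
    ggplot2::labs(size = "mean abundance", fill = "module") +
    ggplot2::theme_void()
}
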