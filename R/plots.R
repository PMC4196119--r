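## ggplot2 autoplot methods for the result objects.

#' @describeIn elbow_select Plot the length/error trade-off with the two
#'   fitted arms and the selected intersection.
#' @param object An `elbow_selection`.
#' @method autoplot elbow_selection
#' @export
autoplot.elbow_selection <- function(object, ...) {
  rec <- tidy(object)
  abline_df <- tibble(arm = c("left", "right"),
                      intercept = c(object$left_coef[1L], object$right_coef[1L]),
                      slope = c(object$left_coef[2L], object$right_coef[2L]))
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$curve_length, y = .data$fitting_error)) +
    ggplot2::geom_abline(data = abline_df,
                         ggplot2::aes(intercept = .data$intercept,
                                      slope = .data$slope, color = .data$arm),
                         linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$selected), size = 2) +
    ggplot2::geom_vline(xintercept = object$length_star, linetype = 3) +
    ggplot2::labs(x = "curve length", y = "fitting error",
                  title = sprintf("Elbow selection: L* = %.3g, sigma = %.3g",
                                  object$length_star, object$sigma)) +
    ggplot2::theme_minimal()
}

#' @describeIn km_curve Step plot of the survival function.
#' @param object A `km_estimate`.
#' @method autoplot km_estimate
#' @export
autoplot.km_estimate <- function(object, ...) {
  tab <- dplyr::bind_rows(tibble(time = 0, survival = 1), object$table)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (years)", y = "S(t)") +
    ggplot2::theme_minimal()
}

#' @describeIn spectral_cluster Scatter of the first two embedding
#'   coordinates colored by cluster.
#' @param object A `clustering_result`.
#' @param ... Unused.
#' @method autoplot clustering_result
#' @export
autoplot.clustering_result <- function(object, ...) {
  Y <- object$embedding$Y
  df <- tibble(y1 = Y[, 1L], y2 = if (ncol(Y) > 1L) Y[, 2L] else 0,
               cluster = factor(object$labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y1, y = .data$y2,
                                   color = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "embedding 1", y = "embedding 2") +
    ggplot2::theme_minimal()
}

#' @describeIn build_tree Tree layout with node size proportional to cluster
#'   size and edge length labels.
#' @param object A `progression_tree`.
#' @method autoplot progression_tree
#' @export
autoplot.progression_tree <- function(object, ...) {
  lay <- igraph::layout_as_tree(object$graph,
                                root = which(igraph::V(object$graph)$name ==
                                               as.character(object$root)))
  nodes <- dplyr::mutate(object$nodes,
                         x = lay[, 1L], y = lay[, 2L],
                         role = ifelse(.data$cluster == object$root, "root", "cluster"))
  name2idx <- stats::setNames(seq_len(nrow(nodes)), nodes$cluster)
  edges <- dplyr::mutate(object$edges,
                         x = nodes$x[name2idx[as.character(.data$from)]],
                         y = nodes$y[name2idx[as.character(.data$from)]],
                         xend = nodes$x[name2idx[as.character(.data$to)]],
                         yend = nodes$y[name2idx[as.character(.data$to)]])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$size, color = .data$role)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$cluster), vjust = -1.2) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::theme_void()
}

#' @describeIn fit_gene_trajectory Normalized expression against arc length
#'   with the fitted polynomial.
#' @param object A `trajectory_fit`.
#' @method autoplot trajectory_fit
#' @export
autoplot.trajectory_fit <- function(object, ...) {
  grid <- seq(min(object$coords), max(object$coords), length.out = 200)
  df <- tibble(coord = object$coords, y = object$y)
  fit <- tibble(coord = grid, y = predict(object, grid))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coord, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = fit, color = "red") +
    ggplot2::labs(x = "arc length", y = "normalized expression") +
    ggplot2::theme_minimal()
}

#' @describeIn pca_view Scatter of the first two principal components.
#' @param object A `pca_view`.
#' @method autoplot pca_view
#' @export
autoplot.pca_view <- function(object, ...) {
  df <- tibble(pc1 = object$coordinates[, 1L],
               pc2 = object$coordinates[, min(2L, ncol(object$coordinates))])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "PC1", y = "PC2",
                  title = sprintf("%.1f%% of variance in %d components",
                                  100 * object$variance_fraction,
                                  ncol(object$coordinates))) +
    ggplot2::theme_minimal()
}
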