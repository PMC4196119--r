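## broom-style tidiers for the package's result objects.

#' @describeIn fit_feature_weights Tidy the fitted weights: one row per
#'   feature with `weight` and a `selected` flag at the fitted tau.
#' @param x A `feature_weights` object.
#' @param tau Selection threshold, defaulting to the fitted configuration's.
#' @param ... Unused.
#' @method tidy feature_weights
#' @export
tidy.feature_weights <- function(x, tau = NULL, ...) {
  tau <- tau %||% x$tau
  out <- tibble(feature = names(x$w) %||% as.character(seq_along(x$w)),
                weight = unname(x$w), selected = unname(x$w) > tau)
  if (!is.null(x$feature_source)) out$source <- x$feature_source
  out
}

#' @describeIn fit_feature_weights One-row fit summary.
#' @method glance feature_weights
#' @export
glance.feature_weights <- function(x, ...) {
  tibble(lambda = x$lambda, kernel_width = x$kernel_width,
         n_features = length(x$w), n_selected = sum(x$w > x$tau),
         l1_norm = sum(x$w), objective = x$objective,
         n_iter = x$n_iter, converged = x$converged)
}

#' @describeIn spectral_cluster Per-sample tidy table: cluster label and
#'   silhouette width.
#' @param x A `clustering_result`.
#' @param ... Unused.
#' @method tidy clustering_result
#' @export
tidy.clustering_result <- function(x, ...) {
  tibble(sample_id = x$sample_ids %||% as.character(seq_along(x$labels)),
         cluster = x$labels, silhouette = x$silhouette$width)
}

#' @describeIn spectral_cluster One-row clustering summary.
#' @method glance clustering_result
#' @export
glance.clustering_result <- function(x, ...) {
  tibble(C = x$C, n = length(x$labels),
         mean_silhouette = mean(x$silhouette$width),
         n_stable = sum(x$clusters$stable),
         frac_positive = mean(x$silhouette$width > 0))
}

#' @describeIn em_fit Tidy node table: node id, mixing weight, arc length
#'   from the root and position coordinates.
#' @param x A `principal_curve_model`.
#' @param ... Unused.
#' @method tidy principal_curve_model
#' @export
tidy.principal_curve_model <- function(x, ...) {
  dplyr::bind_cols(tibble(node = seq_len(x$topology$n_nodes), p = x$p,
                          arc_length = node_arc_lengths(x)),
                   as_tibble(x$mu, .name_repair = ~ paste0("dim", seq_along(.x))))
}

#' @describeIn em_fit One-row model summary.
#' @method glance principal_curve_model
#' @export
glance.principal_curve_model <- function(x, ...) {
  tibble(n_nodes = x$topology$n_nodes, sigma = x$sigma,
         curve_length = curve_length(x), loglik = x$loglik,
         n_iter = x$n_iter, converged = x$converged)
}

#' @describeIn build_tree Per-sample assignment table of the tree.
#' @param x A `progression_tree`.
#' @param ... Unused.
#' @method tidy progression_tree
#' @export
tidy.progression_tree <- function(x, ...) x$samples

#' @describeIn build_tree One-row tree summary.
#' @method glance progression_tree
#' @export
glance.progression_tree <- function(x, ...) {
  tibble(n_clusters = nrow(x$nodes), n_samples = sum(x$nodes$size),
         n_edges = nrow(x$edges), root = x$root,
         n_leaves = length(tree_leaves(x)),
         n_dropped = nrow(x$dropped))
}

#' @describeIn km_curve Tidy life table.
#' @param x A `km_estimate`.
#' @param ... Unused.
#' @method tidy km_estimate
#' @export
tidy.km_estimate <- function(x, ...) x$table

#' @describeIn elbow_select Tidy the sorted records with the fitted arm
#'   assignment.
#' @param x An `elbow_selection`.
#' @param ... Unused.
#' @method tidy elbow_selection
#' @export
tidy.elbow_selection <- function(x, ...) {
  rec <- rec0 <- x$records
  rec$arm <- ifelse(seq_len(nrow(rec0)) <= x$breakpoint, "left", "right")
  rec$selected <- seq_len(nrow(rec0)) == x$selected
  rec
}

#' @describeIn elbow_select One-row selection summary.
#' @method glance elbow_selection
#' @export
glance.elbow_selection <- function(x, ...) {
  tibble(sigma = x$sigma, length_star = x$length_star,
         breakpoint = x$breakpoint,
         left_slope = x$left_coef[2L], right_slope = x$right_coef[2L])
}
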