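## Two-pronged progression model: the principal curve is the backbone, the
## clusters are the nodes. Curve nodes are labeled by the cluster whose samples
## project nearest them, runs of equally labeled nodes are contracted, and the
## surviving adjacencies become the edges of a cluster-level progression tree
## on which covariates, gene trajectories and survival are mapped.

#' Build the cluster-level progression tree on the curve backbone
#'
#' Clusters below `min_cluster_size` are dropped (the omission rule for tiny
#' clusters). Every curve node is assigned to the cluster owning the plurality
#' of samples whose projection lands nearest that node; unclaimed nodes
#' inherit the label of the nearest claimed node along the tree. If a cluster
#' claims several disconnected regions of the backbone, the largest region
#' keeps the label (with a warning). Consecutive equally labeled nodes are
#' contracted; surviving adjacencies become tree edges whose length is the
#' Euclidean distance between cluster centroids.
#'
#' @param labels Integer cluster labels aligned with rows of `X` (or a
#'   `clustering_result`).
#' @param model A fitted `principal_curve_model` (root designated; see
#'   [designate_root()]).
#' @param X The data matrix or [sample_matrix()] the clustering and curve were
#'   fitted on.
#' @param projections Optional precomputed [project_samples()] table.
#' @param min_cluster_size Minimum retained cluster size, default 5.
#' @param baseline Optional baseline sample ids; the root cluster is the one
#'   holding most of them (default: the cluster of the curve's root node).
#' @return An object of class `progression_tree`: tibbles `nodes` (cluster,
#'   size, mean silhouette placeholder-free) and `edges` (from, to, length),
#'   the cluster `centroids`, igraph `graph`, `root`, per-sample assignment
#'   table `samples` (cluster, nearest node, arc length), and `dropped`
#'   clusters.
#' @export
build_tree <- function(labels, model, X, projections = NULL,
                       min_cluster_size = 5, baseline = NULL) {
  if (inherits(labels, "clustering_result")) labels <- labels$labels
  Xm <- as_values_matrix(X)
  if (length(labels) != nrow(Xm)) stopf("labels must match rows of X")
  projections <- projections %||% project_samples(Xm, model)
  sizes <- table(labels)
  small <- as.integer(names(sizes))[sizes < min_cluster_size]
  if (length(small))
    message(sprintf("omitting %d cluster(s) below min size %d: %s",
                    length(small), min_cluster_size,
                    paste(small, collapse = ", ")))
  keep <- !(labels %in% small)
  if (!any(keep)) stopf("no clusters survive the size filter")
  lab <- labels[keep]
  proj <- projections[keep, ]
  ids <- rownames(Xm)[keep] %||% as.character(which(keep))

  M <- model$topology$n_nodes
  g_curve <- model$topology$graph
  ## plurality vote per curve node (ties -> smaller cluster id)
  node_lab <- rep(NA_integer_, M)
  votes <- table(factor(proj$nearest_node, levels = seq_len(M)), lab)
  has <- rowSums(votes) > 0
  node_lab[has] <- as.integer(colnames(votes))[apply(votes[has, , drop = FALSE],
                                                     1L, which.max)]
  ## propagate labels to unclaimed nodes along the tree
  adj <- igraph::as_adj_list(g_curve)
  while (anyNA(node_lab)) {
    na_idx <- which(is.na(node_lab))
    filled <- FALSE
    for (v in na_idx) {
      nb <- setdiff(node_lab[adj[[v]]], NA_integer_)
      if (length(nb)) { node_lab[v] <- min(nb); filled <- TRUE }
    }
    if (!filled) stopf("could not propagate cluster labels over the backbone")
  }
  ## enforce one connected region per cluster
  for (c in unique(node_lab)) {
    vs <- which(node_lab == c)
    comp <- igraph::components(igraph::induced_subgraph(g_curve, vs))
    if (comp$no > 1L) {
      warnf("cluster %d occupies %d disconnected backbone regions; keeping the largest",
            c, comp$no)
      keep_comp <- which.max(comp$csize)
      lose <- vs[comp$membership != keep_comp]
      node_lab[lose] <- NA_integer_
      while (anyNA(node_lab)) {
        for (v in which(is.na(node_lab))) {
          nb <- setdiff(node_lab[adj[[v]]], c(NA_integer_, c))
          if (length(nb)) node_lab[v] <- min(nb)
        }
      }
    }
  }
  ## contract runs of equal labels into cluster-level edges
  e <- model$topology$edges
  cl_edges <- unique(t(apply(cbind(node_lab[e[, 1L]], node_lab[e[, 2L]]), 1L,
                             sort)))
  cl_edges <- cl_edges[cl_edges[, 1L] != cl_edges[, 2L], , drop = FALSE]
  clusters <- sort(unique(node_lab))
  centroids <- do.call(rbind, lapply(clusters, function(c)
    colMeans(Xm[keep, , drop = FALSE][lab == c, , drop = FALSE])))
  rownames(centroids) <- clusters
  edge_len <- sqrt(rowSums((centroids[as.character(cl_edges[, 1L]), , drop = FALSE] -
                              centroids[as.character(cl_edges[, 2L]), , drop = FALSE])^2))
  g_tree <- igraph::graph_from_data_frame(
    data.frame(from = cl_edges[, 1L], to = cl_edges[, 2L], length = edge_len),
    directed = FALSE,
    vertices = data.frame(name = clusters))
  if (!igraph::is_tree(g_tree))
    warnf("contracted cluster graph is not a tree; downstream paths may be ambiguous")
  root <- if (!is.null(baseline)) {
    bl <- ids %in% baseline
    if (!any(bl)) stopf("no baseline sample found among retained samples")
    as.integer(names(which.max(table(lab[bl]))))
  } else node_lab[model$root]
  message(sprintf("progression tree rooted at cluster %d", root))
  samples <- tibble(sample_id = ids, cluster = lab,
                    nearest_node = proj$nearest_node,
                    arc_length = proj$arc_length)
  structure(list(nodes = tibble(cluster = clusters,
                                size = as.integer(table(factor(lab, levels = clusters)))),
                 edges = tibble(from = cl_edges[, 1L], to = cl_edges[, 2L],
                                length = edge_len),
                 centroids = centroids, graph = g_tree, root = root,
                 samples = samples,
                 dropped = tibble(cluster = small,
                                  size = as.integer(sizes[as.character(small)]))),
            class = "progression_tree")
}

#' @export
print.progression_tree <- function(x, ...) {
  cat(sprintf("<progression_tree> %d clusters (%d samples), root %d, %d edge(s), %d leaf/leaves\n",
              nrow(x$nodes), sum(x$nodes$size), x$root, nrow(x$edges),
              length(tree_leaves(x))))
  invisible(x)
}

#' Leaves of a progression tree
#'
#' Degree-one clusters other than the root: the tips of the progression paths.
#'
#' @param tree A [build_tree()] result.
#' @return Integer vector of leaf cluster ids.
#' @export
tree_leaves <- function(tree) {
  deg <- igraph::degree(tree$graph)
  leaves <- as.integer(igraph::V(tree$graph)$name[deg == 1L])
  setdiff(leaves, tree$root)
}

#' Bifurcation nodes of a progression tree
#'
#' Clusters with at least two children in the tree rooted at the designated
#' root — the points where progression paths diverge. A root from which two
#' paths emanate is itself a bifurcation node.
#'
#' @param tree A [build_tree()] result.
#' @return Integer vector of bifurcating cluster ids.
#' @export
tree_bifurcations <- function(tree) {
  root_v <- which(igraph::V(tree$graph)$name == as.character(tree$root))
  parent <- igraph::dfs(tree$graph, root = root_v, father = TRUE)$father
  kids <- table(as.integer(parent[!is.na(parent)]))
  as.integer(igraph::V(tree$graph)$name[as.integer(names(kids))[kids >= 2]])
}

#' Extract a root-to-leaf progression path
#'
#' All samples whose cluster lies on the root-to-leaf cluster sequence,
#' ordered by their arc-length coordinate along the curve backbone.
#'
#' @param tree A [build_tree()] result.
#' @param leaf A leaf cluster id (see [tree_leaves()]).
#' @return Tibble with `sample_id`, `cluster`, `arc_length` and `rank`;
#'   the cluster sequence is attached as attribute `clusters`.
#' @export
extract_path <- function(tree, leaf) {
  if (!leaf %in% tree_leaves(tree)) stopf("cluster %s is not a leaf", leaf)
  vp <- igraph::shortest_paths(tree$graph,
                               from = as.character(tree$root),
                               to = as.character(leaf))$vpath[[1L]]
  cl_seq <- as.integer(igraph::V(tree$graph)$name[vp])
  out <- tree$samples |>
    dplyr::filter(.data$cluster %in% cl_seq) |>
    dplyr::arrange(.data$arc_length) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(out, "clusters") <- cl_seq
  attr(out, "path_id") <- paste(tree$root, leaf, sep = "->")
  out
}

#' Spearman correlation of a covariate along a progression path
#'
#' Rank correlation (average ranks for ties) between the samples' arc-length
#' coordinates and a covariate; missing covariate values are dropped pairwise.
#' Two-sided P comes from the t approximation
#' `t = r sqrt((n-2)/(1-r^2))` for n > 10 and from the exact permutation
#' distribution for n <= 10. Zero variance in either variable yields a missing
#' correlation.
#'
#' @param coords Numeric arc-length coordinates, or a path tibble from
#'   [extract_path()] (its `arc_length` is used).
#' @param values Covariate values aligned with `coords` (or, for a path
#'   tibble, a vector named by sample id).
#' @return Tibble with `r`, `p_value` and `n`.
#' @export
spearman_path <- function(coords, values) {
  if (is.data.frame(coords)) {
    if (!is.null(names(values))) values <- values[coords$sample_id]
    coords <- coords$arc_length
  }
  ok <- is.finite(coords) & !is.na(values) & is.finite(as.numeric(values))
  x <- coords[ok]
  y <- as.numeric(values)[ok]
  n <- length(x)
  if (n < 3L) stopf("need >= 3 paired non-missing values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(tibble(r = NA_real_, p_value = NA_real_, n = n))
  r <- cor(x, y, method = "spearman")
  p <- if (n > 10L) {
    tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
    2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    rx <- rank(x); ry <- rank(y)
    perms <- e1071::permutations(n)
    stats_perm <- as.numeric(matrix(ry[perms], nrow(perms)) %*%
                               (rx - mean(rx)))
    obs <- sum((rx - mean(rx)) * ry)
    mean(abs(stats_perm) >= abs(obs) - 1e-12)
  }
  tibble(r = r, p_value = min(p, 1), n = n)
}

#' Format P-values for reporting
#'
#' P-values below machine range are printed as `"< 1e-15"` rather than a
#' misleading exact zero.
#'
#' @param p Numeric P-values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 1e-15, "< 1e-15", formatC(p, digits = 3, format = "g")))
}

#' Export a progression tree to JSON or GraphML
#'
#' @param tree A [build_tree()] result.
#' @param path Output file.
#' @param format `"json"` (nodes with size/centroid, edges with length, root,
#'   per-sample assignments) or `"graphml"` (via igraph, node size and edge
#'   length attributes).
#' @return The path, invisibly.
#' @export
export_tree <- function(tree, path, format = c("json", "graphml")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(nodes = tree$nodes, edges = tree$edges,
                              root = tree$root,
                              centroids = as.data.frame(tree$centroids),
                              samples = tree$samples,
                              dropped = tree$dropped),
                         path, digits = NA)
  } else {
    g <- tree$graph
    g <- igraph::set_vertex_attr(g, "size", value = tree$nodes$size)
    g <- igraph::set_edge_attr(g, "length", value = tree$edges$length)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Map covariates onto every progression path
#'
#' Runs [spearman_path()] for each covariate along each root-to-leaf path.
#'
#' @param tree A [build_tree()] result.
#' @param clinical Clinical table with `sample_id` and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @return Tibble with `path`, `leaf`, `covariate`, `r`, `p_value`, `n`.
#' @export
map_covariates <- function(tree, clinical, covariates) {
  miss <- setdiff(covariates, names(clinical))
  if (length(miss)) stopf("covariate(s) not in clinical table: %s",
                          paste(miss, collapse = ", "))
  purrr::map_dfr(tree_leaves(tree), function(leaf) {
    path <- extract_path(tree, leaf)
    purrr::map_dfr(covariates, function(cv) {
      vals <- stats::setNames(clinical[[cv]], clinical$sample_id)
      dplyr::bind_cols(tibble(path = attr(path, "path_id"), leaf = leaf,
                              covariate = cv),
                       spearman_path(path, vals))
    })
  })
}

#' Polynomial gene trajectory along a path
#'
#' Min-max normalizes the expression values to \[0, 1\], fits least-squares
#' polynomials of each candidate degree in the arc-length coordinate, picks
#' the degree with the lowest k-fold cross-validated MSE (ties to the lower
#' degree), and refits on all samples. Constant genes normalize to all zeros
#' and get a flat degree-1 fit.
#'
#' @param values Expression values of one gene along the path.
#' @param coords Arc-length coordinates (same length), or a path tibble.
#' @param degree_grid Candidate polynomial degrees, default `1:8`.
#' @param folds CV folds, default 10.
#' @param seed Seed for the fold assignment.
#' @return An object of class `trajectory_fit`: `degree`, `coefficients` (on
#'   the internally standardized coordinate), `cv` tibble, the normalized
#'   values and coordinates.
#' @export
fit_gene_trajectory <- function(values, coords, degree_grid = 1:8, folds = 10,
                                seed = 1) {
  if (is.data.frame(coords)) coords <- coords$arc_length
  ok <- is.finite(values) & is.finite(coords)
  values <- values[ok]; coords <- coords[ok]
  n <- length(values)
  if (n < folds) stopf("need at least `folds` (%d) samples on the path", folds)
  if (diff(range(coords)) == 0) stopf("degenerate design: all coordinates equal")
  rng <- range(values)
  if (diff(rng) == 0) {
    y <- rep(0, n)
    return(structure(list(degree = 1L, coefficients = c(0, 0),
                          cv = tibble(degree = 1L, mse = 0),
                          center = mean(coords), scale = stats::sd(coords),
                          y = y, coords = coords, constant = TRUE),
                     class = "trajectory_fit"))
  }
  y <- (values - rng[1L]) / diff(rng)
  ctr <- mean(coords); scl <- stats::sd(coords)
  xs <- (coords - ctr) / scl
  fold_id <- withr::with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  cv_mse <- vapply(degree_grid, function(d) {
    err <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (sum(tr) < d + 1L) return(NA_real_)
      V <- stats::poly(xs, degree = d, raw = TRUE)
      fit <- stats::lm.fit(cbind(1, V[tr, , drop = FALSE]), y[tr])
      pred <- cbind(1, V[!tr, , drop = FALSE]) %*% fit$coefficients
      mean((y[!tr] - pred)^2)
    }, numeric(1))
    mean(err, na.rm = TRUE)
  }, numeric(1))
  degree <- degree_grid[which.min(cv_mse)]
  V <- stats::poly(xs, degree = degree, raw = TRUE)
  coefs <- stats::lm.fit(cbind(1, V), y)$coefficients
  structure(list(degree = degree, coefficients = unname(coefs),
                 cv = tibble(degree = degree_grid, mse = cv_mse),
                 center = ctr, scale = scl, y = y, coords = coords,
                 constant = FALSE),
            class = "trajectory_fit")
}

#' @export
predict.trajectory_fit <- function(object, newdata = NULL, ...) {
  x <- newdata %||% object$coords
  xs <- (x - object$center) / object$scale
  as.numeric(cbind(1, stats::poly(xs, degree = length(object$coefficients) - 1L,
                                  raw = TRUE)) %*% object$coefficients)
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> degree %d over %d samples (CV-MSE %.4g)\n",
              x$degree, length(x$y), min(x$cv$mse, na.rm = TRUE)))
  invisible(x)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the
#' distinct event times (via `survival::survfit`); `S(0) = 1` and the curve
#' steps only at event times.
#'
#' @param times Nonnegative survival times.
#' @param events Event indicator (1 = event, 0 = censored).
#' @return An object of class `km_estimate`: tibble `table` with `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0L) stopf("empty survival input")
  if (any(times < 0)) stopf("survival times must be >= 0")
  if (!all(events %in% c(0, 1))) stopf("events must be 0/1")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(table = tibble(time = sf$time, n_risk = sf$n.risk,
                                n_event = sf$n.event, n_censor = sf$n.censor,
                                survival = sf$surv),
                 n = length(times)),
            class = "km_estimate")
}

#' Evaluate a Kaplan-Meier estimate at given times
#'
#' @param km A [km_curve()] result.
#' @param t Times at which to evaluate the step function.
#' @return Survival probabilities `S(t)`.
#' @export
km_survival_at <- function(km, t) {
  steps <- km$table[km$table$n_event > 0, ]
  vapply(t, function(tt) {
    if (nrow(steps) == 0L || tt < steps$time[1L]) 1
    else steps$survival[max(which(steps$time <= tt))]
  }, numeric(1))
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("<km_estimate> %d subjects, %d event time(s)\n",
              x$n, sum(x$table$n_event > 0)))
  invisible(x)
}

#' PCA view of the data
#'
#' Mean-centered principal component analysis retaining `d` components, with
#' the fraction of total variance they explain.
#'
#' @param X Data matrix or [sample_matrix()].
#' @param d Number of components, default 3.
#' @return An object of class `pca_view`: `coordinates` (N x d),
#'   `variance_fraction`, and per-component `sdev`.
#' @export
pca_view <- function(X, d = 3) {
  X <- as_values_matrix(X)
  if (d > min(dim(X))) stopf("d must be at most min(N, J)")
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  vars <- pr$sdev^2
  structure(list(coordinates = pr$x[, seq_len(d), drop = FALSE],
                 variance_fraction = sum(vars[seq_len(d)]) / sum(vars),
                 sdev = pr$sdev),
            class = "pca_view")
}

#' @export
print.pca_view <- function(x, ...) {
  cat(sprintf("<pca_view> %d samples x %d components; %.1f%% of variance\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$variance_fraction))
  invisible(x)
}
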