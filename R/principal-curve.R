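## EM fitting of a discretized, possibly branching principal curve under
## isotropic fixed-variance Gaussian noise. The curve is a polyline tree over M
## nodes: a mixture of M isotropic Gaussians whose means live on a fixed tree
## topology, re-spaced to equal arc length along each branch after every
## M-step. The noise scale sigma is a user parameter selected by an elbow
## criterion on the (curve length, fitting error) trade-off.

#' Curve topology: a tree of polyline chains
#'
#' The node set of a discretized principal curve, organized as chains (maximal
#' sequences of consecutive nodes between junctions/endpoints) whose union
#' forms a connected acyclic graph.
#'
#' @param chains List of integer vectors of node ids; consecutive ids within a
#'   chain are curve segments.
#' @return An object of class `curve_topology` with `chains`, `n_nodes`, an
#'   `edges` matrix, and an igraph `graph`.
#' @export
curve_topology <- function(chains) {
  if (!length(chains)) stopf("topology needs at least one chain")
  if (any(vapply(chains, length, 1L) < 2L)) stopf("chains need >= 2 nodes")
  edges <- do.call(rbind, lapply(chains, function(ch)
    cbind(head(ch, -1L), tail(ch, -1L))))
  n_nodes <- max(unlist(chains))
  if (!setequal(unlist(chains), seq_len(n_nodes)))
    stopf("chain node ids must cover 1..M")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::gsize(g) != n_nodes - 1L || !igraph::is_connected(g))
    stopf("chains must form a connected acyclic tree over the nodes")
  structure(list(chains = chains, n_nodes = n_nodes, edges = edges, graph = g),
            class = "curve_topology")
}

#' @export
print.curve_topology <- function(x, ...) {
  cat(sprintf("<curve_topology> %d nodes, %d chains, %d edges\n",
              x$n_nodes, length(x$chains), nrow(x$edges)))
  invisible(x)
}

#' Initialize a curve topology and node positions
#'
#' Two backbones: `"pc1"` places M nodes evenly along the first
#' principal-component segment spanning the data; `"centroids"` builds the
#' minimum spanning tree over supplied cluster centroids and subdivides each
#' MST edge into equal segments, allocating interior nodes proportionally to
#' edge length until about `n_nodes` nodes exist.
#'
#' @param X Numeric matrix or [sample_matrix()].
#' @param backbone `"pc1"` or `"centroids"`.
#' @param centroids Centroid matrix (rows), required for `"centroids"`.
#' @param n_nodes Target node count, default 100.
#' @return List with `topology` ([curve_topology()]) and the initial node
#'   position matrix `mu`.
#' @export
init_topology <- function(X, backbone = c("pc1", "centroids"), centroids = NULL,
                          n_nodes = 100) {
  backbone <- match.arg(backbone)
  X <- as_values_matrix(X)
  if (backbone == "pc1") {
    ctr <- colMeans(X)
    v <- prcomp(X, center = TRUE, rank. = 1L)$rotation[, 1L]
    score <- as.numeric(sweep(X, 2L, ctr) %*% v)
    ts <- seq(min(score), max(score), length.out = n_nodes)
    mu <- outer(ts, v) + rep(ctr, each = n_nodes)
    return(list(topology = curve_topology(list(seq_len(n_nodes))), mu = mu))
  }
  if (is.null(centroids) || nrow(centroids) < 2L)
    stopf("'centroids' backbone needs >= 2 centroids")
  ncen <- nrow(centroids)
  D <- as.matrix(dist(centroids))
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g)
  el <- igraph::as_edgelist(mst, names = FALSE)
  lens <- igraph::E(mst)$weight
  extra <- max(0L, n_nodes - ncen)
  n_int <- if (sum(lens) > 0) round(extra * lens / sum(lens)) else rep(0L, length(lens))
  mu <- centroids
  chains <- vector("list", nrow(el))
  for (e in seq_len(nrow(el))) {
    a <- el[e, 1L]; b <- el[e, 2L]
    k <- n_int[e]
    if (k > 0L) {
      tfrac <- seq_len(k) / (k + 1)
      interior <- outer(1 - tfrac, centroids[a, ]) + outer(tfrac, centroids[b, ])
      ids <- nrow(mu) + seq_len(k)
      mu <- rbind(mu, interior)
      chains[[e]] <- c(a, ids, b)
    } else chains[[e]] <- c(a, b)
  }
  rownames(mu) <- NULL
  list(topology = curve_topology(chains), mu = mu)
}

## Re-space the nodes of every chain to equal arc length along the current
## polyline; chain endpoints (junctions) stay put.
reparametrize_chains <- function(mu, topology) {
  for (ch in topology$chains) {
    pts <- mu[ch, , drop = FALSE]
    seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2))
    total <- sum(seg)
    if (total <= 0) next
    cum <- c(0, cumsum(seg))
    targets <- seq(0, total, length.out = length(ch))
    idx <- findInterval(targets, cum, rightmost.closed = TRUE)
    idx <- pmin(pmax(idx, 1L), length(seg))
    t0 <- (targets - cum[idx]) / pmax(seg[idx], 1e-300)
    mu[ch, ] <- (1 - t0) * pts[idx, , drop = FALSE] +
      t0 * pts[idx + 1L, , drop = FALSE]
  }
  mu
}

## Gaussian mixture E-quantities: responsibilities and log-likelihood.
e_step <- function(X, mu, p, sigma) {
  Jdim <- ncol(X)
  logd <- -cross_sqdist(X, mu) / (2 * sigma^2) - Jdim / 2 * log(2 * pi * sigma^2)
  logw <- sweep(logd, 2L, ifelse(p > 0, log(p), -Inf), "+")
  ll_n <- row_logsumexp(logw)
  list(R = exp(logw - ll_n), loglik = sum(ll_n))
}

#' EM fit of a discretized principal curve at fixed sigma
#'
#' E-step: responsibilities `r_nm` proportional to
#' `p_m exp(-||x_n - mu_m||^2 / (2 sigma^2))`. M-step: node positions become
#' responsibility-weighted means and mixing weights the mean responsibilities,
#' after which the nodes of every chain are re-spaced to equal arc length
#' (disable with `reparametrize = FALSE`, which makes the fit identical to an
#' isotropic fixed-variance Gaussian-mixture EM). Stops when the
#' log-likelihood gain drops below `tol` (relative).
#'
#' @inheritParams init_topology
#' @param topology A [curve_topology()].
#' @param mu Initial node positions (M x J).
#' @param sigma Positive noise scale (fixed during EM).
#' @param p Initial mixing weights, default uniform.
#' @param tol Relative log-likelihood tolerance, default `1e-6`.
#' @param max_iter Maximum EM iterations, default 500.
#' @param reparametrize Enforce equal arc-length node spacing each M-step.
#' @return An object of class `principal_curve_model`: `mu`, `p`, `sigma`,
#'   `topology`, `loglik`, `loglik_trace`, `n_iter`, `converged`, `root`.
#' @export
em_fit <- function(X, topology, mu, sigma, p = NULL, tol = 1e-6,
                   max_iter = 500, reparametrize = TRUE) {
  X <- as_values_matrix(X)
  assert_scalar_num(sigma, "sigma", lower = 1e-300)
  M <- topology$n_nodes
  if (nrow(mu) != M) stopf("`mu` must have one row per topology node")
  p <- p %||% rep(1 / M, M)
  N <- nrow(X)
  trace <- numeric(0)
  frozen_any <- FALSE
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    es <- e_step(X, mu, p, sigma)
    trace <- c(trace, es$loglik)
    if (iter > 1L) {
      gain <- es$loglik - trace[iter - 1L]
      if (gain < tol * (1 + abs(trace[iter - 1L]))) { converged <- TRUE; break }
    }
    Nm <- colSums(es$R)
    live <- Nm >= 1e-12
    frozen_any <- frozen_any || !all(live)
    mu_new <- mu
    mu_new[live, ] <- crossprod(es$R[, live, drop = FALSE], X) / Nm[live]
    p <- Nm / N
    mu <- if (reparametrize) reparametrize_chains(mu_new, topology) else mu_new
  }
  if (frozen_any) warnf("node(s) with vanishing responsibility were frozen in place")
  structure(list(mu = mu, p = p, sigma = sigma, topology = topology,
                 loglik = tail(trace, 1L), loglik_trace = trace,
                 n_iter = length(trace), converged = converged, root = 1L),
            class = "principal_curve_model")
}

#' @export
print.principal_curve_model <- function(x, ...) {
  cat(sprintf("<principal_curve_model> %d nodes, sigma = %.4g, length = %.4g, loglik = %.4g (%d EM iterations)\n",
              x$topology$n_nodes, x$sigma, curve_length(x), x$loglik, x$n_iter))
  invisible(x)
}

#' Log-likelihood of data under a principal curve model
#'
#' `sum_n log sum_m p_m N(x_n | mu_m, sigma^2 I)` including the Gaussian
#' normalizing constant, evaluated with log-sum-exp.
#'
#' @param X Data matrix or [sample_matrix()].
#' @param model A [em_fit()] result.
#' @return The log-likelihood.
#' @export
log_likelihood <- function(X, model) {
  X <- as_values_matrix(X)
  e_step(X, model$mu, model$p, model$sigma)$loglik
}

#' Total polyline length of a fitted curve
#'
#' @param model A `principal_curve_model` (or list with `mu` and `topology`).
#' @return Sum of consecutive-node Euclidean distances over all chains.
#' @export
curve_length <- function(model) {
  e <- model$topology$edges
  sum(sqrt(rowSums((model$mu[e[, 1L], , drop = FALSE] -
                      model$mu[e[, 2L], , drop = FALSE])^2)))
}

## Project every sample onto every segment; returns the per-sample best
## segment, barycentric coordinate and squared distance. Ties in distance keep
## the lower edge index.
project_to_polyline <- function(X, mu, edges) {
  N <- nrow(X)
  best <- list(sq = rep(Inf, N), edge = integer(N), t = numeric(N))
  for (e in seq_len(nrow(edges))) {
    a <- mu[edges[e, 1L], ]
    b <- mu[edges[e, 2L], ]
    d <- b - a
    L2 <- sum(d^2)
    Xa <- sweep(X, 2L, a)
    t0 <- if (L2 > 0) pmin(pmax(as.numeric(Xa %*% d) / L2, 0), 1) else rep(0, N)
    sq <- rowSums((Xa - outer(t0, d))^2)
    upd <- sq < best$sq
    best$sq[upd] <- sq[upd]
    best$edge[upd] <- e
    best$t[upd] <- t0[upd]
  }
  best
}

#' Curve fitting error
#'
#' Sum over samples of the squared Euclidean distance to the closest point on
#' the curve (continuous projection onto every segment, not just node-nearest).
#'
#' @inheritParams log_likelihood
#' @return Nonnegative total squared projection distance.
#' @export
fitting_error <- function(X, model) {
  X <- as_values_matrix(X)
  sum(project_to_polyline(X, model$mu, model$topology$edges)$sq)
}

#' Designate the root node of a fitted curve
#'
#' Arc-length coordinates are measured from the root. With `baseline` sample
#' ids (e.g. normal tissue) the root becomes the node nearest the baseline
#' centroid; otherwise node 1 is kept.
#'
#' @inheritParams log_likelihood
#' @param baseline Optional character vector of baseline sample ids (rows of
#'   `X`) or integer row indices.
#' @return The model with `root` set.
#' @export
designate_root <- function(model, X = NULL, baseline = NULL) {
  if (is.null(baseline)) return(model)
  X <- as_values_matrix(X)
  idx <- if (is.character(baseline)) match(baseline, rownames(X)) else baseline
  if (any(is.na(idx))) stopf("baseline sample(s) not found in X")
  ctr <- colMeans(X[idx, , drop = FALSE])
  model$root <- which.min(rowSums(sweep(model$mu, 2L, ctr)^2))
  model
}

## Arc length of every node from the root, along the tree.
node_arc_lengths <- function(model) {
  e <- model$topology$edges
  w <- sqrt(rowSums((model$mu[e[, 1L], , drop = FALSE] -
                       model$mu[e[, 2L], , drop = FALSE])^2))
  g <- igraph::set_edge_attr(model$topology$graph, "weight", value = w)
  as.numeric(igraph::distances(g, v = model$root))
}

#' Project samples onto a fitted curve
#'
#' Orthogonal projection of every sample onto its nearest curve segment, with
#' the arc-length coordinate of the projected point measured from the root
#' node along the tree.
#'
#' @inheritParams log_likelihood
#' @return Tibble with `sample_id` (row names if present), owning `edge`, its
#'   node pair, the within-segment coordinate `t`, `arc_length`, squared
#'   distance `sq_dist`, and the `nearest_node` of the owning segment.
#' @export
project_samples <- function(X, model) {
  X <- as_values_matrix(X)
  pr <- project_to_polyline(X, model$mu, model$topology$edges)
  arc <- node_arc_lengths(model)
  a <- model$topology$edges[pr$edge, 1L]
  b <- model$topology$edges[pr$edge, 2L]
  tibble(sample_id = rownames(X) %||% as.character(seq_len(nrow(X))),
         edge = pr$edge, node_a = a, node_b = b, t = pr$t,
         arc_length = arc[a] + pr$t * (arc[b] - arc[a]),
         sq_dist = pr$sq,
         nearest_node = ifelse(pr$t <= 0.5, a, b))
}

#' Sweep the noise scale and record the length/error trade-off
#'
#' Runs one EM fit per sigma on a descending grid, warm-starting each fit from
#' the previous one, and records (sigma, curve length, fitting error). As
#' sigma decreases the curve tightens: its length grows and the fitting error
#' falls.
#'
#' @inheritParams em_fit
#' @param sigma_grid Noise scales; sorted descending internally.
#' @param cold_restart Additionally fit each sigma cold from the initial
#'   backbone and keep the higher-likelihood fit (default `TRUE`). At large
#'   sigma the optimal curve contracts toward the data mean; warm-starting the
#'   next sigma from a contracted curve can re-grow it tangled, so the
#'   deterministic restart from the initial geometry guards the sweep.
#' @param ... Passed to [em_fit()] (`tol`, `max_iter`, `reparametrize`).
#' @return An object of class `elbow_sweep`: tibble `records` and the fitted
#'   `models` (named by sigma).
#' @export
sweep_sigma <- function(X, topology, mu, sigma_grid, p = NULL,
                        cold_restart = TRUE, ...) {
  X <- as_values_matrix(X)
  sigma_grid <- sort(sigma_grid, decreasing = TRUE)
  records <- vector("list", length(sigma_grid))
  models <- vector("list", length(sigma_grid))
  cur_mu <- mu
  cur_p <- p
  safe_fit <- function(mu0, p0, sigma) {
    tryCatch(em_fit(X, topology, mu0, sigma, p = p0, ...),
             error = function(e) {
               warnf("EM failed at sigma = %g: %s", sigma, conditionMessage(e))
               NULL
             })
  }
  for (i in seq_along(sigma_grid)) {
    fit <- safe_fit(cur_mu, cur_p, sigma_grid[i])
    if (cold_restart && i > 1L) {
      cold <- safe_fit(mu, p, sigma_grid[i])
      if (!is.null(cold) && (is.null(fit) || cold$loglik > fit$loglik))
        fit <- cold
    }
    if (is.null(fit)) next
    cur_mu <- fit$mu
    cur_p <- fit$p
    models[[i]] <- fit
    records[[i]] <- tibble(sigma = sigma_grid[i],
                           curve_length = curve_length(fit),
                           fitting_error = fitting_error(X, fit),
                           loglik = fit$loglik, n_iter = fit$n_iter)
  }
  keep <- !vapply(records, is.null, logical(1))
  structure(list(records = dplyr::bind_rows(records[keep]),
                 models = stats::setNames(models[keep],
                                          signif(sigma_grid[keep], 6))),
            class = "elbow_sweep")
}

#' Default log-spaced sigma grid
#'
#' 12 values log-spaced over `[0.05, 2]` times the root-mean-square distance of
#' the samples to their global mean.
#'
#' @param X Data matrix or [sample_matrix()].
#' @param n Grid size, default 12.
#' @param span Multiplicative range, default `c(0.05, 2)`.
#' @return Descending numeric vector of sigmas.
#' @export
default_sigma_grid <- function(X, n = 12, span = c(0.05, 2)) {
  X <- as_values_matrix(X)
  rms <- sqrt(mean(rowSums(sweep(X, 2L, colMeans(X))^2)))
  sort(exp(seq(log(span[1L] * rms), log(span[2L] * rms), length.out = n)),
       decreasing = TRUE)
}

#' Elbow selection of the noise scale
#'
#' Fits two least-squares lines to the left and right arms of the
#' (curve length, fitting error) records around every interior breakpoint,
#' picks the breakpoint minimizing the total SSE, intersects the two lines,
#' and returns the first record at or past the intersection length (the
#' shortest curve that has reached the flattened arm).
#' Records whose curve has contracted to (nearly) a point — below 2% of the
#' longest recorded curve — are excluded first: a collapsed curve carries no
#' geometry. Collinear records (no elbow) fall back to the smallest-length
#' record with a warning.
#'
#' @param sweep An `elbow_sweep` or a data frame with `curve_length` and
#'   `fitting_error` columns (and optionally `sigma`).
#' @return An object of class `elbow_selection`: `sigma`, `length_star` (the
#'   intersection), the selected record index, arm coefficients and the sorted
#'   records. `selected_model` is attached when the sweep carried models.
#' @export
elbow_select <- function(sweep) {
  models <- NULL
  if (inherits(sweep, "elbow_sweep")) { models <- sweep$models; rec <- sweep$records }
  else rec <- as_tibble(sweep)
  if (!all(c("curve_length", "fitting_error") %in% names(rec)))
    stopf("records need 'curve_length' and 'fitting_error' columns")
  ord <- order(rec$curve_length)
  rec <- rec[ord, ]
  if (!is.null(models)) models <- models[ord]
  ## fits whose curve has contracted to (nearly) a point are degenerate: they
  ## carry no length/error geometry and would distort the left arm
  keep <- rec$curve_length >= 0.02 * max(rec$curve_length)
  if (any(!keep) && sum(keep) >= 4L) {
    rec <- rec[keep, ]
    if (!is.null(models)) models <- models[keep]
  }
  n <- nrow(rec)
  if (n < 4L) stopf("elbow selection needs >= 4 records")
  x <- rec$curve_length
  y <- rec$fitting_error
  best <- NULL
  for (b in 2:(n - 2L)) {
    il <- 1:b; ir <- (b + 1L):n
    fl <- stats::lm.fit(cbind(1, x[il]), y[il])
    fr <- stats::lm.fit(cbind(1, x[ir]), y[ir])
    sse <- sum(fl$residuals^2) + sum(fr$residuals^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(b = b, sse = sse, cl = fl$coefficients, cr = fr$coefficients)
  }
  m1 <- best$cl[2L]; m2 <- best$cr[2L]
  scale <- abs(m1) + abs(m2) + 1e-12
  if (abs(m1 - m2) <= 1e-8 * scale) {
    warnf("length/error records are collinear; no elbow, selecting the smallest length")
    sel <- 1L
    lstar <- x[1L]
  } else {
    lstar <- (best$cr[1L] - best$cl[1L]) / (m1 - m2)
    ## take the first record past the intersection: rounding down re-enters
    ## the steep arm, where the fit is by construction still inadequate
    past <- which(x >= lstar)
    sel <- if (length(past)) min(past) else n
  }
  structure(list(sigma = if ("sigma" %in% names(rec)) rec$sigma[sel] else NA_real_,
                 length_star = unname(lstar), selected = sel,
                 breakpoint = best$b,
                 left_coef = unname(best$cl), right_coef = unname(best$cr),
                 records = rec,
                 selected_model = if (!is.null(models)) models[[sel]] else NULL),
            class = "elbow_selection")
}

#' @export
print.elbow_selection <- function(x, ...) {
  cat(sprintf("<elbow_selection> L* = %.4g -> record %d (sigma = %.4g) of %d\n",
              x$length_star, x$selected, x$sigma, nrow(x$records)))
  invisible(x)
}
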