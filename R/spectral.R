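## Self-tuning spectral clustering on a mutual-KNN graph, with rotation-based
## estimation of the number of clusters, resampling consensus and a
## similarity-based silhouette.

#' Mutual K-nearest-neighbor graph with local scales
#'
#' Connects samples i and j when each is among the other's K nearest neighbors
#' under Euclidean distance (ties broken by index order); the local scale
#' `sigma_i` is the distance from i to its K-th nearest neighbor.
#'
#' @param X Numeric matrix or [sample_matrix()].
#' @param K Neighborhood size, default 30.
#' @return An object of class `similarity_graph`: logical `adjacency`,
#'   numeric `scales`, and the cached distance matrix `dist`.
#' @export
mutual_knn <- function(X, K = 30) {
  X <- as_values_matrix(X)
  N <- nrow(X)
  if (N <= K) stopf("need more samples (%d) than K = %d; use a smaller K", N, K)
  D <- as.matrix(dist(X))
  adj <- matrix(FALSE, N, N)
  scales <- numeric(N)
  for (i in seq_len(N)) {
    d <- D[i, ]
    d[i] <- Inf
    ord <- order(d)            # stable: ties resolved by index order
    nb <- ord[seq_len(K)]
    adj[i, nb] <- TRUE
    scales[i] <- d[ord[K]]
  }
  adj <- adj & t(adj)
  diag(adj) <- FALSE
  dimnames(adj) <- dimnames(D)
  structure(list(adjacency = adj, scales = scales, dist = D, K = K),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %d samples, K = %d, %d mutual edges\n",
              nrow(x$adjacency), x$K, sum(x$adjacency) / 2))
  invisible(x)
}

#' Locally scaled similarity matrix
#'
#' On mutual-KNN edges, `S_ij = exp(-||x_i - x_j||^2 / (sigma_i sigma_j))`
#' with the per-sample scales of the graph; zero elsewhere. Zero scales
#' (duplicated points beyond K) are replaced by the smallest positive scale.
#'
#' @param graph A [mutual_knn()] result.
#' @return Symmetric similarity matrix with entries in \[0, 1\], zero
#'   diagonal.
#' @export
local_scaled_similarity <- function(graph) {
  sig <- graph$scales
  if (any(sig <= 0)) {
    pos <- sig[sig > 0]
    if (length(pos) == 0L) stopf("all local scales are zero; data are degenerate")
    warnf("%d zero local scale(s) replaced by smallest positive scale", sum(sig <= 0))
    sig[sig <= 0] <- min(pos)
  }
  S <- exp(-graph$dist^2 / outer(sig, sig))
  S[!graph$adjacency] <- 0
  diag(S) <- 0
  (S + t(S)) / 2
}

#' Normalized Laplacian `D^{-1/2} S D^{-1/2}`
#'
#' Eigenvalues lie in \[-1, 1\] and the multiplicity of eigenvalue 1 equals the
#' number of connected components. Isolated vertices (zero degree) are an
#' error; the caller may drop them.
#'
#' @param S Symmetric nonnegative similarity matrix.
#' @return Symmetric matrix `L`.
#' @export
normalized_laplacian <- function(S) {
  deg <- rowSums(S)
  if (any(deg <= 0)) {
    who <- rownames(S)[deg <= 0] %||% which(deg <= 0)
    stopf("isolated vertex (zero similarity degree): %s",
          paste(head(who, 5L), collapse = ", "))
  }
  inv <- 1 / sqrt(deg)
  L <- S * outer(inv, inv)
  (L + t(L)) / 2
}

## ---- rotation-based estimation of the number of clusters -------------------

givens_rotation <- function(C, i, j, theta, deriv = FALSE) {
  G <- diag(C)
  if (deriv) {
    G[] <- 0
    G[i, i] <- -sin(theta); G[j, j] <- -sin(theta)
    G[i, j] <- cos(theta);  G[j, i] <- -cos(theta)
  } else {
    G[i, i] <- cos(theta); G[j, j] <- cos(theta)
    G[i, j] <- sin(theta); G[j, i] <- -sin(theta)
  }
  G
}

## Alignment cost of a rotated eigenvector matrix. Rows with no mass (possible
## when C understates the number of graph components) are degenerate: they are
## charged the maximal per-row cost C so that too-small C is never rewarded.
rotation_cost_value <- function(Z) {
  m <- apply(abs(Z), 1L, max)
  zero <- m < 1e-12
  m[zero] <- 1
  sum((Z[!zero, , drop = FALSE] / m[!zero])^2) + sum(zero) * ncol(Z)
}

## Minimize the alignment cost J(theta) = sum_i sum_c Z_ic^2 / m_i^2 over
## Givens rotations of the top-C eigenvector matrix by gradient descent with an
## analytic gradient.
minimize_rotation_cost <- function(U, n_iter = 200, lr = 0.05) {
  C <- ncol(U)
  pairs <- which(upper.tri(diag(C)), arr.ind = TRUE)
  Kang <- nrow(pairs)
  run <- function(theta0) {
    theta <- theta0
    best <- list(J = rotation_cost_value(U), theta = theta)
    for (iter in seq_len(n_iter)) {
      Gs <- lapply(seq_len(Kang), function(k)
        givens_rotation(C, pairs[k, 1L], pairs[k, 2L], theta[k]))
      prefix <- vector("list", Kang + 1L)   # prefix[[k+1]] = U G_1 ... G_k
      prefix[[1L]] <- U
      for (k in seq_len(Kang)) prefix[[k + 1L]] <- prefix[[k]] %*% Gs[[k]]
      suffix <- vector("list", Kang + 1L)   # suffix[[k]] = G_k ... G_K
      suffix[[Kang + 1L]] <- diag(C)
      for (k in rev(seq_len(Kang))) suffix[[k]] <- Gs[[k]] %*% suffix[[k + 1L]]
      Z <- prefix[[Kang + 1L]]
      m <- apply(abs(Z), 1L, max)
      zero <- m < 1e-12
      m[zero] <- 1
      cstar <- max.col(abs(Z), ties.method = "first")
      J <- rotation_cost_value(Z)
      if (!is.finite(J)) return(NULL)
      if (J < best$J) best <- list(J = J, theta = theta)
      dJdZ <- 2 * Z / m^2
      rs <- rowSums(Z^2)
      idx <- cbind(seq_len(nrow(Z)), cstar)
      dJdZ[idx] <- dJdZ[idx] - 2 * rs * sign(Z[idx]) / m^3
      dJdZ[zero, ] <- 0
      grad <- vapply(seq_len(Kang), function(k) {
        dG <- givens_rotation(C, pairs[k, 1L], pairs[k, 2L], theta[k], deriv = TRUE)
        sum(dJdZ * (prefix[[k]] %*% (dG %*% suffix[[k + 1L]])))
      }, numeric(1))
      theta <- theta - lr * grad
    }
    best
  }
  res <- run(rep(0, Kang))
  if (is.null(res)) {
    res <- run(0.01 * sin(seq_len(Kang)))
    if (is.null(res)) {
      warnf("rotation descent failed twice; using unrotated cost")
      res <- list(J = rotation_cost_value(U), theta = rep(0, Kang))
    }
  }
  res
}

#' Estimate the number of clusters from eigenvector alignment
#'
#' For each candidate C, the top-C eigenvectors of the normalized Laplacian are
#' rotated (Givens rotations, gradient descent on the alignment cost
#' `J = sum_i sum_c Z_ic^2 / max_c(Z_ic)^2`) and the alignment quality
#' `1 - (J/N - 1)/C` is recorded; the estimate is the quality maximizer, ties
#' going to the larger C. Exactly uniform within-cluster similarities are
#' degenerate (every refinement of a uniform clique aligns perfectly, so ties
#' push the estimate to `C_max`); generic similarities do not tie.
#'
#' @param L Normalized Laplacian matrix.
#' @param C_min,C_max Candidate range (default 2 to `min(10, N/2)`).
#' @param n_iter,lr Gradient-descent iterations and learning rate.
#' @return List with the estimate `C` and a tibble `quality` (candidate C,
#'   alignment cost, quality score).
#' @export
estimate_cluster_number <- function(L, C_min = 2, C_max = NULL,
                                    n_iter = 200, lr = 0.05) {
  N <- nrow(L)
  C_max <- C_max %||% min(10L, floor(N / 2))
  if (C_max > N / 2) stopf("C_max must be at most N/2")
  if (C_min < 2 || C_min > C_max) stopf("need 2 <= C_min <= C_max")
  eig <- eigen(L, symmetric = TRUE)
  cand <- seq.int(C_min, C_max)
  qual <- vapply(cand, function(C) {
    res <- minimize_rotation_cost(eig$vectors[, seq_len(C), drop = FALSE],
                                  n_iter = n_iter, lr = lr)
    c(res$J, 1 - (res$J / N - 1) / C)
  }, numeric(2))
  quality <- tibble(C = cand, cost = qual[1L, ], quality = qual[2L, ])
  best <- max(quality$quality)
  list(C = max(quality$C[quality$quality >= best - 1e-12]), quality = quality)
}

#' Spectral embedding from the top Laplacian eigenvectors
#'
#' Takes the top-C eigenvectors (by descending eigenvalue) of the normalized
#' Laplacian and normalizes each row to unit Euclidean norm; zero rows are left
#' at zero and flagged.
#'
#' @param L Normalized Laplacian.
#' @param C Number of eigenvectors.
#' @return An object of class `spectral_embedding`: `values` (all
#'   eigenvalues), `U`, row-normalized `Y`, logical `zero_rows`.
#' @export
spectral_embed <- function(L, C) {
  if (C < 1 || C > nrow(L)) stopf("C must be between 1 and N")
  eig <- eigen(L, symmetric = TRUE)
  U <- eig$vectors[, seq_len(C), drop = FALSE]
  nrm <- sqrt(rowSums(U^2))
  zero <- nrm < 1e-12
  nrm[zero] <- 1
  structure(list(values = eig$values, U = U, Y = U / nrm, zero_rows = zero),
            class = "spectral_embedding")
}

## k-means++ initial centers.
kmeanspp_centers <- function(Y, C) {
  N <- nrow(Y)
  centers <- matrix(NA_real_, C, ncol(Y))
  centers[1L, ] <- Y[sample.int(N, 1L), ]
  d2 <- rowSums(sweep(Y, 2L, centers[1L, ], "-")^2)
  for (c in seq_len(C - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / N, N)
    centers[c, ] <- Y[sample.int(N, 1L, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(Y, 2L, centers[c, ], "-")^2))
  }
  centers
}

#' Seeded K-means with k-means++ restarts
#'
#' Runs `restarts` k-means++-initialized K-means fits and keeps the lowest
#' within-cluster sum of squares; deterministic for a fixed seed. Restarts that
#' produce an empty cluster are re-seeded.
#'
#' @param Y Numeric matrix of points (e.g. a spectral embedding's rows).
#' @param C Number of clusters.
#' @param seed Integer seed.
#' @param restarts Number of restarts, default 10.
#' @return Integer labels in `1..C`.
#' @export
kmeans_cluster <- function(Y, C, seed = 1, restarts = 10) {
  if (C > nrow(Y)) stopf("C cannot exceed the number of points")
  if (C == nrow(Y)) {                      # every point its own cluster, SSE 0
    if (anyDuplicated(Y)) stopf("C = N requires distinct points")
    return(seq_len(nrow(Y)))
  }
  withr::with_seed(seed, {
    best <- NULL
    attempts <- 0L
    done <- 0L
    while (done < restarts && attempts < restarts * 4L) {
      attempts <- attempts + 1L
      km <- tryCatch(
        suppressWarnings(kmeans(Y, centers = kmeanspp_centers(Y, C),
                                iter.max = 100L)),
        error = function(e) NULL)
      if (is.null(km) || length(unique(km$cluster)) < C) next
      done <- done + 1L
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) stopf("k-means failed to produce %d non-empty clusters", C)
    as.integer(best$cluster)
  })
}

## Similarity matrix of the pipeline: mutual-KNN graph, locally scaled
## similarity, and a rescue for isolated vertices (typically outliers whose
## neighbors do not reciprocate): each is connected to its single nearest
## neighbor with the formula similarity, so the Laplacian is well-defined
## without dropping samples.
pipeline_similarity <- function(Xm, K) {
  graph <- mutual_knn(Xm, K)
  S <- local_scaled_similarity(graph)
  iso <- which(rowSums(S) == 0)
  if (length(iso)) {
    warnf("%d isolated sample(s) connected to their nearest neighbor", length(iso))
    sig <- pmax(graph$scales, min(graph$scales[graph$scales > 0]))
    for (i in iso) {
      d <- graph$dist[i, ]
      d[i] <- Inf
      j <- which.min(d)
      S[i, j] <- S[j, i] <- max(exp(-d[j]^2 / (sig[i] * sig[j])), 1e-12)
    }
  }
  list(graph = graph, S = S)
}

#' Full self-tuning spectral clustering pipeline
#'
#' Mutual-KNN graph, locally scaled similarity, normalized Laplacian,
#' (optional) rotation-based estimate of C, row-normalized spectral embedding,
#' seeded K-means, and similarity-based silhouette widths.
#'
#' @inheritParams mutual_knn
#' @param C Number of clusters; estimated with [estimate_cluster_number()]
#'   when `NULL`.
#' @param C_max Upper bound for the estimate.
#' @param seed Seed for K-means.
#' @param restarts K-means restarts.
#' @return An object of class `clustering_result`: integer `labels`, `C`, the
#'   `embedding`, `similarity` matrix, `silhouette` tibble, per-cluster
#'   `clusters` tibble (mean width, stability flag), and the quality table if C
#'   was estimated.
#' @export
spectral_cluster <- function(X, K = 30, C = NULL, C_max = NULL, seed = 1,
                             restarts = 10) {
  Xm <- as_values_matrix(X)
  ps <- pipeline_similarity(Xm, K)
  graph <- ps$graph
  S <- ps$S
  L <- normalized_laplacian(S)
  quality <- NULL
  if (is.null(C)) {
    est <- estimate_cluster_number(L, C_max = C_max)
    C <- est$C
    quality <- est$quality
  }
  emb <- spectral_embed(L, C)
  labels <- kmeans_cluster(emb$Y, C, seed = seed, restarts = restarts)
  sil <- silhouette_similarity(S, labels)
  structure(list(labels = labels, C = C, embedding = emb, similarity = S,
                 silhouette = sil$widths, clusters = sil$clusters,
                 quality = quality, sample_ids = rownames(Xm), graph = graph),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> %d samples in %d clusters; mean silhouette %.3f (%d/%d stable)\n",
              length(x$labels), x$C, mean(x$silhouette$width),
              sum(x$clusters$stable), nrow(x$clusters)))
  invisible(x)
}

#' Spectral clustering at the largest silhouette-stable cluster count
#'
#' Runs the spectral pipeline at every candidate C (re-using one similarity
#' matrix and eigendecomposition) and returns the clustering at the largest C
#' for which every cluster is silhouette-stable (mean similarity-silhouette
#' width > 0). Splitting a coherent group across noise produces non-positive
#' widths, so the stability rule caps C at the number of genuinely separable
#' groups — useful where the rotation-alignment estimate is biased (e.g.
#' clusters chained along a manifold).
#'
#' @inheritParams spectral_cluster
#' @param C_min,C_max Candidate range, defaults 2 and 8.
#' @return A `clustering_result` (with `quality = NULL`); errors if no
#'   candidate is fully stable.
#' @export
stable_spectral_cluster <- function(X, K = 30, C_min = 2, C_max = 8, seed = 1,
                                    restarts = 10) {
  Xm <- as_values_matrix(X)
  ps <- pipeline_similarity(Xm, K)
  S <- ps$S
  eig <- eigen(normalized_laplacian(S), symmetric = TRUE)
  best <- NULL
  for (C in seq.int(C_min, min(C_max, nrow(Xm) - 1L))) {
    U <- eig$vectors[, seq_len(C), drop = FALSE]
    nrm <- sqrt(rowSums(U^2))
    zero <- nrm < 1e-12
    nrm[zero] <- 1
    emb <- structure(list(values = eig$values, U = U, Y = U / nrm,
                          zero_rows = zero), class = "spectral_embedding")
    labels <- kmeans_cluster(emb$Y, C, seed = seed, restarts = restarts)
    sil <- silhouette_similarity(S, labels)
    if (all(sil$clusters$stable))
      best <- structure(list(labels = labels, C = C, embedding = emb,
                             similarity = S, silhouette = sil$widths,
                             clusters = sil$clusters, quality = NULL,
                             sample_ids = rownames(Xm), graph = ps$graph),
                        class = "clustering_result")
  }
  if (is.null(best)) stopf("no candidate C in [%d, %d] is fully stable",
                           C_min, C_max)
  best
}

#' Resampling consensus clustering
#'
#' Repeats the spectral pipeline at fixed C on random subsamples
#' (`floor(frac * N)` samples drawn without replacement per run) and aggregates
#' co-membership into a consensus matrix: entry (i, j) is the fraction of runs
#' containing both samples in which they were co-clustered; pairs never
#' co-sampled are `NA`. Final labels come from one full-data clustering, the
#' consensus matrix being a stability diagnostic.
#'
#' @inheritParams spectral_cluster
#' @param C Fixed number of clusters.
#' @param runs Number of subsampling runs, default 1000.
#' @param frac Subsampling fraction, default 0.8.
#' @return List with the `consensus` matrix, full-data `labels`,
#'   `n_cosampled` counts, and the full-data `clustering_result` as `full`.
#' @export
consensus_cluster <- function(X, C, runs = 1000, frac = 0.8, seed = 1, K = 30,
                              restarts = 5) {
  Xm <- as_values_matrix(X)
  N <- nrow(Xm)
  m <- floor(frac * N)
  if (m < C) stopf("frac * N must be at least C")
  co <- matrix(0, N, N)
  cnt <- matrix(0, N, N)
  withr::with_seed(seed, {
    run <- 0L
    attempts <- 0L
    while (run < runs && attempts < runs * 2L) {
      attempts <- attempts + 1L
      idx <- sample.int(N, m)
      labs <- tryCatch({
        ps <- suppressWarnings(
          pipeline_similarity(Xm[idx, , drop = FALSE], min(K, m - 1L)))
        L <- normalized_laplacian(ps$S)
        emb <- spectral_embed(L, C)
        kmeans_cluster(emb$Y, C, seed = sample.int(.Machine$integer.max, 1L),
                       restarts = restarts)
      }, error = function(e) NULL)
      if (is.null(labs)) next
      run <- run + 1L
      cnt[idx, idx] <- cnt[idx, idx] + 1
      for (c in seq_len(C)) {
        ii <- idx[labs == c]
        co[ii, ii] <- co[ii, ii] + 1
      }
    }
    if (run < runs) warnf("only %d of %d consensus runs succeeded", run, runs)
  })
  consensus <- co / cnt
  consensus[cnt == 0] <- NA_real_
  dimnames(consensus) <- list(rownames(Xm), rownames(Xm))
  full <- spectral_cluster(Xm, K = K, C = C, seed = seed, restarts = restarts)
  list(consensus = consensus, labels = full$labels, n_cosampled = cnt,
       full = full)
}

#' Within- and between-cluster consensus summary
#'
#' @param consensus Consensus matrix from [consensus_cluster()].
#' @param labels Cluster labels.
#' @return Tibble with mean within-cluster and between-cluster consensus
#'   (missing entries excluded).
#' @export
consensus_summary <- function(consensus, labels) {
  same <- outer(labels, labels, "==")
  off <- !diag(nrow(consensus))
  tibble(within = mean(consensus[same & off], na.rm = TRUE),
         between = mean(consensus[!same & off], na.rm = TRUE))
}

#' Similarity-based silhouette widths
#'
#' The width of a sample is its average similarity to the other members of its
#' own cluster minus the highest average similarity to any other cluster; a
#' cluster is stable when its mean width is positive. Samples in singleton
#' clusters get width 0.
#'
#' @param S Symmetric similarity matrix.
#' @param labels Cluster labels (>= 2 clusters).
#' @return List of tibbles: per-sample `widths` (`sample`, `cluster`, `width`)
#'   and per-cluster `clusters` (`cluster`, `mean_width`, `stable`).
#' @export
silhouette_similarity <- function(S, labels) {
  uc <- sort(unique(labels))
  if (length(uc) < 2L) stopf("silhouette needs >= 2 clusters")
  N <- length(labels)
  width <- numeric(N)
  for (i in seq_len(N)) {
    own <- which(labels == labels[i])
    own <- own[own != i]
    if (length(own) == 0L) { width[i] <- 0; next }
    a <- mean(S[i, own])
    b <- max(vapply(uc[uc != labels[i]],
                    function(c) mean(S[i, labels == c]), numeric(1)))
    width[i] <- a - b
  }
  widths <- tibble(sample = seq_len(N), cluster = labels, width = width)
  clusters <- widths |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(mean_width = mean(.data$width), size = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(stable = .data$mean_width > 0)
  list(widths = widths, clusters = clusters)
}
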