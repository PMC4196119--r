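## A reusable bifurcation fixture: data, clustering labels (planted), fitted
## curve on the centroid MST, projections and tree.
make_bifurcation_fixture <- function(seed = 77, n = 220) {
  sim <- simulate_branching_data(n = n, j_rel = 5, j_irrel = 0, seed = seed,
                                 noise_sd = 0.06, nodes_per_segment = 15)
  X <- sim$matrix
  lab <- sim$truth$samples$cluster
  cent <- do.call(rbind, lapply(sort(unique(lab)), function(c)
    colMeans(as.matrix(X)[lab == c, , drop = FALSE])))
  init <- init_topology(X, "centroids", centroids = cent, n_nodes = 45)
  fit <- em_fit(X, init$topology, init$mu, sigma = 0.08, max_iter = 150)
  tt <- sim$truth$samples$t
  fit <- designate_root(fit, X,
                        baseline = sim$truth$samples$sample_id[
                          tt <= quantile(tt, 0.05)])
  list(sim = sim, X = X, labels = lab, fit = fit,
       proj = project_samples(X, fit))
}

test_that("three clusters along a line contract to a path tree", {
  set.seed(2)
  t <- runif(150, 0, 3)
  X <- cbind(t, 0.05 * rnorm(150))
  rownames(X) <- paste0("s", 1:150); colnames(X) <- c("a", "b")
  lab <- pmin(floor(t) + 1L, 3L)
  init <- init_topology(X, "pc1", n_nodes = 20)
  fit <- em_fit(X, init$topology, init$mu, sigma = 0.1, max_iter = 100)
  fit <- designate_root(fit, X, baseline = rownames(X)[t < 0.2])
  suppressMessages(tree <- build_tree(lab, fit, X))
  expect_equal(nrow(tree$nodes), 3L)
  expect_equal(nrow(tree$edges), 2L)
  deg <- igraph::degree(tree$graph)
  expect_equal(sort(unname(deg)), c(1, 1, 2))   # a path A-B-C
  expect_equal(tree$root, 1L)
  expect_setequal(tree_leaves(tree), 3L)
  ## node sizes sum to retained samples; edges have positive length
  expect_equal(sum(tree$nodes$size), 150L)
  expect_true(all(tree$edges$length > 0))
})

test_that("tiny clusters are omitted from the tree", {
  set.seed(2)
  t <- runif(100, 0, 2)
  X <- cbind(t, 0.05 * rnorm(100))
  rownames(X) <- paste0("s", 1:100); colnames(X) <- c("a", "b")
  lab <- ifelse(t < 1, 1L, 2L)
  lab[1:3] <- 3L                               # a 3-sample cluster
  init <- init_topology(X, "pc1", n_nodes = 15)
  fit <- em_fit(X, init$topology, init$mu, sigma = 0.1, max_iter = 80)
  suppressMessages(tree <- build_tree(lab, fit, X, min_cluster_size = 5))
  expect_false(3L %in% tree$nodes$cluster)
  expect_equal(tree$dropped$cluster, 3L)
  expect_equal(sum(tree$nodes$size), 97L)
})

test_that("bifurcation data yield a tree with two leaves and one branch node", {
  fx <- make_bifurcation_fixture()
  suppressMessages(tree <- suppressWarnings(build_tree(fx$labels, fx$fit, fx$X)))
  expect_equal(length(tree_bifurcations(tree)), 1L)
  expect_equal(length(tree_leaves(tree)), 2L)
  ## root is on the trunk (cluster 1 holds the earliest samples)
  expect_equal(tree$root, 1L)
})

test_that("path extraction orders samples by arc length from the root", {
  fx <- make_bifurcation_fixture()
  suppressMessages(tree <- build_tree(fx$labels, fx$fit, fx$X))
  leaves <- tree_leaves(tree)
  p1 <- extract_path(tree, leaves[1])
  p2 <- extract_path(tree, leaves[2])
  expect_true(!is.unsorted(p1$arc_length))
  expect_true(all(p1$arc_length >= 0))
  ## trunk samples appear on both root->leaf paths
  trunk_ids <- fx$sim$truth$samples$sample_id[fx$sim$truth$samples$branch == "trunk"]
  trunk_in_tree <- intersect(trunk_ids, tree$samples$sample_id)
  expect_true(all(trunk_in_tree %in% p1$sample_id))
  expect_true(all(trunk_in_tree %in% p2$sample_id))
  expect_error(extract_path(tree, tree$root), "not a leaf")
  ## recovered coordinate tracks the true latent coordinate on each branch
  for (p in list(p1, p2)) {
    truth_t <- fx$sim$truth$samples$t[match(p$sample_id,
                                            fx$sim$truth$samples$sample_id)]
    expect_gt(spearman_path(p$arc_length, truth_t)$r, 0.9)
  }
})

test_that("spearman_path matches signs, brute-force ranks and P conventions", {
  expect_equal(spearman_path(1:20, (1:20)^3)$r, 1)
  expect_equal(spearman_path(1:20, -(1:20)^2)$r, -1)
  ## tied data against the average-rank oracle
  set.seed(19)
  for (r in 1:50) {
    n <- sample(5:25, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:6, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_path(as.numeric(x), y)$r, brute_spearman(x, y),
                 tolerance = 1e-12)
  }
  ## missing covariates are dropped pairwise
  out <- spearman_path(1:10, c(1:9 + 0.5, NA))
  expect_equal(out$n, 9L)
  ## zero variance -> missing r
  expect_true(is.na(spearman_path(1:10, rep(2, 10))$r))
  ## exact permutation P for small n agrees with the known two-sided value:
  ## for n = 3 and perfectly concordant data, 2 of 6 permutations reach |obs|
  expect_equal(spearman_path(c(1, 2, 3), c(10, 20, 30))$p_value, 2 / 6,
               tolerance = 1e-12)
  ## t approximation kicks in above n = 10 and is small for strong trends
  expect_lt(spearman_path(1:30, (1:30) + rnorm(30, sd = 1e-3))$p_value, 1e-10)
})

test_that("covariate mapping reports one row per path and covariate", {
  fx <- make_bifurcation_fixture()
  suppressMessages(tree <- build_tree(fx$labels, fx$fit, fx$X))
  clin <- simulate_survival(fx$sim$truth, seed = 5)
  cm <- map_covariates(tree, clin, c("progression_score", "age"))
  expect_equal(nrow(cm), 2L * 2L)
  ps <- dplyr::filter(cm, covariate == "progression_score")
  expect_true(all(ps$r > 0.8))
  expect_true(all(ps$p_value < 1e-6))
})

test_that("gene trajectories select sensible degrees and normalize to [0,1]", {
  set.seed(23)
  x <- runif(60, 0, 4)
  y <- 3 + 2 * (x - 2)^2                     # noiseless quadratic
  fit <- fit_gene_trajectory(y, x, seed = 2)
  expect_gte(fit$degree, 2L)
  expect_lt(mean((predict(fit) - fit$y)^2), 1e-10)
  expect_true(all(fit$y >= 0 & fit$y <= 1))
  ## constant gene: all-zero normalization, flat degree-1 fit
  cf <- fit_gene_trajectory(rep(5, 30), seq_len(30), seed = 2)
  expect_equal(cf$degree, 1L)
  expect_equal(cf$y, rep(0, 30))
  expect_error(fit_gene_trajectory(rnorm(20), rep(1, 20), seed = 1),
               "degenerate design")
  expect_error(fit_gene_trajectory(rnorm(5), rnorm(5), folds = 10, seed = 1),
               "folds")
})

test_that("Kaplan-Meier estimates equal hand-computed product limits", {
  ## no events: S identically 1
  km0 <- km_curve(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km_survival_at(km0, c(0, 3, 10)) == 1))
  ## n = 4, one event at t = 2: S(2) = 3/4
  km1 <- km_curve(c(2, 3, 5, 7), c(1, 0, 0, 0))
  expect_equal(km_survival_at(km1, 2), 0.75)
  ## 6 subjects with interleaved censoring, hand-computed:
  ## events at 1 (n=6), 3 (n=4), 5 (n=2), 6 (n=1); censored at 2+, 4+
  t6 <- c(1, 2, 3, 4, 5, 6)
  e6 <- c(1, 0, 1, 0, 1, 1)
  km6 <- km_curve(t6, e6)
  expect_equal(km_survival_at(km6, c(1, 3, 5, 6)),
               c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 1 / 2, 0),
               tolerance = 1e-12)
  ## agreement with the direct product-limit construction, any order
  perm <- c(4, 1, 6, 3, 2, 5)
  km6p <- km_curve(t6[perm], e6[perm])
  bk <- brute_km(t6, e6)
  expect_equal(km_survival_at(km6p, bk$time), bk$surv, tolerance = 1e-12)
  expect_error(km_curve(numeric(0), numeric(0)), "empty")
})

test_that("PCA view reports coordinates and the explained-variance fraction", {
  set.seed(29)
  ## data in a 3-D affine subspace of 8-D: fraction = 1
  B <- matrix(rnorm(24), 8, 3)
  X <- matrix(rnorm(150), 50, 3) %*% t(B) + rep(rnorm(8), each = 50)
  rownames(X) <- paste0("s", 1:50); colnames(X) <- paste0("f", 1:8)
  pv <- pca_view(X, d = 3)
  expect_equal(pv$variance_fraction, 1, tolerance = 1e-9)
  expect_equal(dim(pv$coordinates), c(50L, 3L))
  ## isotropic Gaussian: fraction near d/J (N large enough that the top
  ## sample eigenvalues sit close to the population value)
  Xi <- named_matrix(rnorm(2000 * 10), 2000, 10)
  pvi <- pca_view(Xi, d = 3)
  expect_lt(abs(pvi$variance_fraction - 3 / 10) / (3 / 10), 0.2)
  expect_true(pvi$variance_fraction >= 0 && pvi$variance_fraction <= 1)
  expect_error(pca_view(Xi, d = 30), "at most")
})
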