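test_that("topology initialization produces the expected backbones", {
  ## 1-D data, pc1: collinear equally spaced nodes
  X <- named_matrix(cbind(seq(0, 10, length.out = 30), 0), 30, 2)
  init <- init_topology(X, "pc1", n_nodes = 5)
  expect_equal(init$topology$n_nodes, 5L)
  expect_equal(length(init$topology$chains), 1L)
  d <- diff(init$mu[, 1])
  expect_equal(d, rep(d[1], 4), tolerance = 1e-9)
  expect_equal(init$mu[, 2], rep(0, 5), tolerance = 1e-9)
  ## collinear centroids -> path topology, no branch
  cent <- cbind(c(0, 1, 2), 0)
  init2 <- init_topology(X, "centroids", centroids = cent, n_nodes = 9)
  deg <- igraph::degree(init2$topology$graph)
  expect_equal(sum(deg == 1), 2L)
  expect_true(all(deg <= 2))
  ## Y-shaped centroids -> tree with one degree-3 node (MST property)
  centY <- rbind(c(0, 0), c(1, 0), c(2, 1), c(2, -1))
  init3 <- init_topology(X, "centroids", centroids = centY, n_nodes = 12)
  degY <- igraph::degree(init3$topology$graph)
  expect_equal(sum(degY == 3), 1L)
  expect_equal(sum(degY == 1), 3L)
  expect_error(init_topology(X, "centroids", centroids = cent[1, , drop = FALSE]),
               ">= 2 centroids")
})

test_that("EM with reparametrization off equals the textbook GMM oracle", {
  set.seed(6)
  X <- named_matrix(rnorm(80, sd = 2), 40, 2)
  init <- init_topology(X, "pc1", n_nodes = 6)
  n_it <- 12
  fit <- em_fit(X, init$topology, init$mu, sigma = 1, tol = 0,
                max_iter = n_it, reparametrize = FALSE)
  oracle <- gmm_em_oracle(X, init$mu, rep(1 / 6, 6), sigma = 1, n_iter = n_it)
  expect_equal(unname(fit$mu), unname(oracle$mu[[n_it]]), tolerance = 1e-10)
  expect_equal(fit$p, oracle$p[[n_it]], tolerance = 1e-10)
  expect_equal(fit$loglik_trace, oracle$loglik[seq_along(fit$loglik_trace)],
               tolerance = 1e-10)
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))   # EM monotonicity
  expect_equal(sum(fit$p), 1, tolerance = 1e-12)
})

test_that("degenerate EM cases follow the mixture identities", {
  ## single node: mean of the data after one step
  X <- named_matrix(c(-1, 1, 3, 7), 2, 2)
  topo1 <- structure(list(chains = list(c(1L, 2L)), n_nodes = 2L,
                          edges = matrix(c(1L, 2L), 1),
                          graph = igraph::make_graph(c(1, 2), directed = FALSE)),
                     class = "curve_topology")
  fit <- em_fit(X, topo1, mu = matrix(c(0, 0, 10, 10), 2, byrow = TRUE),
                sigma = 100, tol = 0, max_iter = 2, reparametrize = FALSE)
  ## huge sigma: responsibilities ~ (0.5, 0.5), both nodes move to the mean
  expect_equal(unname(fit$mu[1, ]), unname(colMeans(X)), tolerance = 1e-3)
  ## sample equidistant from two equal-weight nodes -> responsibilities 1/2
  es <- progpath:::e_step(matrix(c(0, 0), 1), matrix(c(-1, 1, 0, 0), 2),
                          c(0.5, 0.5), sigma = 1)
  expect_equal(as.numeric(es$R), c(0.5, 0.5))
})

test_that("log-likelihood has its closed form and additivity", {
  ## one node at the mean, sigma = 1, J = 1, points at +-1:
  ## each point has density N(+-1 | 0, 1) -> loglik = -(log(2*pi) + 1)
  X <- matrix(c(-1, 1), 2, 1, dimnames = list(c("a", "b"), "f"))
  model <- list(mu = matrix(0, 1, 1), p = 1, sigma = 1)
  expect_equal(log_likelihood(X, model), -(log(2 * pi) + 1), tolerance = 1e-12)
  ## duplicating every sample doubles the log-likelihood
  X2 <- rbind(X, X)
  rownames(X2) <- paste0("r", 1:4)
  expect_equal(log_likelihood(X2, model), 2 * log_likelihood(X, model),
               tolerance = 1e-12)
})

test_that("curve length is additive over segments", {
  topo <- curve_topology(list(1:3))
  model <- list(mu = matrix(c(0, 0, 3, 0, 3, 4), 3, 2, byrow = TRUE),
                topology = topo)
  expect_equal(curve_length(model), 3 + 4)
  model$mu <- matrix(0, 3, 2)
  expect_equal(curve_length(model), 0)
  ## Y-tree with six unit segments
  chains <- list(1:3, c(3L, 4L, 5L), c(3L, 6L, 7L))
  mu <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0), c(4, 0), c(2, 1), c(2, 2))
  expect_equal(curve_length(list(mu = mu, topology = curve_topology(chains))), 6)
})

test_that("fitting error and projection match the dense-sampling oracle", {
  topo <- curve_topology(list(1:3))
  mu <- rbind(c(0, 0), c(1, 0), c(1, 1))
  model <- list(mu = mu, topology = topo, root = 1L)
  ## points exactly on the polyline -> error 0
  on_curve <- rbind(c(0.5, 0), c(1, 0.25), c(1, 1))
  rownames(on_curve) <- paste0("p", 1:3); colnames(on_curve) <- c("x", "y")
  expect_equal(fitting_error(on_curve, model), 0, tolerance = 1e-20)
  ## single-node model: total squared distance to that node
  one <- list(mu = matrix(c(0, 0), 1), p = 1,
              topology = structure(list(chains = list(c(1L, 1L)),
                                        n_nodes = 1L,
                                        edges = matrix(c(1L, 1L), 1),
                                        graph = igraph::make_graph(integer(0),
                                                                   n = 1)),
                                   class = "curve_topology"))
  X <- named_matrix(rnorm(10), 5, 2)
  expect_equal(fitting_error(X, one), sum(X^2), tolerance = 1e-12)
  ## random cloud against the dense oracle
  set.seed(14)
  Xr <- named_matrix(runif(24, -1, 2), 12, 2)
  fe <- fitting_error(Xr, model)
  or <- dense_projection_error(Xr, mu, topo$edges)
  expect_lt(abs(fe - or) / or, 1e-6)
  ## projections: sample at a node and perpendicular to a midpoint
  P <- rbind(c(1, 0), c(0.5, -2), c(2, 0.5))
  rownames(P) <- paste0("q", 1:3); colnames(P) <- c("x", "y")
  pr <- project_samples(P, model)
  expect_equal(pr$arc_length[1], 1)         # at node 2
  expect_equal(pr$arc_length[2], 0.5)       # foot at segment midpoint
  expect_equal(pr$arc_length[3], 1.5)       # clamps to nearest point
  ## projection optimality: never farther than every node
  prr <- project_samples(Xr, model)
  node_d2 <- apply(Xr, 1, function(x) min(colSums((t(mu) - x)^2)))
  expect_true(all(prr$sq_dist <= node_d2 + 1e-12))
})

test_that("equal-arc reparametrization respaces interior nodes", {
  topo <- curve_topology(list(1:4))
  mu <- rbind(c(0, 0), c(0.1, 0), c(0.2, 0), c(3, 0))
  mu2 <- progpath:::reparametrize_chains(mu, topo)
  expect_equal(mu2[, 1], c(0, 1, 2, 3), tolerance = 1e-12)
  expect_equal(mu2[1, ], mu[1, ])           # endpoints fixed
  expect_equal(mu2[4, ], mu[4, ])
})

test_that("sigma sweep records a monotone trade-off and warm starts agree", {
  sim <- simulate_branching_data(n = 120, j_rel = 4, j_irrel = 0, seed = 31,
                                 noise_sd = 0.05, nodes_per_segment = 12)
  X <- sim$matrix
  cl <- kmeans_cluster(as.matrix(X), 5, seed = 2)
  cent <- do.call(rbind, lapply(1:5, function(c)
    colMeans(as.matrix(X)[cl == c, , drop = FALSE])))
  init <- init_topology(X, "centroids", centroids = cent, n_nodes = 40)
  grid <- default_sigma_grid(X, n = 6, span = c(0.1, 1.5))
  sw <- sweep_sigma(X, init$topology, init$mu, grid, max_iter = 120)
  expect_equal(nrow(sw$records), 6L)
  rec <- dplyr::arrange(sw$records, curve_length)
  tolr <- 0.01 * diff(range(rec$fitting_error))
  expect_true(all(diff(rec$fitting_error) <= tolr))
  ## single-sigma grid -> single record
  sw1 <- sweep_sigma(X, init$topology, init$mu, grid[3], max_iter = 60)
  expect_equal(nrow(sw1$records), 1L)
  ## warm vs cold start at a mid-grid sigma agree in log-likelihood
  ## (at the smallest sigmas EM has many local optima and paths may differ)
  mid <- grid[3]
  cold <- em_fit(X, init$topology, init$mu, mid, max_iter = 300)
  warm_ll <- dplyr::filter(sw$records, sigma == mid)$loglik
  expect_lt(abs(warm_ll - cold$loglik) / abs(cold$loglik), 0.02)
})

test_that("elbow selection recovers intersections exactly and under noise", {
  ## exact two-line data
  exact <- simulate_elbow(l_star = 20, noise_sd = 0)
  es <- elbow_select(exact)
  expect_equal(es$length_star, 20, tolerance = 1e-9)
  ## seeded noise at 1% of range: within 10% of truth
  noisy <- simulate_elbow(l_star = 20, noise_sd = 0.01, seed = 44)
  en <- elbow_select(noisy)
  expect_lt(abs(en$length_star - 20) / 20, 0.10)
  ## collinear records: warning and smallest length
  line <- tibble::tibble(curve_length = 1:6,
                         fitting_error = 10 - (1:6) * 0.5)
  expect_warning(ec <- elbow_select(line), "collinear")
  expect_equal(ec$selected, 1L)
  expect_error(elbow_select(line[1:3, ]), ">= 4 records")
})

test_that("fitting error decreases weakly with more nodes at fixed sigma", {
  sim <- simulate_branching_data(n = 100, j_rel = 3, j_irrel = 0, seed = 12,
                                 noise_sd = 0.05, nodes_per_segment = 10)
  X <- sim$matrix
  errs <- vapply(c(5, 10, 20), function(m) {
    init <- init_topology(X, "pc1", n_nodes = m)
    fitting_error(X, em_fit(X, init$topology, init$mu, sigma = 0.1,
                            max_iter = 150))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-6 + 0.01 * errs[-3]))
})
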