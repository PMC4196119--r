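test_that("endpoints are midpoints of consecutive distinct times", {
  expect_equal(compute_endpoints(c(1, 2, 3, 4)), c(1.5, 2.5, 3.5))
  expect_equal(compute_endpoints(c(1, 1, 2)), 1.5)   # ties collapse
  expect_error(compute_endpoints(c(5, 5, 5)), "distinct")
})

test_that("weighted block distance follows its definition", {
  expect_equal(weighted_block_distance(c(0, 0), c(1, 2), c(1, 1)), 3)
  expect_equal(weighted_block_distance(c(0, 0), c(1, 2), c(0, 1)), 2)
  expect_equal(weighted_block_distance(c(3, 7), c(3, 7), c(2, 5)), 0)
  expect_error(weighted_block_distance(1:3, 1:2, 1:3), "equal length")
})

test_that("neighbor probabilities normalize and respect symmetry and limits", {
  ## x2 equidistant from x1 and x4 on the opposite side -> (0.5, 0.5)
  X <- named_matrix(c(0, 1, 5, 2, 0, 0, 5, 0), 4, 2)
  times <- c(1, 5, 5, 1)
  np <- neighbor_probabilities(X, times, w = c(1, 1), s_k = 3, n = 2)
  expect_equal(unname(np$Q), c(0.5, 0.5))
  expect_equal(np$opposite, c(1L, 4L))
  ## single candidate on a side -> probability 1
  X3 <- named_matrix(c(0, 1, 2, 0, 0, 0), 3, 2)
  np2 <- neighbor_probabilities(X3, c(1, 5, 4), c(1, 1), s_k = 3, n = 2)
  expect_equal(unname(np2$Q), 1)
  expect_equal(unname(np2$P), 1)
  ## huge kernel width -> uniform over candidates
  set.seed(4)
  Xr <- named_matrix(runif(40), 10, 4)
  tr <- 1:10
  np3 <- neighbor_probabilities(Xr, tr, runif(4), s_k = 5.5, n = 8,
                                kernel_width = 1e9)
  expect_equal(unname(np3$Q), rep(1 / 5, 5), tolerance = 1e-6)
  ## Q and P always sum to one with nonnegative entries
  for (n in c(1, 4, 10)) for (s in c(2.5, 5.5, 8.5)) {
    np4 <- neighbor_probabilities(Xr, tr, runif(4), s_k = s, n = n)
    expect_equal(sum(np4$Q), 1, tolerance = 1e-12)
    expect_equal(sum(np4$P), 1, tolerance = 1e-12)
    expect_true(all(np4$Q >= 0) && all(np4$P >= 0))
  }
})

test_that("expected margin vectors match the brute-force enumeration", {
  ## 4-point 1-D toy from the endpoint decomposition: x = 0,1,10,11
  X <- named_matrix(c(0, 1, 10, 11), 4, 1)
  times <- 1:4
  w <- 1
  grid <- compute_endpoints(times)
  mv <- expected_margin_vectors(X, times, w, grid, kernel_width = 2)
  expect_equal(ncol(mv$Z), 1L)           # every z has length J
  for (r in seq_len(nrow(mv$Z))) {
    z <- brute_margin_vector(X, times, w, mv$pairs$s[r], mv$pairs$sample[r], 2)
    expect_equal(unname(mv$Z[r, ]), unname(z), tolerance = 1e-12)
  }
  ## multivariate case against the same oracle
  set.seed(9)
  Xr <- named_matrix(rnorm(36), 6, 6)
  tr <- c(1, 2, 2, 3, 4, 5)
  wr <- runif(6)
  mvr <- expected_margin_vectors(Xr, tr, wr, kernel_width = 1.3)
  for (r in seq_len(nrow(mvr$Z))) {
    z <- brute_margin_vector(Xr, tr, wr, mvr$pairs$s[r], mvr$pairs$sample[r], 1.3)
    expect_equal(unname(mvr$Z[r, ]), unname(z), tolerance = 1e-12)
  }
})

test_that("kernel width -> 0 recovers nearest-neighbor hypothesis margins", {
  X <- named_matrix(c(0, 1, 10, 11), 4, 1)
  times <- 1:4
  mv <- expected_margin_vectors(X, times, w = 1, kernel_width = 1e-8)
  for (r in seq_len(nrow(mv$Z))) {
    z_nn <- nn_margin_vector(X, times, 1, mv$pairs$s[r], mv$pairs$sample[r])
    expect_equal(unname(mv$Z[r, ]), unname(z_nn), tolerance = 1e-9)
  }
})

test_that("hinge solver matches the 2-D grid oracle on the canonical cases", {
  ## any w >= 0 worsens the hinge when z is all-negative: optimum w = 0
  sol0 <- solve_l1_hinge(matrix(c(-1, -1), 1), lambda = 1)
  expect_equal(sol0$objective, 1, tolerance = 1e-9)
  expect_equal(unname(sol0$w), c(0, 0), tolerance = 1e-6)
  cases <- list(list(z = c(1, 0), lambda = 0.5),
                list(z = c(2, 0), lambda = 1),
                list(z = c(-1, -1), lambda = 1))
  for (cs in cases) {
    Z <- matrix(cs$z, 1)
    sol <- solve_l1_hinge(Z, cs$lambda)
    oracle <- grid_hinge_oracle(Z, cs$lambda)
    expect_lt(abs(sol$objective - oracle), 1e-3)
  }
  ## the lambda = 0.5 case has the unique optimum (0.5, 0)
  sol1 <- solve_l1_hinge(matrix(c(1, 0), 1), lambda = 0.5)
  expect_equal(unname(sol1$w), c(0.5, 0), tolerance = 1e-4)
})

test_that("hinge solver trace is non-increasing and the result feasible", {
  set.seed(11)
  Z <- matrix(rnorm(200), 50, 4)
  w0 <- runif(4, 0, 0.4)                  # already feasible for lambda = 2
  sol <- solve_l1_hinge(Z, lambda = 2, w_init = w0)
  expect_true(all(diff(sol$trace) <= 1e-12))
  expect_lte(sol$objective, sum(pmax(0, 1 - Z %*% w0)))
  expect_true(all(sol$w >= 0))
  expect_lte(sum(sol$w), 2 + 1e-9)
  expect_error(solve_l1_hinge(matrix(c(NA, 1), 1), 1), "non-finite")
})

test_that("fixed-point recursion recovers the relevant feature on a noiseless toy", {
  set.seed(3)
  n <- 40; j <- 50
  x1 <- runif(n)
  X <- named_matrix(cbind(x1, matrix(runif(n * (j - 1)), n)), n, j)
  y <- 1 + 5 * x1^2                       # noiseless monotone link
  fw <- fit_feature_weights(X, y, lambda = 2)
  expect_true(fw$converged)
  expect_gt(fw$w[1], 1e-3)
  expect_gt(mean(fw$w[-1] < 1e-3), 0.9)
  ## the relevant feature alone classifies almost every endpoint split
  ## correctly (1-NN margins positive except right at split boundaries),
  ## confirming the planted structure the selector exploits
  margins <- c()
  for (s in compute_endpoints(y)) {
    for (n_i in seq_len(n)) {
      same_n <- sum(if (y[n_i] > s) y > s else y < s) - 1L
      opp_n <- sum(if (y[n_i] > s) y < s else y > s)
      if (same_n < 1L || opp_n < 1L) next
      margins <- c(margins, nn_margin_vector(matrix(x1, ncol = 1), y, 1, s, n_i))
    }
  }
  expect_gt(mean(margins), 0)
  expect_gt(mean(margins > 0), 0.8)
})

test_that("fixed point is initialization-independent and lambda -> 0 kills w", {
  set.seed(5)
  n <- 30
  x1 <- runif(n)
  X <- named_matrix(cbind(x1, matrix(runif(n * 9), n)), n, 10)
  y <- 2 + 3 * x1
  fw1 <- fit_feature_weights(X, y, lambda = 1.5)
  w0 <- withr::with_seed(7, runif(10))
  w0 <- w0 / sum(w0) * 1.5
  fw2 <- fit_feature_weights(X, y, lambda = 1.5, w_init = w0)
  expect_lt(max(abs(fw1$w - fw2$w)), 1e-3)
  fw0 <- suppressWarnings(fit_feature_weights(X, y, lambda = 1e-9))
  expect_lt(sum(fw0$w), 1e-8)
})

test_that("feature-order permutation permutes the weights identically", {
  set.seed(13)
  n <- 25; j <- 8
  X <- named_matrix(cbind(runif(n), matrix(runif(n * (j - 1)), n)), n, j)
  y <- 1 + X[, 1]
  perm <- sample(j)
  Xp <- X[, perm]
  fw <- fit_feature_weights(X, y, lambda = 1)
  fwp <- fit_feature_weights(Xp, y, lambda = 1)
  expect_equal(unname(fwp$w), unname(fw$w[perm]), tolerance = 1e-8)
})

test_that("select_features applies the threshold rule", {
  fw <- structure(list(w = c(a = 0.5, b = 1e-4, c = 0.002), tau = 1e-3,
                       feature_source = NULL),
                  class = "feature_weights")
  expect_equal(select_features(fw, 1e-3)$index, c(1L, 3L))
  expect_warning(out <- select_features(fw, 2), "no feature weight")
  expect_equal(nrow(out), 0L)
  expect_equal(select_features(fw, 0)$index, c(1L, 2L, 3L))
})

test_that("lambda cross-validation behaves on degenerate and structured toys", {
  set.seed(21)
  n <- 24
  x1 <- runif(n)
  X <- named_matrix(cbind(x1, matrix(runif(n * 4), n)), n, 5)
  y <- 1 + 4 * x1
  ## single-value grid returns that value
  one <- tune_lambda_cv(X, y, lambda_grid = 0.7, folds = 3, seed = 2)
  expect_equal(one$lambda, 0.7)
  ## structured toy: chosen lambda must select the relevant feature
  tuned <- tune_lambda_cv(X, y, lambda_grid = c(0.5, 2), folds = 3, seed = 2)
  fw <- fit_feature_weights(X, y, lambda = tuned$lambda)
  expect_true(1L %in% select_features(fw)$index)
})

test_that("pure-noise outcomes prefer the sparsest lambda", {
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    X <- withr::with_seed(100 + r, named_matrix(runif(40 * 5), 40, 5))
    y <- withr::with_seed(200 + r, runif(40))
    tuned <- tune_lambda_cv(X, y, lambda_grid = c(0.05, 5), folds = 10,
                            seed = 300 + r)
    hits <- hits + (tuned$lambda == 0.05)
  }
  expect_gte(hits / n_rep, 0.8)
})
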