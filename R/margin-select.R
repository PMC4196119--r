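## Large-margin feature selection for nonlinear regression on survival times.
##
## A regression on survival time is decomposed into binary classification
## problems at every midpoint between consecutive distinct observed times.
## For each sample and endpoint, the hypothesis margin (distance to the nearest
## neighbor on the opposite side of the split minus distance to the nearest
## neighbor on the same side) is replaced by its expectation under kernel
## neighbor probabilities, giving margin vectors z that are linear in the
## feature weights w. The weights minimize the total hinge loss subject to
## w >= 0 and an l1 budget, and the mutual dependency between w and the
## neighbor probabilities is resolved by fixed-point recursion.

#' Endpoint grid for the regression-to-classification decomposition
#'
#' Midpoints between consecutive *distinct* sorted survival times; ties
#' collapse so no split has zero width.
#'
#' @param times Numeric vector of survival times.
#' @return Strictly increasing numeric vector of `K = n_distinct - 1`
#'   endpoints.
#' @export
compute_endpoints <- function(times) {
  ts <- sort(unique(times))
  if (length(ts) < 2L) stopf("need >= 2 distinct survival times to place endpoints")
  (head(ts, -1L) + tail(ts, -1L)) / 2
}

#' Feature-weighted block (L1) distance
#'
#' `sum_j w_j |a_j - b_j|`, the distance underlying all neighbor computations.
#'
#' @param a,b Numeric vectors of equal length.
#' @param w Nonnegative weights of the same length.
#' @return A nonnegative number.
#' @export
weighted_block_distance <- function(a, b, w) {
  if (length(a) != length(b) || length(a) != length(w))
    stopf("`a`, `b` and `w` must have equal length")
  sum(w * abs(a - b))
}

## Kernel weights exp(-d/width) normalized over a candidate set, computed
## stably by shifting by the minimum distance.
kernel_probs <- function(d, width) {
  e <- exp(-(d - min(d)) / width)
  e / sum(e)
}

#' Kernel neighbor probabilities for one (sample, endpoint) pair
#'
#' For sample `n` at endpoint `s_k`, returns the probability of each candidate
#' being the nearest neighbor of `x_n` on the opposite side of the split (`Q`)
#' and on its own side excluding itself (`P`). Probabilities are proportional
#' to `exp(-d_w(x_n, x_j) / kernel_width)` with the feature-weighted block
#' distance, normalized within each side.
#'
#' @param X Numeric matrix or [sample_matrix()] (samples x features).
#' @param times Survival times aligned with rows of `X`.
#' @param w Nonnegative feature weights.
#' @param s_k Endpoint (threshold time).
#' @param n Row index of the held-out sample.
#' @param kernel_width Positive kernel width.
#' @return List with `Q`, `P` (named by row index), and the index sets
#'   `opposite`, `same`. `NULL` if either side of the split is empty.
#' @export
neighbor_probabilities <- function(X, times, w, s_k, n, kernel_width = 2) {
  X <- as_values_matrix(X)
  assert_scalar_num(kernel_width, "kernel_width", lower = 1e-12)
  above <- which(times > s_k)
  below <- which(times < s_k)
  if (times[n] > s_k) { same <- setdiff(above, n); opposite <- below }
  else                { same <- setdiff(below, n); opposite <- above }
  if (length(same) == 0L || length(opposite) == 0L) return(NULL)
  d <- abs(sweep(X, 2L, X[n, ], "-")) %*% w
  Q <- kernel_probs(d[opposite], kernel_width)
  P <- kernel_probs(d[same], kernel_width)
  list(Q = stats::setNames(as.numeric(Q), opposite),
       P = stats::setNames(as.numeric(P), same),
       opposite = opposite, same = same)
}

#' Expected margin vectors over all (sample, endpoint) pairs
#'
#' The expected hypothesis margin of sample `n` at endpoint `k` is `w' z_n(k)`
#' with `z_n(k) = sum_j Q(j|n,w) |x_n - x_j| - sum_j P(j|n,w) |x_n - x_j|`
#' (element-wise absolute differences; Q over the opposite side of the split, P
#' over the same side minus `n`), so a positive value means a one-nearest-
#' neighbor classifier puts the sample on the correct side. Pairs where either
#' side of the split is empty are skipped.
#'
#' @inheritParams neighbor_probabilities
#' @param endpoints Endpoint grid; defaults to [compute_endpoints()] of
#'   `times`.
#' @return An object of class `margin_vectors`: list with matrix `Z` (one row
#'   per retained (n, k) pair, `J` columns) and a tibble `pairs` (`sample`,
#'   `endpoint`, `s`).
#' @export
expected_margin_vectors <- function(X, times, w, endpoints = NULL, kernel_width = 2) {
  X <- as_values_matrix(X)
  N <- nrow(X)
  if (length(times) != N) stopf("`times` must match rows of `X`")
  endpoints <- endpoints %||% compute_endpoints(times)
  K <- length(endpoints)
  above <- lapply(endpoints, function(s) times > s)
  z_list <- vector("list", N)
  pair_list <- vector("list", N)
  for (n in seq_len(N)) {
    A <- abs(sweep(X, 2L, X[n, ], "-"))
    d <- as.numeric(A %*% w)
    W <- matrix(0, K, N)
    valid <- logical(K)
    for (k in seq_len(K)) {
      up <- above[[k]]
      if (up[n]) { same <- which(up); opp <- which(!up) }
      else       { same <- which(!up); opp <- which(up) }
      same <- setdiff(same, n)
      if (length(same) == 0L || length(opp) == 0L) next
      W[k, opp] <- kernel_probs(d[opp], kernel_width)
      W[k, same] <- -kernel_probs(d[same], kernel_width)
      valid[k] <- TRUE
    }
    if (!any(valid)) next
    z_list[[n]] <- W[valid, , drop = FALSE] %*% A
    pair_list[[n]] <- tibble(sample = n, endpoint = which(valid),
                             s = endpoints[valid])
  }
  keep <- !vapply(z_list, is.null, logical(1))
  Z <- do.call(rbind, z_list[keep])
  colnames(Z) <- colnames(X)
  structure(list(Z = Z, pairs = dplyr::bind_rows(pair_list[keep]),
                 kernel_width = kernel_width),
            class = "margin_vectors")
}

#' @export
print.margin_vectors <- function(x, ...) {
  cat(sprintf("<margin_vectors> %d (sample, endpoint) pairs x %d features\n",
              nrow(x$Z), ncol(x$Z)))
  invisible(x)
}

hinge_objective <- function(Z, w) sum(pmax(0, 1 - as.numeric(Z %*% w)))

#' Nonnegative l1-constrained hinge minimization
#'
#' Approximately minimizes `sum_i max(0, 1 - w' z_i)` over
#' `{w >= 0, ||w||_1 <= lambda}` by projected subgradient descent with step
#' `eta_0 / sqrt(t)`, Euclidean projection onto the feasible set, and monotone
#' acceptance (a step is halved until it does not increase the objective), so
#' the recorded objective trace is non-increasing.
#'
#' @param Z A `margin_vectors` object or a numeric matrix of margin vectors
#'   (rows).
#' @param lambda Positive l1 budget.
#' @param w_init Starting point; default `lambda/J` on every feature. Projected
#'   to the feasible set first.
#' @param max_iter Iteration budget, default 300.
#' @param step0 Initial step; default `lambda`.
#' @param tol Stop when the objective has improved less than this over 25
#'   iterations.
#' @return List with `w`, `objective`, the non-increasing `trace`, `n_iter`.
#' @export
solve_l1_hinge <- function(Z, lambda, w_init = NULL, max_iter = 300,
                           step0 = NULL, tol = 1e-9) {
  if (inherits(Z, "margin_vectors")) Z <- Z$Z
  if (!all(is.finite(Z))) stopf("margin vectors contain non-finite entries")
  assert_scalar_num(lambda, "lambda", lower = 1e-12)
  J <- ncol(Z)
  w <- project_l1_nonneg(w_init %||% rep(lambda / J, J), lambda)
  step0 <- step0 %||% lambda
  obj <- hinge_objective(Z, w)
  trace <- numeric(max_iter + 1L)
  trace[1L] <- obj
  stall <- 0L
  it <- 0L
  eta <- step0
  for (t in seq_len(max_iter)) {
    it <- t
    margins <- as.numeric(Z %*% w)
    active <- margins < 1
    if (!any(active)) { trace[t + 1L] <- obj; break }
    g <- -colSums(Z[active, , drop = FALSE])
    ## monotone acceptance with an adaptive step: resume from the last
    ## accepted step, halve on rejection, grow gently on easy acceptance
    accepted <- FALSE
    for (h in 1:30) {
      cand <- project_l1_nonneg(w - eta * g, lambda)
      cobj <- hinge_objective(Z, cand)
      if (cobj <= obj) {
        w <- cand; obj <- cobj; accepted <- TRUE
        if (h == 1L) eta <- eta * 1.3
        break
      }
      eta <- eta / 2
    }
    trace[t + 1L] <- obj
    stall <- if (accepted && trace[max(1L, t - 24L)] - obj > tol) 0L else stall + 1L
    if (stall >= 25L) break
  }
  w <- as.numeric(w)
  names(w) <- colnames(Z)
  list(w = w, objective = obj, trace = trace[seq_len(it + 1L)], n_iter = it)
}

#' Configuration for the feature selector
#'
#' @param tol Convergence threshold on the sup-norm change of `w` between
#'   fixed-point iterations.
#' @param max_iter Maximum fixed-point iterations.
#' @param tau Selection threshold on weights.
#' @param cv_folds Folds for lambda cross-validation.
#' @param solver_iter Iteration budget of the inner hinge solver.
#' @param max_endpoints Cap on the endpoint grid; grids longer than this are
#'   thinned to evenly spaced quantiles of the midpoint list (a size control
#'   for large cohorts; the full grid is the default).
#' @return A list of class `selector_config`.
#' @export
selector_config <- function(tol = 1e-4, max_iter = 50, tau = 1e-3,
                            cv_folds = 10, solver_iter = 300,
                            max_endpoints = Inf) {
  assert_scalar_num(tol, "tol", lower = 1e-16)
  structure(list(tol = tol, max_iter = max_iter, tau = tau,
                 cv_folds = cv_folds, solver_iter = solver_iter,
                 max_endpoints = max_endpoints),
            class = "selector_config")
}

thin_endpoints <- function(endpoints, max_endpoints) {
  K <- length(endpoints)
  if (!is.finite(max_endpoints) || K <= max_endpoints) return(endpoints)
  endpoints[unique(round(seq(1L, K, length.out = max_endpoints)))]
}

#' Fit feature weights by fixed-point recursion
#'
#' Alternates (i) computing expected margin vectors under the current weights
#' and (ii) solving the l1-constrained hinge problem, until the weights change
#' less than `config$tol` in sup-norm. With a suitable kernel width the
#' recursion converges to the same weights regardless of initialization.
#'
#' @inheritParams expected_margin_vectors
#' @param lambda Positive l1 budget on the weights.
#' @param config A [selector_config()].
#' @param w_init Optional starting weights (default uniform `lambda/J`).
#' @return An object of class `feature_weights`: nonnegative named weights `w`,
#'   `lambda`, `kernel_width`, `converged`, `n_iter`, per-iteration `delta`
#'   (sup-norm changes) and final hinge `objective`.
#' @export
fit_feature_weights <- function(X, times, lambda, kernel_width = 2,
                                config = selector_config(), w_init = NULL,
                                endpoints = NULL) {
  Xm <- as_values_matrix(X)
  src <- if (inherits(X, "sample_matrix")) X$feature_source else NULL
  J <- ncol(Xm)
  endpoints <- thin_endpoints(endpoints %||% compute_endpoints(times),
                              config$max_endpoints)
  w <- project_l1_nonneg(w_init %||% rep(lambda / J, J), lambda)
  deltas <- numeric(0)
  converged <- FALSE
  sol <- NULL
  for (iter in seq_len(config$max_iter)) {
    mv <- expected_margin_vectors(Xm, times, w, endpoints, kernel_width)
    sol <- solve_l1_hinge(mv, lambda, w_init = w, max_iter = config$solver_iter)
    delta <- max(abs(sol$w - w))
    deltas <- c(deltas, delta)
    w <- sol$w
    if (delta < config$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("fixed-point recursion did not converge in %d iterations (last delta %.3g)",
          config$max_iter, tail(deltas, 1L))
  names(w) <- colnames(Xm)
  structure(list(w = w, lambda = lambda, kernel_width = kernel_width,
                 converged = converged, n_iter = length(deltas),
                 delta = deltas, objective = sol$objective,
                 feature_source = src, tau = config$tau),
            class = "feature_weights")
}

#' @export
print.feature_weights <- function(x, ...) {
  cat(sprintf(paste0("<feature_weights> %d features, lambda = %g, kappa = %g; ",
                     "%d selected at tau = %g; %s in %d iteration(s)\n"),
              length(x$w), x$lambda, x$kernel_width,
              sum(x$w > x$tau), x$tau,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Select features whose weight exceeds a threshold
#'
#' @param fw A [fit_feature_weights()] result.
#' @param tau Weight threshold, default `1e-3`.
#' @return A tibble with `index`, `feature`, `weight` and `source` (if known)
#'   of the selected features.
#' @export
select_features <- function(fw, tau = 1e-3) {
  idx <- which(unname(fw$w) > tau)
  if (length(idx) == 0L) warnf("no feature weight exceeds tau = %g", tau)
  out <- tibble(index = idx,
                feature = names(fw$w)[idx] %||% as.character(idx),
                weight = unname(fw$w[idx]))
  if (!is.null(fw$feature_source)) out$source <- fw$feature_source[idx]
  out
}

## Held-out margin classification error: margin vectors of validation samples
## are computed against the training samples and training endpoint grid; the
## score is the fraction with a negative expected margin (the endpoint
## decomposition's test-error objective; scale-invariant in lambda).
validation_margin_error <- function(X_tr, t_tr, X_val, t_val, w, kernel_width) {
  endpoints <- compute_endpoints(t_tr)
  wrong <- total <- 0L
  for (i in seq_len(nrow(X_val))) {
    A <- abs(sweep(X_tr, 2L, X_val[i, ], "-"))
    d <- as.numeric(A %*% w)
    for (s in endpoints) {
      same <- if (t_val[i] > s) which(t_tr > s) else which(t_tr < s)
      opp <- setdiff(seq_along(t_tr), same)
      opp <- opp[t_tr[opp] != s]
      if (length(same) == 0L || length(opp) == 0L) next
      z <- kernel_probs(d[opp], kernel_width) %*% A[opp, , drop = FALSE] -
        kernel_probs(d[same], kernel_width) %*% A[same, , drop = FALSE]
      total <- total + 1L
      if (sum(w * z) < 0) wrong <- wrong + 1L
    }
  }
  if (total == 0L) return(NA_real_)
  wrong / total
}

#' Choose the l1 budget by k-fold cross-validation
#'
#' For every lambda on the grid, fits the selector on each training fold and
#' scores the classification error of the held-out samples' expected margins
#' at the training endpoint splits (the fraction of negative margins, computed
#' against the training samples with the trained weights) — the unseen-data
#' objective of the endpoint decomposition. The choice is the sparsest lambda
#' whose mean error is within one standard error of the minimum, so
#' indistinguishable candidates resolve to the smaller budget.
#'
#' @inheritParams fit_feature_weights
#' @param lambda_grid Candidate lambdas.
#' @param folds Number of folds, default 10.
#' @param seed Seed for the fold assignment.
#' @return List with `lambda` (the choice) and a tibble `cv` of mean held-out
#'   margin error and its standard error per lambda.
#' @export
tune_lambda_cv <- function(X, times, lambda_grid, folds = 10, seed = 1,
                           kernel_width = 2, config = selector_config()) {
  if (length(lambda_grid) == 0L) stopf("empty lambda grid")
  Xm <- as_values_matrix(X)
  N <- nrow(Xm)
  folds <- min(folds, N)
  fold_id <- NULL
  for (attempt in seq_len(5L)) {
    fold_id <- withr::with_seed(seed + attempt - 1L,
                                sample(rep(seq_len(folds), length.out = N)))
    ok <- all(vapply(seq_len(folds), function(f) {
      length(unique(times[fold_id != f])) >= 2L
    }, logical(1)))
    if (ok) break
    if (attempt == 5L) stopf("could not build folds with >= 2 distinct training times")
  }
  grid <- sort(lambda_grid)
  per_fold <- vapply(grid, function(lam) {
    vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fw <- suppressWarnings(
        fit_feature_weights(Xm[tr, , drop = FALSE], times[tr], lam,
                            kernel_width, config))
      validation_margin_error(Xm[tr, , drop = FALSE], times[tr],
                              Xm[!tr, , drop = FALSE], times[!tr],
                              fw$w, kernel_width)
    }, numeric(1))
  }, numeric(folds))
  per_fold <- matrix(per_fold, nrow = folds)
  means <- colMeans(per_fold, na.rm = TRUE)
  ses <- apply(per_fold, 2L, stats::sd, na.rm = TRUE) / sqrt(folds)
  best <- which.min(means)
  pick <- min(which(means <= means[best] + ses[best] + 1e-12))
  list(lambda = grid[pick],
       cv = tibble(lambda = grid, mean_error = means, se = ses))
}
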