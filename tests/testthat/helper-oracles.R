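## Independent brute-force oracles used to freeze expected values. Each is a
## direct, unoptimized implementation kept deliberately separate from the
## package's code paths.

## Hinge objective on a grid over the 2-D feasible set {w >= 0, ||w||_1 <= lambda}.
grid_hinge_oracle <- function(Z, lambda, n_grid = 200) {
  g <- seq(0, lambda, length.out = n_grid)
  best <- Inf
  for (w1 in g) for (w2 in g) {
    if (w1 + w2 > lambda) next
    obj <- sum(pmax(0, 1 - (Z[, 1L] * w1 + Z[, 2L] * w2)))
    if (obj < best) best <- obj
  }
  best
}

## Expected margin vector for one (n, k) pair by direct summation.
brute_margin_vector <- function(X, times, w, s, n, width) {
  above <- which(times > s)
  below <- which(times < s)
  if (times[n] > s) { same <- setdiff(above, n); opp <- below }
  else { same <- setdiff(below, n); opp <- above }
  if (!length(same) || !length(opp)) return(NULL)
  d <- sapply(seq_len(nrow(X)), function(j) sum(w * abs(X[n, ] - X[j, ])))
  kq <- exp(-(d[opp] - min(d[opp])) / width); kq <- kq / sum(kq)
  kp <- exp(-(d[same] - min(d[same])) / width); kp <- kp / sum(kp)
  z <- rep(0, ncol(X))
  for (i in seq_along(opp)) z <- z + kq[i] * abs(X[n, ] - X[opp[i], ])
  for (i in seq_along(same)) z <- z - kp[i] * abs(X[n, ] - X[same[i], ])
  z
}

## Nearest-neighbor hypothesis margin vector |x_n - nearmiss| - |x_n - nearhit|.
nn_margin_vector <- function(X, times, w, s, n) {
  above <- which(times > s)
  below <- which(times < s)
  if (times[n] > s) { same <- setdiff(above, n); opp <- below }
  else { same <- setdiff(below, n); opp <- above }
  d <- sapply(seq_len(nrow(X)), function(j) sum(w * abs(X[n, ] - X[j, ])))
  miss <- opp[which.min(d[opp])]
  hit <- same[which.min(d[same])]
  abs(X[n, ] - X[miss, ]) - abs(X[n, ] - X[hit, ])
}

## Mutual-KNN adjacency by explicit double loop.
brute_mutual_knn <- function(X, K) {
  N <- nrow(X)
  D <- as.matrix(dist(X))
  knn <- lapply(seq_len(N), function(i) {
    d <- D[i, ]; d[i] <- Inf
    order(d)[seq_len(K)]
  })
  A <- matrix(FALSE, N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    if (i != j && j %in% knn[[i]] && i %in% knn[[j]]) A[i, j] <- TRUE
  A
}

## Similarity-silhouette by explicit double loop.
brute_silhouette <- function(S, labels) {
  N <- length(labels)
  sapply(seq_len(N), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) return(0)
    a <- mean(sapply(own, function(j) S[i, j]))
    others <- setdiff(unique(labels), labels[i])
    b <- max(sapply(others, function(c)
      mean(sapply(which(labels == c), function(j) S[i, j]))))
    a - b
  })
}

## Spearman rank correlation with average ranks, from the definition
## (Pearson correlation of midranks computed by hand).
brute_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

## Isotropic fixed-variance Gaussian-mixture EM, textbook form, no curve
## structure. Returns the full mu/p/loglik trajectories.
gmm_em_oracle <- function(X, mu, p, sigma, n_iter) {
  N <- nrow(X); M <- nrow(mu); J <- ncol(X)
  mu_trace <- list(); p_trace <- list(); ll_trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    logd <- matrix(0, N, M)
    for (m in seq_len(M))
      logd[, m] <- -rowSums(sweep(X, 2L, mu[m, ])^2) / (2 * sigma^2) -
        J / 2 * log(2 * pi * sigma^2) + log(p[m])
    mx <- apply(logd, 1L, max)
    ll_n <- mx + log(rowSums(exp(logd - mx)))
    ll_trace[it] <- sum(ll_n)
    R <- exp(logd - ll_n)
    Nm <- colSums(R)
    for (m in seq_len(M)) if (Nm[m] >= 1e-12) mu[m, ] <- colSums(R[, m] * X) / Nm[m]
    p <- Nm / N
    mu_trace[[it]] <- mu; p_trace[[it]] <- p
  }
  list(mu = mu_trace, p = p_trace, loglik = ll_trace)
}

## Fitting error by dense sampling of every segment.
dense_projection_error <- function(X, mu, edges, points_per_segment = 10000) {
  pts <- do.call(rbind, lapply(seq_len(nrow(edges)), function(e) {
    a <- mu[edges[e, 1L], ]; b <- mu[edges[e, 2L], ]
    tt <- seq(0, 1, length.out = points_per_segment)
    outer(1 - tt, a) + outer(tt, b)
  }))
  sum(apply(X, 1L, function(x) min(colSums((t(pts) - x)^2))))
}

## Product-limit estimator by hand.
brute_km <- function(times, events) {
  ev_times <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = ev_times, surv = NA_real_)
  for (i in seq_along(ev_times)) {
    ti <- ev_times[i]
    n_i <- sum(times >= ti)
    d_i <- sum(times == ti & events == 1)
    s <- s * (1 - d_i / n_i)
    out$surv[i] <- s
  }
  out
}

## Small labeled matrix fixture with ids.
named_matrix <- function(vals, n, j, prefix = "s") {
  m <- matrix(vals, n, j)
  dimnames(m) <- list(paste0(prefix, seq_len(n)), paste0("f", seq_len(j)))
  m
}
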