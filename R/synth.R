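## Seeded generators emulating the statistical structure the pipeline assumes:
## a branching one-dimensional manifold (trunk + bifurcation) embedded in a
## high-dimensional feature space among many irrelevant features, with planted
## clusters along the manifold and survival times monotonically (nonlinearly)
## linked to the progression coordinate under right censoring.

## Smooth curved backbone of a trunk + two arms, realized as fine polylines in
## j_rel dimensions (samples drawn at noise 0 lie exactly on the polyline).
## Every relevant feature gets its own random linear-plus-sinusoidal loading of
## the latent coordinate on each segment (a full-rank nonlinear embedding), so
## each relevant feature carries partially independent signal about t.
branching_backbone <- function(j_rel, t_split, nodes_per_segment) {
  ## Per-feature loading amplitudes are heterogeneous (as real gene loadings
  ## are) but bounded away from zero, so every relevant feature carries signal
  ## and the aggregate manifold stands well clear of the noise floor.
  sgn <- function() sample(c(-1, 1), j_rel, replace = TRUE)
  slope <- function() sgn() * stats::runif(j_rel, 1, 2)
  bend <- function() sgn() * stats::runif(j_rel, 0.15, 0.45)
  a_tr <- slope(); b_tr <- bend()
  a_A <- slope(); b_A <- bend()
  a_B <- slope(); b_B <- bend()
  trunk_f <- function(u) outer(u, a_tr) + outer(sin(pi * u / t_split), b_tr)
  Pb <- trunk_f(t_split)[1L, ]
  arm_f <- function(v, a, b) {
    rep(Pb, each = length(v)) + outer(v, a) +
      outer(sin(pi * v / (1 - t_split)), b)
  }
  u_grid <- seq(0, t_split, length.out = nodes_per_segment + 1L)
  v_grid <- seq(0, 1 - t_split, length.out = nodes_per_segment + 1L)
  list(trunk = trunk_f(u_grid),
       armA = arm_f(v_grid, a_A, b_A), armB = arm_f(v_grid, a_B, b_B),
       u_grid = u_grid, v_grid = v_grid, t_split = t_split)
}

## Position of latent coordinate t (branch "trunk"/"A"/"B") on the polyline.
backbone_position <- function(bb, t, branch) {
  interp <- function(grid, pts, val) {
    i <- findInterval(val, grid, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(grid) - 1L)
    w <- (val - grid[i]) / (grid[i + 1L] - grid[i])
    (1 - w) * pts[i, , drop = FALSE] + w * pts[i + 1L, , drop = FALSE]
  }
  out <- matrix(NA_real_, length(t), ncol(bb$trunk))
  tr <- branch == "trunk"
  if (any(tr)) out[tr, ] <- interp(bb$u_grid, bb$trunk, t[tr])
  for (arm in c("A", "B")) {
    sel <- branch == arm
    if (any(sel))
      out[sel, ] <- interp(bb$v_grid, bb[[paste0("arm", arm)]],
                           t[sel] - bb$t_split)
  }
  out
}

## Equal-arc-length cluster bins: at least one bin per segment, the rest
## allocated proportionally to segment length. Within each bin the coordinate
## is squeezed away from the bin edges by `gap` (relative width), creating the
## density gaps between consecutive clusters that give the manifold genuine
## cluster structure; returns both the labels and the adjusted coordinate.
plant_clusters <- function(t, branch, t_split, n_clusters, gap = 0,
                           fork_gap = 0) {
  seg_len <- c(trunk = t_split, A = 1 - t_split, B = 1 - t_split)
  n_bins <- stats::setNames(pmax(1L, round(n_clusters * seg_len / sum(seg_len))),
                            names(seg_len))
  while (sum(n_bins) > n_clusters) n_bins[which.max(n_bins)] <- n_bins[which.max(n_bins)] - 1L
  while (sum(n_bins) < n_clusters) n_bins[which.min(n_bins)] <- n_bins[which.min(n_bins)] + 1L
  offset <- c(trunk = 0L, A = n_bins[["trunk"]],
              B = n_bins[["trunk"]] + n_bins[["A"]])
  seg_lo <- ifelse(branch == "trunk", 0, t_split)
  seg_w <- ifelse(branch == "trunk", t_split, 1 - t_split)
  pos <- (t - seg_lo) / seg_w
  nb <- n_bins[branch]
  bin <- pmin(floor(pos * nb), nb - 1L)
  u <- pos * nb - bin
  pos2 <- (bin + gap / 2 + u * (1 - gap)) / nb
  ## arms start fork_gap of the way out: the bifurcation region itself is
  ## sparsely populated (commitment to a branch is a jump, not a continuum)
  pos2 <- ifelse(branch == "trunk", pos2, fork_gap + pos2 * (1 - fork_gap))
  list(cluster = as.integer(offset[branch] + bin + 1L),
       t = seg_lo + pos2 * seg_w)
}

#' Simulate branching-manifold expression data
#'
#' Samples a latent progression coordinate `t ~ Uniform(0, 1)` on a trunk that
#' bifurcates at `t_split` into two arms, embeds the backbone as smooth curved
#' polylines in `j_rel` relevant dimensions, adds isotropic Gaussian noise to
#' the relevant block, and appends `j_irrel` irrelevant i.i.d. noise features.
#' Planted cluster labels are equal arc-length bins along the tree.
#'
#' @param n Number of samples (>= 50).
#' @param j_rel Number of relevant (manifold-supporting) features, >= 2.
#' @param j_irrel Number of irrelevant noise features.
#' @param t_split Bifurcation coordinate in (0, 1), default 0.4.
#' @param noise_sd Gaussian noise on the relevant block, default 0.1.
#' @param irrel_sd Scale of the irrelevant features, default 0.3.
#' @param n_clusters Planted clusters (equal arc-length bins), default 5.
#' @param cluster_gap Relative width of the density gap separating consecutive
#'   bins (the latent coordinate is uniform within each shrunken bin), default
#'   0.65; 0 gives a gapless uniform coordinate.
#' @param fork_gap Fraction of each arm adjacent to the bifurcation left
#'   unpopulated (commitment to a branch is a jump), default 0.25.
#' @param seed Integer seed; output is bit-reproducible.
#' @param nodes_per_segment Polyline resolution of the true backbone.
#' @return List with `matrix` (a [sample_matrix()]) and `truth`: tibble
#'   (`sample_id`, `t`, `branch`, `cluster`), `relevant` feature indices, the
#'   true `backbone` as a `principal_curve_model` (usable with
#'   [fitting_error()]/[project_samples()]), `noise_sd`, `seed`.
#' @export
simulate_branching_data <- function(n = 600, j_rel = 20, j_irrel = 980,
                                    t_split = 0.4, noise_sd = 0.1,
                                    irrel_sd = 0.3, n_clusters = 5,
                                    cluster_gap = 0.65, fork_gap = 0.25,
                                    seed = 1, nodes_per_segment = 50) {
  if (n < 50) stopf("n must be >= 50")
  if (j_rel < 2) stopf("j_rel must be >= 2")
  if (t_split <= 0 || t_split >= 1) stopf("t_split must be in (0, 1)")
  if (cluster_gap < 0 || cluster_gap >= 1) stopf("cluster_gap must be in [0, 1)")
  withr::with_seed(seed, {
    bb <- branching_backbone(j_rel, t_split, nodes_per_segment)
    t <- stats::runif(n)
    branch <- ifelse(t <= t_split, "trunk",
                     sample(c("A", "B"), n, replace = TRUE))
    planted <- plant_clusters(t, branch, t_split, n_clusters, cluster_gap,
                              fork_gap)
    t <- planted$t
    pos <- backbone_position(bb, t, branch)
    rel <- pos + matrix(stats::rnorm(n * j_rel, sd = noise_sd), n)
    irrel <- matrix(stats::rnorm(n * j_irrel, sd = irrel_sd), n)
    J <- j_rel + j_irrel
    rel_idx <- sort(sample.int(J, j_rel))
    vals <- matrix(NA_real_, n, J)
    vals[, rel_idx] <- rel
    vals[, setdiff(seq_len(J), rel_idx)] <- irrel
    dimnames(vals) <- list(sprintf("S%04d", seq_len(n)),
                           sprintf("g%04d", seq_len(J)))
    cluster <- planted$cluster
    ## true backbone as a principal-curve model over the relevant block
    m <- nodes_per_segment + 1L
    mu <- rbind(bb$trunk, bb$armA[-1L, , drop = FALSE], bb$armB[-1L, , drop = FALSE])
    chains <- list(seq_len(m),
                   c(m, m + seq_len(m - 1L)),
                   c(m, (2L * m - 1L) + seq_len(m - 1L)))
    topo <- curve_topology(chains)
    backbone <- structure(list(mu = mu, p = rep(1 / nrow(mu), nrow(mu)),
                               sigma = max(noise_sd, 1e-6), topology = topo,
                               loglik = NA_real_, loglik_trace = numeric(0),
                               n_iter = 0L, converged = TRUE, root = 1L),
                          class = "principal_curve_model")
    list(matrix = sample_matrix(vals, "expression"),
         truth = list(samples = tibble(sample_id = rownames(vals), t = t,
                                       branch = branch, cluster = cluster),
                      relevant = rel_idx, backbone = backbone,
                      noise_sd = noise_sd, t_split = t_split, seed = seed))
  })
}

#' Simulate survival outcomes from a latent progression coordinate
#'
#' Survival time is a strictly monotone (nonlinear) link of the remaining
#' progression `1 - t` plus Gaussian noise, so early-progression samples live
#' longest. An independent fraction `censor_rate` of samples is right-censored
#' at a uniform time before their true event. Also adds covariates: an ordinal
#' `grade` and a continuous `progression_score`, both increasing with `t`, and
#' an unrelated `age`.
#'
#' @param truth The `truth` component of [simulate_branching_data()].
#' @param link Strictly monotone increasing link from remaining progression to
#'   years; default `function(u) 2 + 20 * u^1.5`.
#' @param noise_sd Gaussian noise on the survival time (years), default 0.5.
#' @param censor_rate Probability of censoring, in \[0, 1).
#' @param seed Integer seed.
#' @return A clinical tibble (`sample_id`, `time`, `event`, `grade`,
#'   `progression_score`, `age`).
#' @export
simulate_survival <- function(truth, link = NULL, noise_sd = 0.5,
                              censor_rate = 0.2, seed = 1) {
  if (censor_rate < 0 || censor_rate >= 1) stopf("censor_rate must be in [0, 1)")
  link <- link %||% function(u) 2 + 20 * u^1.5
  t <- truth$samples$t
  withr::with_seed(seed, {
    true_time <- pmax(link(1 - t) + stats::rnorm(length(t), sd = noise_sd), 0.01)
    censored <- stats::runif(length(t)) < censor_rate
    time <- ifelse(censored, stats::runif(length(t), 0, true_time), true_time)
    grade <- pmin(3L, pmax(1L, findInterval(t + stats::rnorm(length(t), sd = 0.08),
                                            c(1 / 3, 2 / 3)) + 1L))
    clinical_table(tibble(sample_id = truth$samples$sample_id,
                          time = time, event = as.integer(!censored),
                          grade = grade,
                          progression_score = t + stats::rnorm(length(t), sd = 0.1),
                          age = stats::runif(length(t), 30, 85)))
  })
}

#' Simulate well-separated Gaussian blobs
#'
#' Isotropic unit-variance blobs whose centers are rescaled so every pairwise
#' center distance is at least `separation`.
#'
#' @param n_per Samples per blob.
#' @param C Number of blobs, >= 2.
#' @param separation Minimum pairwise center distance.
#' @param j Feature dimension.
#' @param seed Integer seed.
#' @return List with `matrix` (a [sample_matrix()]) and integer `labels`.
#' @export
simulate_blobs <- function(n_per = 100, C = 4, separation = 10, j = 10, seed = 1) {
  if (C < 2) stopf("need C >= 2 blobs")
  withr::with_seed(seed, {
    centers <- matrix(stats::rnorm(C * j), C)
    dmin <- min(dist(centers))
    if (dmin <= 0) stopf("degenerate random centers; change seed")
    centers <- centers * (separation / dmin)
    labels <- rep(seq_len(C), each = n_per)
    vals <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(C * n_per * j), C * n_per)
    dimnames(vals) <- list(sprintf("B%04d", seq_along(labels)),
                           sprintf("f%03d", seq_len(j)))
    list(matrix = sample_matrix(vals, "expression"), labels = labels)
  })
}

#' Simulate a two-line elbow fixture
#'
#' Points on two straight lines of slopes `slopes` meeting at
#' `(l_star, error_at_elbow)`, with optional Gaussian noise proportional to
#' the error range — the idealized (curve length, fitting error) trade-off the
#' elbow selector is meant to recover.
#'
#' @param l_star True intersection length.
#' @param slopes Two negative slopes (steep, shallow).
#' @param n_points Number of records, default 12.
#' @param noise_sd Noise as a fraction of the error range, default 0.
#' @param error_at_elbow Error at the intersection, default 5.
#' @param seed Integer seed.
#' @return Tibble with descending pseudo-`sigma`, `curve_length`,
#'   `fitting_error`, and the generating `arm`.
#' @export
simulate_elbow <- function(l_star = 20, slopes = c(-4, -0.3), n_points = 12,
                           noise_sd = 0, error_at_elbow = 5, seed = 1) {
  if (length(slopes) != 2L || any(slopes >= 0)) stopf("need two negative slopes")
  withr::with_seed(seed, {
    lengths <- seq(0.3 * l_star, 2 * l_star, length.out = n_points)
    err <- ifelse(lengths <= l_star,
                  error_at_elbow + slopes[1L] * (lengths - l_star),
                  error_at_elbow + slopes[2L] * (lengths - l_star))
    if (noise_sd > 0)
      err <- err + stats::rnorm(n_points, sd = noise_sd * diff(range(err)))
    tibble(sigma = seq(2, 0.1, length.out = n_points),
           curve_length = lengths, fitting_error = err,
           arm = ifelse(lengths <= l_star, "left", "right"))
  })
}

#' Benchmark cohort for feature selection
#'
#' Generates a branching-manifold cohort with survival outcomes, applies the
#' short-follow-up censoring filter, subsamples exactly `n` survivors
#' (deterministically), and robust-scales the features — the fixed study
#' conditions for the selection benchmark: 20 relevant among 1,000 features,
#' a monotone nonlinear survival link, right censoring.
#'
#' @param n Cohort size after filtering, default 150.
#' @param j_rel,j_irrel Feature split, defaults 20 / 980.
#' @param seed Integer seed.
#' @param min_years Censoring-filter threshold, default 10.
#' @param cluster_gap Cluster density gap; 0 by default — survival carries the
#'   progression continuum, so the selection benchmark uses the gapless
#'   manifold (within-cluster survival order is pure noise otherwise).
#' @return List with the scaled `matrix`, `clinical`, `truth` (filtered), and
#'   `relevant` indices.
#' @export
simulate_selection_cohort <- function(n = 150, j_rel = 20, j_irrel = 980,
                                      seed = 1, min_years = 10,
                                      cluster_gap = 0) {
  sim <- simulate_branching_data(n = max(4 * n, 200), j_rel = j_rel,
                                 j_irrel = j_irrel, seed = seed,
                                 cluster_gap = cluster_gap, fork_gap = 0)
  clin <- simulate_survival(sim$truth, censor_rate = 0.3, seed = seed + 1L)
  flt <- filter_short_followup(sim$matrix, clin, min_years = min_years)
  ids <- sample_ids(flt$matrix)
  if (length(ids) < n) stopf("filtered cohort smaller than n = %d", n)
  keep_ids <- withr::with_seed(seed + 2L, sort(sample(ids, n)))
  keep <- match(keep_ids, ids)
  m <- sample_matrix(flt$matrix$values[keep, , drop = FALSE],
                     flt$matrix$feature_source)
  tr <- sim$truth
  tr$samples <- tr$samples[match(keep_ids, tr$samples$sample_id), ]
  list(matrix = robust_scale(m),
       clinical = flt$clinical[keep, ],
       truth = tr, relevant = sim$truth$relevant)
}
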