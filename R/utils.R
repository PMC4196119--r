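## Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("`%s` must be a finite number in [%s, %s]", name, lower, upper)
  invisible(x)
}

## Row-wise log-sum-exp of a matrix, guarding -Inf rows.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

## Squared Euclidean distances between rows of a and rows of b (n_a x n_b).
cross_sqdist <- function(a, b) {
  d <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d[d < 0] <- 0
  d
}

#' Normalized mutual information between two labelings
#'
#' Symmetric NMI with sqrt normalization, `I(a;b) / sqrt(H(a) H(b))`. Used to
#' compare recovered cluster labels with planted ones.
#'
#' @param a,b Vectors of labels of equal length.
#' @return A number in \[0, 1\].
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  pjk <- tab / n
  nz <- pjk > 0
  mi <- sum(pjk[nz] * log(pjk[nz] / (pj[row(pjk)[nz]] * pk[col(pjk)[nz]])))
  ha <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  hb <- -sum(pk[pk > 0] * log(pk[pk > 0]))
  if (ha == 0 || hb == 0) return(as.numeric(ha == hb))
  mi / sqrt(ha * hb)
}

## Euclidean projection of v onto {w >= 0, sum(w) <= radius}.
project_l1_nonneg <- function(v, radius) {
  w <- pmax(v, 0)
  s <- sum(w)
  if (s <= radius) return(w)
  u <- sort(w, decreasing = TRUE)
  css <- cumsum(u)
  j <- seq_along(u)
  rho <- max(j[u > (css - radius) / j])
  theta <- (css[rho] - radius) / rho
  pmax(w - theta, 0)
}
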