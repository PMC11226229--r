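# Shared linear algebra. Population (n-denominator) variance conventions
# throughout: the total variance of a point cloud is the trace of its
# feature-space covariance, i.e. mean squared deviation from the centroid
# summed over features.

total_variance <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  sum(sweep(X, 2, ctr)^2) / nrow(X)
}

cov_n <- function(X, center = NULL) {
  X <- as.matrix(X)
  if (is.null(center)) center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  crossprod(Xc) / nrow(X)
}

# Mean-centered PCA of a point cloud.  Returns eigenvalues (n-denominator),
# the orthonormal basis (features x rank), and the centroid.
pca_decomp <- function(X, tol = 1e-12) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  ev <- sv$d^2 / nrow(X)
  keep <- ev > tol * max(ev, 0)
  if (max(ev, 0) <= 0) keep <- rep(FALSE, length(ev))
  list(values = ev[keep], basis = sv$v[, keep, drop = FALSE], center = ctr)
}

# Smallest k whose cumulative explained-variance fraction reaches the
# threshold (ties resolved toward the smaller k).
pick_k <- function(eigenvalues, threshold) {
  assert_that(length(eigenvalues) >= 1 && sum(eigenvalues) > 0,
              "cannot pick components from a zero spectrum", "degenerate_subspace")
  frac <- cumsum(eigenvalues) / sum(eigenvalues)
  which(frac >= threshold - 1e-12)[1]
}

# Fix each column's sign so its largest-magnitude coefficient is positive.
fix_signs <- function(B) {
  for (j in seq_len(ncol(B))) {
    i <- which.max(abs(B[, j]))
    if (B[i, j] < 0) B[, j] <- -B[, j]
  }
  B
}

# Affine projection of rows of X onto the subspace: subtract the subspace
# center, project onto span(basis), add the center back.
project_affine <- function(X, basis, center) {
  Xc <- sweep(as.matrix(X), 2, center)
  sweep(Xc %*% basis %*% t(basis), 2, center, `+`)
}

# Random orthonormal matrix via QR of a Gaussian, with a sign convention
# making it deterministic up to the RNG stream.
random_orthonormal <- function(n, k = n) {
  M <- matrix(stats::rnorm(n * n), n, n)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  Q <- sweep(Q, 2, d, `*`)
  Q[, seq_len(k), drop = FALSE]
}
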