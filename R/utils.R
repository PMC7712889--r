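#' @include AllClasses.R
NULL

# Population-SD z-score (divisor n, not n-1). Returns a vector of the same
# length; errors are the caller's job (zero variance handled upstream).
zscorePop <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  (x - m) / s
}

popSd <- function(x) sqrt(mean((x - mean(x))^2))

# Stationary distribution of a row-stochastic matrix (left eigenvector of
# eigenvalue 1, normalised to the simplex).
stationaryDistribution <- function(A) {
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

# Derive a per-unit substream seed from a base seed. Keeps results for unit i
# invariant to how many other units are simulated, and stays below 2^31.
substreamSeed <- function(seed, i) {
  as.integer((as.numeric(seed) + 48271 * as.numeric(i)) %% 2147483647)
}

# Draw one multivariate normal sample per row of `which` states using
# pre-computed Cholesky factors (list of upper-triangular R: Sigma = R'R).
rmvnormStates <- function(path, means, cholList) {
  T <- length(path)
  P <- ncol(means)
  Z <- matrix(rnorm(T * P), T, P)
  out <- matrix(0, T, P)
  for (s in unique(path)) {
    idx <- which(path == s)
    out[idx, ] <- Z[idx, , drop = FALSE] %*% cholList[[s]] +
      matrix(means[s, ], length(idx), P, byrow = TRUE)
  }
  out
}

# Deterministic orthonormal rows: type-II DCT basis restricted to K rows of
# length P. Used for default state mean maps.
dctRows <- function(K, P) {
  stopifnot(K <= P)
  out <- matrix(0, K, P)
  p <- seq_len(P) - 0.5
  for (s in seq_len(K)) {
    out[s, ] <- sqrt(2 / P) * cos(pi * s * p / P)
  }
  out
}
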