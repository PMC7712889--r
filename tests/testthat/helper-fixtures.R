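# Shared fixtures and independent oracles used across the suite.

# Small well-separated two-state configuration.
twoStateConfig <- function(nSubjects = 8, nTimepoints = 120, nParcels = 5,
                           persistence = 0.9, amplitude = 2, seed = 1, ...) {
  simulationConfig(
    nSubjects = nSubjects, nTimepoints = nTimepoints, nParcels = nParcels,
    nStates = 2,
    transitionMatrix = defaultTransitionMatrix(2, persistence),
    stateMeans = rbind(rep(amplitude, nParcels), rep(-amplitude, nParcels)),
    seed = seed, ...)
}

# Brute-force Viterbi oracle: enumerate all K^T paths and maximise the joint
# log-probability, breaking ties toward the lexicographically smallest path.
bruteForceViterbi <- function(X, means, covs, A, pi0) {
  K <- nrow(means)
  Tn <- nrow(X)
  logB <- sapply(seq_len(K), function(s) {
    mvtnormLogDens(X, means[s, ], covs[[s]])
  })
  logB <- matrix(logB, Tn, K)
  paths <- as.matrix(expand.grid(rev(replicate(Tn, seq_len(K),
                                               simplify = FALSE))))
  paths <- paths[, rev(seq_len(Tn)), drop = FALSE]  # column t = state at t
  best <- -Inf
  bestPath <- NULL
  for (i in seq_len(nrow(paths))) {
    p <- as.integer(paths[i, ])
    lp <- log(pi0[p[1]]) + logB[1, p[1]]
    if (Tn > 1) {
      for (t in 2:Tn) lp <- lp + log(A[p[t - 1], p[t]]) + logB[t, p[t]]
    }
    if (lp > best + 1e-12) { best <- lp; bestPath <- p }
  }
  bestPath
}

# Multivariate normal log density, written independently of the package.
mvtnormLogDens <- function(X, mu, Sigma) {
  P <- length(mu)
  Xc <- sweep(as.matrix(X), 2, mu)
  Si <- solve(Sigma)
  -0.5 * (P * log(2 * pi) + determinant(Sigma)$modulus[1] +
            rowSums((Xc %*% Si) * Xc))
}

# Run-length dwell-time oracle.
dwellOracle <- function(path, K) {
  out <- rep(NA_real_, K)
  runs <- split(path, cumsum(c(1, diff(path) != 0)))
  for (s in seq_len(K)) {
    lens <- lengths(runs)[vapply(runs, function(r) r[1] == s, logical(1))]
    if (length(lens)) out[s] <- mean(lens)
  }
  out
}

# Constant-FD motion trace fixture.
flatMotion <- function(id, fd, n = 100, scrub = 0.5) {
  new("MotionTrace", subjectId = id, fdMm = rep(fd, n),
      scrubThresholdMm = scrub)
}

# White-noise parcel time series fixture.
noiseSeries <- function(id, n = 100, p = 4, offset = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  new("ParcelTimeSeries", subjectId = id,
      values = matrix(rnorm(n * p), n, p) + offset, trSeconds = 3)
}
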