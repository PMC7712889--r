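randomTwoStateModel <- function(P = 2) {
  means <- matrix(rnorm(2 * P), 2, P)
  covs <- replicate(2, {
    M <- matrix(rnorm(P * P, sd = 0.3), P, P)
    crossprod(M) + diag(P)
  }, simplify = FALSE)
  A <- matrix(runif(4, 0.2, 0.8), 2, 2)
  A <- A / rowSums(A)
  pi0 <- runif(2); pi0 <- pi0 / sum(pi0)
  new("HmmModel", nStates = 2, means = means, covariances = covs,
      transitionMatrix = A, initialProbs = pi0, objectiveTrace = 0,
      runObjectives = 0, bestRun = 1, converged = TRUE, regularised = FALSE)
}

test_that("Viterbi decoding equals brute-force path enumeration", {
  set.seed(101)
  for (rep in 1:15) {
    m <- randomTwoStateModel()
    X <- matrix(rnorm(12), 6, 2)
    oracle <- bruteForceViterbi(X, m@means, m@covariances,
                                m@transitionMatrix, m@initialProbs)
    expect_identical(viterbiDecode(m, X), oracle)
  }
})

test_that("a single-state model decodes to a constant path", {
  m <- new("HmmModel", nStates = 1, means = matrix(0, 1, 3),
           covariances = list(diag(3)), transitionMatrix = matrix(1, 1, 1),
           initialProbs = 1, objectiveTrace = 0, runObjectives = 0,
           bestRun = 1, converged = TRUE, regularised = FALSE)
  expect_identical(viterbiDecode(m, matrix(rnorm(30), 10, 3)), rep(1L, 10))
})

test_that("exactly symmetric states break ties toward the lowest index", {
  m <- new("HmmModel", nStates = 2, means = matrix(0, 2, 2),
           covariances = list(diag(2), diag(2)),
           transitionMatrix = matrix(0.5, 2, 2), initialProbs = c(0.5, 0.5),
           objectiveTrace = 0, runObjectives = 0, bestRun = 1,
           converged = TRUE, regularised = FALSE)
  set.seed(4)
  expect_identical(viterbiDecode(m, matrix(rnorm(20), 10, 2)), rep(1L, 10))
})

test_that("dimension mismatches are rejected", {
  m <- randomTwoStateModel(P = 3)
  expect_error(viterbiDecode(m, matrix(0, 5, 2)), "parcel count mismatch")
})

test_that("state metrics match run-length enumeration on the toy path", {
  met <- computeStateMetrics(list(s = c(1L, 1L, 2L, 2L, 2L, 1L)), nStates = 2)
  expect_equal(unname(meanDwellTime(met)[1, ]), c(1.5, 3))
  expect_equal(unname(fractionalOccupancy(met)[1, ]), c(0.5, 0.5))
  expect_equal(switchingRate(met), 2 / 5)
})

test_that("constant and alternating paths give the extreme metrics", {
  met <- computeStateMetrics(list(a = rep(2L, 30)), nStates = 3)
  expect_equal(unname(meanDwellTime(met)[1, ]), c(NA, 30, NA))
  expect_equal(unname(fractionalOccupancy(met)[1, ]), c(0, 1, 0))
  expect_equal(switchingRate(met), 0)

  alt <- computeStateMetrics(list(a = rep(c(1L, 2L), 20)), nStates = 2)
  expect_equal(unname(meanDwellTime(alt)[1, ]), c(1, 1))
  expect_equal(switchingRate(alt), 1)
})

test_that("dwell metrics agree with an independent run-length oracle", {
  set.seed(12)
  for (i in 1:20) {
    path <- sample.int(3, 50, replace = TRUE)
    met <- computeStateMetrics(list(p = path), nStates = 3)
    expect_equal(unname(meanDwellTime(met)[1, ]), dwellOracle(path, 3))
  }
})

test_that("occupancy times T sums to T for every subject", {
  set.seed(13)
  paths <- lapply(1:10, function(i) sample.int(4, 60, replace = TRUE))
  met <- computeStateMetrics(paths, nStates = 4)
  expect_equal(unname(rowSums(fractionalOccupancy(met)) * 60), rep(60, 10))
})

test_that("empty path input is rejected", {
  expect_error(computeStateMetrics(list(), nStates = 2), "no paths")
  expect_error(computeStateMetrics(list(integer(0)), nStates = 2), "empty")
})

test_that("dwell-time standardisation applies the outlier rule", {
  set.seed(21)
  dt <- matrix(rgamma(100, 5), 20, 5)
  z <- standardiseDwellTimes(dt, sigma = 2.5)
  # columns centred
  expect_true(all(abs(colMeans(z)) < 0.7))
  # independent recount of replacements
  for (s in 1:5) {
    col <- dt[, s]
    zz <- (col - mean(col)) / sqrt(mean((col - mean(col))^2))
    expect_equal(sum(z[, s] == 0 & abs(zz) > 2.5), sum(abs(zz) > 2.5))
  }
  # no value beyond the threshold: output equals the plain z-scores
  dtSmall <- matrix(rep(c(1, 2, 3, 4), 2), 4, 2)
  zPlain <- apply(dtSmall, 2, function(c) {
    (c - mean(c)) / sqrt(mean((c - mean(c))^2))
  })
  expect_equal(unname(standardiseDwellTimes(dtSmall)), zPlain)
  # forced extreme value lands at exactly 0
  dtOut <- matrix(c(rep(1, 19), 30), 20, 1)
  expect_identical(standardiseDwellTimes(dtOut)[20, 1], 0)
  expect_error(standardiseDwellTimes(matrix(1, 5, 1)), "zero variance")
  expect_error(standardiseDwellTimes(matrix(1:4, 2, 2)), "at least 3")
})

test_that("never-visited states are mean-imputed to zero", {
  dt <- matrix(c(2, 3, 4, NA, 5, 6, 7, 8), 4, 2)
  z <- standardiseDwellTimes(dt)
  expect_identical(z[4, 1], 0)
})

test_that("state matching recovers relabellings exactly", {
  set.seed(31)
  A <- matrix(rnorm(7 * 17), 7, 17)
  perm <- sample(7)
  B <- A[perm, ]
  res <- matchStates(A, B)
  expect_equal(B[res$permutation, ], A, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(res$correlations, rep(1, 7), tolerance = 1e-12)
  idres <- matchStates(A, A)
  expect_identical(idres$permutation, 1:7)
})

test_that("independent random maps match poorly", {
  set.seed(32)
  meanCorr <- vapply(1:200, function(i) {
    mean(matchStates(matrix(rnorm(7 * 17), 7, 17),
                     matrix(rnorm(7 * 17), 7, 17))$correlations)
  }, numeric(1))
  expect_lt(mean(meanCorr), 0.8)
})

test_that("state-count mismatch in matching is rejected", {
  expect_error(matchStates(matrix(0, 2, 4), matrix(0, 3, 4)), "mismatch")
})

test_that("Viterbi agrees with the posterior argmax under strong separation", {
  cfg <- twoStateConfig(nSubjects = 4, nTimepoints = 150, amplitude = 10,
                        seed = 6)
  sim <- simulateHmmTimeseries(cfg)
  gm <- standardiseConcatenate(sim$timeSeries)
  fit <- fitGroupHmm(gm, 2, nRuns = 2, seed = 2)
  seqs <- decodeStates(fit, gm)
  agree <- vapply(seqs, function(s) {
    mean(s@viterbiPath == max.col(s@posteriors, ties.method = "first"))
  }, numeric(1))
  expect_true(all(agree >= 0.99))
})
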