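test_that("the same configuration and seed reproduce every output exactly", {
  cfg <- twoStateConfig(nSubjects = 4, nTimepoints = 40)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(lapply(a$timeSeries, function(t) t@values),
                   lapply(b$timeSeries, function(t) t@values))
  expect_identical(a$reports$items, b$reports$items)
  expect_identical(lapply(a$motion, function(m) m@fdMm),
                   lapply(b$motion, function(m) m@fdMm))
  expect_identical(a$gradientBasis, b$gradientBasis)
  expect_identical(a$groundTruth@statePaths, b$groundTruth@statePaths)
})

test_that("subject-level outputs are invariant to cohort size", {
  small <- twoStateConfig(nSubjects = 3, nTimepoints = 50)
  large <- twoStateConfig(nSubjects = 6, nTimepoints = 50)
  a <- simulateHmmTimeseries(small)
  b <- simulateHmmTimeseries(large)
  for (i in 1:3) {
    expect_identical(a$timeSeries[[i]]@values, b$timeSeries[[i]]@values)
  }
})

test_that("a single-state chain emits i.i.d. Gaussian data at the state mean", {
  cfg <- simulationConfig(nSubjects = 1, nTimepoints = 5000, nParcels = 3,
                          nStates = 1,
                          stateMeans = matrix(c(1, -2, 0.5), 1, 3),
                          seed = 7)
  sim <- simulateHmmTimeseries(cfg)
  v <- sim$timeSeries[[1]]@values
  se <- 1 / sqrt(nrow(v))
  expect_true(all(abs(colMeans(v) - c(1, -2, 0.5)) < 3 * se))
  expect_true(all(sim$groundTruth@statePaths[[1]] == 1L))
})

test_that("empirical transition frequencies and occupancy match the chain", {
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  cfg <- simulationConfig(nSubjects = 1, nTimepoints = 20000, nParcels = 3,
                          nStates = 2, transitionMatrix = A,
                          stateMeans = matrix(0, 2, 3), seed = 11)
  path <- simulateHmmTimeseries(cfg)$groundTruth@statePaths[[1]]
  for (i in 1:2) {
    from <- which(path[-length(path)] == i)
    freq <- table(factor(path[from + 1], levels = 1:2)) / length(from)
    expect_true(all(abs(freq - A[i, ]) < 0.01))
  }
  occ <- tabulate(path, 2) / length(path)
  expect_true(all(abs(occ - 0.5) < 0.01))  # stationary distribution
})

test_that("ground-truth dwell-times equal the metric recomputation exactly", {
  cfg <- twoStateConfig(nSubjects = 6, nTimepoints = 80)
  sim <- simulateHmmTimeseries(cfg)
  met <- computeStateMetrics(sim$groundTruth@statePaths, nStates = 2)
  expect_identical(unname(meanDwellTime(met)),
                   unname(sim$groundTruth@trueDwellTimes))
})

test_that("report items are bounded Likert scores", {
  cfg <- twoStateConfig(nSubjects = 40, nTimepoints = 60)
  co <- simulateCohort(cfg)
  expect_true(all(co$reports$items %in% 1:4))
  expect_true(all(co$wellbeing$items %in% 1:4))
  expect_type(co$reports$items[1, 1], "integer")
})

test_that("zero effect size leaves dwell-item correlations in the null band", {
  cfg <- simulationConfig(nSubjects = 200, nTimepoints = 100, nParcels = 4,
                          nStates = 2, nComponents = 3, nItems = 9,
                          reportEffectSize = 0, couplingStates = 1,
                          couplingComponents = 1, seed = 5)
  sim <- simulateHmmTimeseries(cfg)
  rep <- simulateReports(sim$groundTruth@trueDwellTimes, cfg)
  r <- cor(sim$groundTruth@trueDwellTimes[, 1], rep$componentScores)
  expect_true(all(abs(r) < 3 / sqrt(cfg@nSubjects)))
})

test_that("the planted effect size is recovered by regression across replicates", {
  cfg <- simulationConfig(nSubjects = 256, nTimepoints = 100, nParcels = 4,
                          nStates = 2, nComponents = 3, nItems = 9,
                          reportEffectSize = 0.5, couplingStates = 1,
                          couplingComponents = 1, seed = 3)
  dwell <- simulateHmmTimeseries(cfg)$groundTruth@trueDwellTimes
  z <- dwell[, 1]
  z[is.na(z)] <- mean(z, na.rm = TRUE)
  z <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
  betas <- vapply(seq_len(100), function(r) {
    rep <- simulateReports(dwell, cfg, seed = 10000 + r)
    unname(coef(lm(rep$componentScores[, 1] ~ z))[2])
  }, numeric(1))
  expect_lt(abs(mean(betas) - 0.5), 0.15)
  expect_true(mean(abs(betas - 0.5) < 0.15) > 0.9)
})

test_that("the gradient basis is centred, orthonormal and seed-dependent", {
  for (seed in c(1, 99)) {
    G <- simulateGradientBasis(17, seed = seed)
    expect_true(all(abs(colMeans(G)) < 1e-10))
    expect_true(max(abs(crossprod(G) - diag(3))) < 1e-10)
  }
  expect_false(isTRUE(all.equal(simulateGradientBasis(17, 1),
                                simulateGradientBasis(17, 2))))
  expect_error(simulateGradientBasis(2), "at least 3")
})

test_that("motion traces are non-negative with the configured exceedance rate", {
  cfg <- simulationConfig(nSubjects = 30, nTimepoints = 200, nParcels = 3,
                          nStates = 2, stateMeans = matrix(0, 2, 3),
                          motionMeanFdMm = 0.1, motionBadFraction = 0.1,
                          seed = 2)
  mot <- simulateMotion(cfg)
  fd <- unlist(lapply(mot, function(m) m@fdMm))
  expect_true(all(fd >= 0))
  expect_lt(abs(mean(fd > 0.5) - 0.1), 0.02)
})

test_that("a clean cohort passes the downstream exclusion rule untouched", {
  cfg <- twoStateConfig(nSubjects = 6, nTimepoints = 60,
                        motionMeanFdMm = 0.08, motionBadFraction = 0)
  co <- simulateCohort(cfg)
  ex <- applyExclusion(co$timeSeries, co$motion)
  expect_equal(sum(ex$report$excluded), 0)
})

test_that("invalid configurations are rejected with informative messages", {
  A <- matrix(c(0.9, 0.2, 0.1, 0.9), 2, 2, byrow = TRUE)  # rows sum to 1.1
  expect_error(simulationConfig(nStates = 2, nParcels = 3,
                                transitionMatrix = A,
                                stateMeans = matrix(0, 2, 3)),
               "sum to 1")
  badCov <- list(diag(3), matrix(0, 3, 3))  # state 2 not positive definite
  expect_error(simulationConfig(nStates = 2, nParcels = 3,
                                stateMeans = matrix(0, 2, 3),
                                stateCovs = badCov),
               "state 2")
  expect_error(simulationConfig(motionBadFraction = 1.5), "motionBadFraction")
})
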