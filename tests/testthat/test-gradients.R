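orthoBasis <- function(P = 17, seed = 71) simulateGradientBasis(P, seed)

test_that("the weighted distance sum evaluates the toy cases exactly", {
  expect_equal(weightedDistanceSum(matrix(0, 3, 3)), 0)
  expect_equal(weightedDistanceSum(rbind(c(0.5, 0, 0))), 0.25)
  expect_equal(weightedDistanceSum(rbind(c(0.3, 0.4, 0))), 0.2)
  # two states add up
  expect_equal(weightedDistanceSum(rbind(c(0.5, 0, 0), c(0.3, 0.4, 0))), 0.45)
  # signed maximum: a zero coordinate caps the weight at zero ...
  expect_equal(weightedDistanceSum(rbind(c(-0.3, -0.4, 0))), 0)
  # ... and an all-negative state contributes a negative weight
  expect_equal(weightedDistanceSum(rbind(c(-0.6, -0.8, -0.2))),
               sqrt(1.04) * -0.2)
  expect_equal(weightedDistanceSum(rbind(c(-0.3, -0.4, 0)),
                                   maxRule = "absolute"), 0.5 * 0.4)
  expect_error(weightedDistanceSum(rbind(c(Inf, 0, 0))), "finite")
})

test_that("the sum is invariant to state ordering", {
  set.seed(72)
  coords <- matrix(rnorm(21, sd = 0.4), 7, 3)
  expect_equal(weightedDistanceSum(coords),
               weightedDistanceSum(coords[sample(7), ]))
})

test_that("maps uncorrelated with the basis project to the origin", {
  G <- orthoBasis(10, seed = 73)
  set.seed(73)
  # a direction orthogonal to all three gradients and to the constant
  M <- cbind(G, rnorm(10))
  M <- qr.Q(qr(sweep(M, 2, colMeans(M))))
  proj <- projectStates(matrix(M[, 4], 1, 10), G)
  expect_lt(max(abs(coordinates(proj))), 1e-8)
})

test_that("affine images of a gradient hit the clipped maximum coordinate", {
  G <- orthoBasis(12, seed = 74)
  state <- 2.5 * G[, 1] + 7
  proj <- projectStates(matrix(state, 1, 12), G)
  expect_equal(unname(proj@rawCorrelations[1, 1]), 1, tolerance = 1e-12)
  # the coordinate is clipped before the Fisher transform, so it stays finite
  expect_equal(unname(coordinates(proj)[1, 1]), atanh(1 - 1e-7),
               tolerance = 1e-6)
  expect_lt(max(abs(coordinates(proj)[1, 2:3])), 1e-6)
})

test_that("a reversed toy map anti-correlates perfectly", {
  basis <- cbind(G1 = c(4, 3, 2, 1), G2 = c(1, -1, 1, -1),
                 G3 = c(-1, -1, 1, 1))
  proj <- projectStates(matrix(1:4, 1, 4), basis)
  expect_equal(unname(proj@rawCorrelations[1, 1]), -1, tolerance = 1e-12)
  expect_equal(unname(coordinates(proj)[1, 1]), atanh(-(1 - 1e-7)),
               tolerance = 1e-6)
})

test_that("projection is invariant to positive affine rescaling", {
  G <- orthoBasis(17, seed = 75)
  set.seed(75)
  M <- matrix(rnorm(7 * 17), 7, 17)
  a <- coordinates(projectStates(M, G))
  b <- coordinates(projectStates(3 * M + 2, G))
  c3 <- coordinates(projectStates(M, 0.5 * G + 1))
  expect_lt(max(abs(a - b)), 1e-10)
  expect_lt(max(abs(a - c3)), 1e-10)
})

test_that("projecting the basis onto itself isolates each axis", {
  G <- orthoBasis(15, seed = 76)
  proj <- projectStates(t(G), G)
  r <- proj@rawCorrelations
  expect_equal(unname(diag(r)), rep(1, 3), tolerance = 1e-12)
  expect_lt(max(abs(r[row(r) != col(r)])), 1e-8)
  expect_equal(unname(diag(coordinates(proj))), rep(atanh(1 - 1e-7), 3),
               tolerance = 1e-6)
})

test_that("zero-variance state maps are rejected by state index", {
  G <- orthoBasis(8, seed = 77)
  M <- rbind(rnorm(8), rep(1, 8))
  expect_error(projectStates(M, G), "state 2")
  expect_error(permutationNull(M, G, 10), "zero variance")
})

test_that("the permutation null is seeded, conservative and sized correctly", {
  G <- orthoBasis(17, seed = 78)
  set.seed(78)
  M <- matrix(rnorm(7 * 17), 7, 17)
  n1 <- permutationNull(M, G, nPermutations = 40, seed = 5)
  n2 <- permutationNull(M, G, nPermutations = 40, seed = 5)
  expect_identical(nullSums(n1), nullSums(n2))
  expect_equal(nrow(coordinates(n1)), 40 * 7)
  # reproduce the first permutation draw independently: same shuffles, and
  # each shuffle conserves the parcel-weight multiset by construction
  set.seed(5)
  Mp <- t(apply(M, 1, function(w) w[sample.int(17)]))
  expect_identical(sort(Mp[3, ]), sort(M[3, ]))
  z <- atanh(pmin(pmax(cor(t(Mp), G), -(1 - 1e-7)), 1 - 1e-7))
  expect_equal(unname(coordinates(n1)[1:7, ]), unname(z), tolerance = 1e-12)
  # the 95% band contains the nominal share of synthetic coordinates
  inBand <- rowMeans(
    (t(coordinates(n1)) >= n1@band95[, "lower"]) &
    (t(coordinates(n1)) <= n1@band95[, "upper"]))
  expect_true(all(abs(inBand - 0.95) < 0.02))
})

test_that("exceedance p follows the add-one permutation formula", {
  G <- orthoBasis(17, seed = 79)
  set.seed(79)
  M <- matrix(rnorm(7 * 17), 7, 17)
  null <- permutationNull(M, G, nPermutations = 300, seed = 2)
  over <- exceedanceTest(max(nullSums(null)) + 1, null)
  expect_equal(over$pValue, 1 / 301)
  expect_equal(over$verdict, "exceeds-all")
  med <- exceedanceTest(stats::median(nullSums(null)), null)
  expect_lt(abs(med$pValue - 0.5), 0.05)
  expect_equal(med$verdict, "within-null")
})
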