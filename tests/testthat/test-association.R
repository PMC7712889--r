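test_that("with one outcome the Wilks F equals the univariate F exactly", {
  set.seed(61)
  n <- 60
  X <- buildDesignMatrix(matrix(rnorm(n * 3), n, 3),
                         motion = rgamma(n, 2), age = rnorm(n, 21, 2),
                         gender = rbinom(n, 1, 0.5))
  y <- rnorm(n) + 0.4 * X[, "state2"]
  res <- fitMancova(matrix(y, n, 1), X)
  fit <- lm(y ~ X - 1)
  tvals <- summary(fit)$coefficients[, "t value"]
  names(tvals) <- colnames(X)
  tab <- mancovaTable(res)
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$fStat[i], unname(tvals[tab$predictor[i]]^2),
                 tolerance = 1e-10)
  }
  expect_equal(tab$df1, rep(1, 3))
  expect_equal(tab$df2, rep(n - ncol(X) - 1 + 1, 3))
})

test_that("Wilks' Lambda matches an independent MANOVA implementation", {
  skip_if_not_installed("car")
  set.seed(62)
  n <- 80
  dwell <- matrix(rnorm(n * 4), n, 4)
  motion <- rgamma(n, 2)
  age <- rnorm(n, 21, 2)
  Y <- matrix(rnorm(n * 3), n, 3) + dwell[, 2] %o% c(0.4, -0.2, 0.1)
  X <- buildDesignMatrix(dwell, motion = motion, age = age)
  res <- mancovaTable(fitMancova(Y, X))
  d <- data.frame(dwell, mo = as.numeric(scale(motion)),
                  ag = as.numeric(scale(age)))
  fit <- lm(Y ~ X1 + X2 + X3 + X4 + mo + ag, data = d)
  man <- summary(car::Manova(fit, test.statistic = "Wilks"))
  for (i in 1:4) {
    sscp <- man$multivariate.tests[[paste0("X", i)]]
    wilks <- det(sscp$SSPE) / det(sscp$SSPE + sscp$SSPH)
    expect_equal(res$wilksLambda[i], wilks, tolerance = 1e-8)
  }
})

test_that("Lambda is invariant to invertible recombination of the outcomes", {
  set.seed(63)
  n <- 70
  X <- buildDesignMatrix(matrix(rnorm(n * 3), n, 3), motion = rnorm(n))
  Y <- matrix(rnorm(n * 4), n, 4)
  M <- matrix(rnorm(16), 4, 4) + 4 * diag(4)  # invertible
  a <- mancovaTable(fitMancova(Y, X))
  b <- mancovaTable(fitMancova(Y %*% M, X))
  expect_equal(a$wilksLambda, b$wilksLambda, tolerance = 1e-10)
})

test_that("partial eta squared equals one minus Lambda", {
  set.seed(64)
  n <- 50
  X <- buildDesignMatrix(matrix(rnorm(n * 2), n, 2))
  res <- mancovaTable(fitMancova(matrix(rnorm(n * 3), n, 3), X))
  expect_equal(res$partialEtaSq, 1 - res$wilksLambda, tolerance = 1e-12)
})

test_that("an orthogonal extra covariate changes only the df", {
  set.seed(65)
  n <- 60
  dwell <- matrix(rnorm(n * 2), n, 2)
  Y <- matrix(rnorm(n * 3), n, 3)
  X <- buildDesignMatrix(dwell)
  # residualise a random vector against the design and the outcomes
  v <- rnorm(n)
  v <- residuals(lm(v ~ cbind(X, Y) - 1))
  X2 <- cbind(X, ortho = v)
  a <- mancovaTable(fitMancova(Y, X, testColumns = c("state1", "state2")))
  b <- mancovaTable(fitMancova(Y, X2, testColumns = c("state1", "state2")))
  expect_equal(a$wilksLambda, b$wilksLambda, tolerance = 1e-10)
  expect_equal(b$df2, a$df2 - 1)
})

test_that("p-values decrease monotonically with effect size", {
  set.seed(66)
  n <- 100
  x <- rnorm(n)
  noise <- matrix(rnorm(n * 3), n, 3)
  X <- buildDesignMatrix(matrix(x, n, 1))
  pvals <- vapply(c(0, 0.2, 0.4, 0.8), function(eff) {
    Y <- noise + x %o% rep(eff, 3)
    mancovaTable(fitMancova(Y, X))$pValue
  }, numeric(1))
  expect_true(all(diff(pvals) < 0))
})

test_that("degenerate designs are rejected with informative errors", {
  n <- 30
  X <- buildDesignMatrix(matrix(rnorm(n * 2), n, 2))
  Xbad <- cbind(X, X[, 2])
  expect_error(fitMancova(matrix(rnorm(n * 2), n, 2), Xbad), "rank deficient")
  expect_error(fitMancova(matrix(rnorm(10 * 9), 10, 9),
                          buildDesignMatrix(matrix(rnorm(10), 10, 1))),
               "need n >")
  expect_error(fitMancova(matrix(rnorm(20), 10, 2),
                          buildDesignMatrix(matrix(rnorm(8), 8, 1))),
               "row-aligned")
})

test_that("item-space betas follow from the component model", {
  set.seed(67)
  cfg <- twoStateConfig(nSubjects = 100, nTimepoints = 60)
  co <- simulateCohort(cfg)
  m <- pcaVarimax(co$reports$items)
  met <- computeStateMetrics(co$groundTruth@statePaths, nStates = 2)
  X <- buildDesignMatrix(standardiseDwellTimes(met))
  res <- fitMancova(componentScores(m), X, componentModel = m)
  expect_equal(dim(res@itemBetas), c(2, ncol(co$reports$items)))
  expect_equal(unname(res@itemBetas),
               unname(res@betas[2:3, ] %*% t(componentLoadings(m))))
})
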