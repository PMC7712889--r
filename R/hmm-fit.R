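#' @include AllClasses.R utils.R
NULL

# T x K matrix of Gaussian log densities, one column per state.
gaussianLogDensities <- function(X, means, covariances) {
  Tn <- nrow(X)
  P <- ncol(X)
  K <- nrow(means)
  logB <- matrix(0, Tn, K)
  for (s in seq_len(K)) {
    R <- chol(covariances[[s]])
    logdet <- 2 * sum(log(diag(R)))
    Xc <- sweep(X, 2, means[s, ])
    Y <- Xc %*% backsolve(R, diag(P))
    logB[, s] <- -0.5 * (P * log(2 * pi) + logdet + rowSums(Y * Y))
  }
  logB
}

# One EM (Baum-Welch) fit from a given initialisation. Returns parameters,
# the per-iteration log-likelihood trace and convergence/regularisation flags.
emFit <- function(X, blocks, K, means, covariances, A, pi0,
                  maxIter = 500, tol = 1e-6, covReg = 1e-6) {
  P <- ncol(X)
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    logB <- gaussianLogDensities(X, means, covariances)
    logpi <- log(pmax(pi0, 1e-300))
    gammaAll <- matrix(0, nrow(X), K)
    xiSum <- matrix(0, K, K)
    pi1 <- numeric(K)
    ll <- 0
    for (b in blocks) {
      fb <- .fb_cpp(logB[b, , drop = FALSE], logpi, A)
      gammaAll[b, ] <- fb$gamma
      xiSum <- xiSum + fb$xi_sum
      pi1 <- pi1 + as.numeric(fb$gamma1)
      ll <- ll + fb$loglik
    }
    trace <- c(trace, ll)
    if (iter > 1) {
      rel <- abs(ll - trace[iter - 1]) / (abs(trace[iter - 1]) + 1e-12)
      if (rel < tol) { converged <- TRUE; break }
    }
    # M-step
    Nk <- colSums(gammaAll)
    for (s in seq_len(K)) {
      if (Nk[s] < 1e-8) {  # empty state: reset to a diffuse component
        means[s, ] <- colMeans(X)
        covariances[[s]] <- diag(P)
        next
      }
      means[s, ] <- colSums(gammaAll[, s] * X) / Nk[s]
      Xc <- sweep(X, 2, means[s, ])
      covariances[[s]] <- crossprod(Xc * sqrt(gammaAll[, s])) / Nk[s] +
        covReg * diag(P)
    }
    rs <- rowSums(xiSum)
    if (K > 1) {
      A <- xiSum / ifelse(rs > 0, rs, 1)
      A[rs == 0, ] <- 1 / K
      A <- A / rowSums(A)
    }
    pi0 <- pi1 / sum(pi1)
  }
  regularised <- any(vapply(covariances, function(S) {
    min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 10 * covReg
  }, logical(1)))
  list(means = means, covariances = covariances, A = A, pi0 = pi0,
       trace = trace, converged = converged, regularised = regularised)
}

# k-means initialisation with a seeded random perturbation per restart.
initialiseRun <- function(X, K, runSeed, covReg) {
  P <- ncol(X)
  set.seed(runSeed)
  if (K == 1) {
    means <- matrix(colMeans(X), 1, P)
    covariances <- list(cov(X) * (nrow(X) - 1) / nrow(X) + covReg * diag(P))
  } else {
    km <- suppressWarnings(kmeans(X, centers = K, iter.max = 50, nstart = 1))
    means <- km$centers + matrix(rnorm(K * P, sd = 0.1), K, P)
    covariances <- lapply(seq_len(K), function(s) {
      idx <- which(km$cluster == s)
      if (length(idx) > P + 1) {
        cov(X[idx, , drop = FALSE]) + covReg * diag(P)
      } else {
        diag(P)
      }
    })
  }
  A <- defaultTransitionMatrix(K, persistence = if (K > 1) 0.8 else 1)
  pi0 <- rep(1 / K, K)
  list(means = means, covariances = covariances, A = A, pi0 = pi0)
}

#' Fit the group-level Gaussian-observation HMM
#'
#' Runs \code{nRuns} independently initialised EM (Baum-Welch) inferences on
#' the concatenated group matrix — one set of state means, covariances and
#' transition probabilities shared by all subjects, with the forward-backward
#' recursions restarted at each subject boundary — and returns the run with
#' the highest final log-likelihood. All runs' final objectives are kept for
#' stability inspection. Initialisation is k-means on the group matrix plus a
#' seeded random perturbation per run; covariances get a 1e-6 ridge after
#' every M-step and the model is flagged if that floor is still active at
#' convergence.
#'
#' @param group a \linkS4class{GroupMatrix} (or plain matrix, treated as one
#'   subject).
#' @param nStates number of states K.
#' @param nRuns number of random restarts (default 10).
#' @param seed base seed; run r uses a derived substream.
#' @param maxIter EM iteration cap (default 500); non-convergence returns the
#'   best-so-far parameters with a warning.
#' @param tol relative log-likelihood change declaring convergence.
#' @return a \linkS4class{HmmModel}.
#' @examples
#' cfg <- simulationConfig(nSubjects = 5, nStates = 2, nParcels = 4,
#'                         nTimepoints = 60, stateMeans = rbind(rep(2, 4), rep(-2, 4)))
#' sim <- simulateHmmTimeseries(cfg)
#' gm <- standardiseConcatenate(sim$timeSeries)
#' fit <- fitGroupHmm(gm, nStates = 2, nRuns = 2, seed = 1)
#' @export
fitGroupHmm <- function(group, nStates, nRuns = 10, seed = 1,
                        maxIter = 500, tol = 1e-6) {
  stopifnot(nStates >= 1, nRuns >= 1)
  if (is(group, "GroupMatrix")) {
    X <- group@values
    blocks <- split(seq_len(nrow(X)),
                    factor(group@subjectIndex, levels = group@retainedIds))
  } else {
    X <- as.matrix(group)
    blocks <- list(seq_len(nrow(X)))
  }
  if (nrow(X) < nStates) stop("fewer observations than states")
  covReg <- 1e-6

  fits <- vector("list", nRuns)
  objectives <- numeric(nRuns)
  for (r in seq_len(nRuns)) {
    init <- initialiseRun(X, nStates, substreamSeed(seed, 7 * r), covReg)
    fits[[r]] <- emFit(X, blocks, nStates, init$means, init$covariances,
                       init$A, init$pi0, maxIter = maxIter, tol = tol,
                       covReg = covReg)
    objectives[r] <- fits[[r]]$trace[length(fits[[r]]$trace)]
  }
  best <- which.max(objectives)
  fit <- fits[[best]]
  if (!fit$converged) {
    warning("EM did not converge within ", maxIter,
            " iterations; returning best-so-far parameters")
  }
  new("HmmModel", nStates = nStates, means = fit$means,
      covariances = fit$covariances, transitionMatrix = fit$A,
      initialProbs = fit$pi0, objectiveTrace = fit$trace,
      runObjectives = objectives, bestRun = best,
      converged = fit$converged, regularised = fit$regularised)
}

#' Total forward-pass log-likelihood of data under a fitted model
#'
#' @param model a \linkS4class{HmmModel}.
#' @param group a \linkS4class{GroupMatrix} or plain matrix.
#' @return total log-likelihood over subjects.
#' @export
hmmLogLik <- function(model, group) {
  if (is(group, "GroupMatrix")) {
    X <- group@values
    blocks <- split(seq_len(nrow(X)),
                    factor(group@subjectIndex, levels = group@retainedIds))
  } else {
    X <- as.matrix(group)
    blocks <- list(seq_len(nrow(X)))
  }
  logB <- gaussianLogDensities(X, model@means, model@covariances)
  logpi <- log(pmax(model@initialProbs, 1e-300))
  sum(vapply(blocks, function(b) {
    .fb_cpp(logB[b, , drop = FALSE], logpi, model@transitionMatrix)$loglik
  }, numeric(1)))
}
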