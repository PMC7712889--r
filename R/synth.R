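#' @include AllClasses.R utils.R
NULL

#' Sticky default transition matrix
#'
#' Row-stochastic K x K matrix with a common self-transition probability and
#' the remaining mass spread evenly over the other states. With the default
#' persistence of 0.9 and TR = 3 s the implied mean dwell-time is 10 TRs
#' (30 s), a typical timescale for fMRI network states.
#'
#' @param nStates number of states K.
#' @param persistence self-transition probability (default 0.9).
#' @return K x K row-stochastic matrix.
#' @export
defaultTransitionMatrix <- function(nStates, persistence = 0.9) {
  stopifnot(nStates >= 1, persistence > 0, persistence <= 1)
  if (nStates == 1) return(matrix(1, 1, 1))
  A <- matrix((1 - persistence) / (nStates - 1), nStates, nStates)
  diag(A) <- persistence
  A
}

#' Construct a simulation configuration
#'
#' Builds a validated \linkS4class{SimulationConfig}. The defaults reproduce
#' the study's acquisition geometry — 256 subjects, a 9-minute run at
#' TR = 3 s (180 volumes), 17 parcels — and a 7-state hidden Markov process.
#' Default state mean maps are orthonormal cosine patterns scaled to 1.5
#' (standardised signal units) with identity covariances, giving
#' well-separated but overlapping states; default coupling plants the
#' dwell-times of states 3 and 7 on report components 1 and 2.
#'
#' @param nSubjects cohort size.
#' @param trSeconds repetition time in seconds.
#' @param scanMinutes run duration; \code{nTimepoints} defaults to
#'   \code{round(scanMinutes * 60 / trSeconds)}.
#' @param nTimepoints volumes per subject (overrides \code{scanMinutes}).
#' @param nParcels observed dimensions.
#' @param nStates number of hidden states K.
#' @param transitionMatrix K x K row-stochastic matrix; default
#'   [defaultTransitionMatrix()].
#' @param stateMeans K x P matrix of state means; default scaled cosine rows.
#' @param stateCovs list of K covariance matrices; default identity.
#' @param nItems,nComponents report geometry (25 Likert items, 8 components).
#' @param couplingStates,couplingComponents which state dwell-times drive
#'   which components.
#' @param reportEffectSize coefficient of standardised dwell-time on each
#'   coupled component.
#' @param noiseSd component-level noise SD.
#' @param motionMeanFdMm expected FD of clean volumes (mm).
#' @param motionBadFraction expected fraction of volumes above the 0.5 mm
#'   scrub threshold.
#' @param wellbeingSubjects,wellbeingItems,wellbeingComponents well-being
#'   questionnaire geometry (subset of the cohort).
#' @param seed base seed for all simulation substreams.
#' @return a validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nSubjects = 4, nStates = 3, nParcels = 5)
#' nStates(cfg)
#' @export
simulationConfig <- function(nSubjects = 256,
                             trSeconds = 3,
                             scanMinutes = 9,
                             nTimepoints = NULL,
                             nParcels = 17,
                             nStates = 7,
                             transitionMatrix = NULL,
                             stateMeans = NULL,
                             stateCovs = NULL,
                             nItems = 25,
                             nComponents = 8,
                             couplingStates = NULL,
                             couplingComponents = NULL,
                             reportEffectSize = 0.5,
                             noiseSd = 1,
                             motionMeanFdMm = 0.15,
                             motionBadFraction = 0.02,
                             wellbeingSubjects = min(168, nSubjects),
                             wellbeingItems = 12,
                             wellbeingComponents = 3,
                             seed = 1) {
  if (is.null(nTimepoints)) nTimepoints <- round(scanMinutes * 60 / trSeconds)
  if (is.null(transitionMatrix)) transitionMatrix <- defaultTransitionMatrix(nStates)
  if (is.null(stateMeans)) stateMeans <- 1.5 * dctRows(nStates, nParcels)
  if (is.null(stateCovs)) {
    stateCovs <- replicate(nStates, diag(nParcels), simplify = FALSE)
  }
  if (is.null(couplingStates)) {
    couplingStates <- if (nStates >= 7 && nComponents >= 2) c(3, 7) else 1
  }
  if (is.null(couplingComponents)) {
    couplingComponents <- seq_along(couplingStates)
  }
  new("SimulationConfig",
    nSubjects = nSubjects, nTimepoints = nTimepoints, nParcels = nParcels,
    trSeconds = trSeconds, scanMinutes = scanMinutes, nStates = nStates,
    transitionMatrix = transitionMatrix, stateMeans = stateMeans,
    stateCovs = stateCovs, nItems = nItems, nComponents = nComponents,
    couplingStates = couplingStates, couplingComponents = couplingComponents,
    reportEffectSize = reportEffectSize, noiseSd = noiseSd,
    motionMeanFdMm = motionMeanFdMm, motionBadFraction = motionBadFraction,
    wellbeingSubjects = wellbeingSubjects, wellbeingItems = wellbeingItems,
    wellbeingComponents = wellbeingComponents, seed = seed)
}

#' Simulate Markov-switching Gaussian parcel time series
#'
#' For each subject, samples a hidden state path from the configured
#' transition matrix (initial state from its stationary distribution, so the
#' chain starts in equilibrium) and draws each volume from the active state's
#' multivariate Gaussian. Each subject uses a seed substream derived from the
#' base seed, so a subject's data do not change when the cohort grows.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{timeSeries} (list of
#'   \linkS4class{ParcelTimeSeries}) and \code{groundTruth}
#'   (\linkS4class{GroundTruth} with the hidden paths and their dwell-times;
#'   component scores are filled in by [simulateReports()] /
#'   [simulateCohort()]).
#' @export
simulateHmmTimeseries <- function(config) {
  validObject(config)
  K <- as.integer(config@nStates)
  P <- as.integer(config@nParcels)
  Tn <- as.integer(config@nTimepoints)
  N <- as.integer(config@nSubjects)
  A <- config@transitionMatrix
  pi0 <- stationaryDistribution(A)
  cholList <- lapply(config@stateCovs, chol)

  ids <- sprintf("sub-%03d", seq_len(N))
  ts <- vector("list", N)
  paths <- vector("list", N)
  for (i in seq_len(N)) {
    set.seed(substreamSeed(config@seed, i))
    path <- integer(Tn)
    path[1] <- sample.int(K, 1, prob = pi0)
    if (Tn > 1) {
      for (t in 2:Tn) path[t] <- sample.int(K, 1, prob = A[path[t - 1], ])
    }
    paths[[i]] <- path
    ts[[i]] <- new("ParcelTimeSeries", subjectId = ids[i],
                   values = rmvnormStates(path, config@stateMeans, cholList),
                   trSeconds = config@trSeconds)
  }
  dwell <- t(vapply(paths, meanDwellFromPath, numeric(K), K = K))
  rownames(dwell) <- ids
  names(paths) <- ids
  truth <- new("GroundTruth", statePaths = paths, trueDwellTimes = dwell,
               trueComponentScores = matrix(numeric(0), N, 0))
  list(timeSeries = ts, groundTruth = truth)
}

# Fixed sparse loading pattern: items assigned round-robin to components,
# loading 0.8 on the home component, 0 elsewhere.
sparseLoadingPattern <- function(nItems, nComponents) {
  L <- matrix(0, nItems, nComponents)
  for (i in seq_len(nItems)) L[i, ((i - 1) %% nComponents) + 1] <- 0.8
  L
}

#' Simulate Likert report items coupled to state dwell-times
#'
#' Latent component scores are a linear combination of standardised
#' dwell-times (coefficient \code{reportEffectSize} on the configured
#' state/component pairs, 0 elsewhere) plus Gaussian noise. Items are the
#' scores pushed through a fixed sparse loading pattern plus item noise,
#' then discretised to a 1-4 Likert scale at the quartile cut-points of each
#' item's latent values (rank information is preserved).
#'
#' @param dwellTimes subjects x K matrix of mean dwell-times (NA allowed for
#'   never-visited states; mean-imputed before standardisation).
#' @param config a \linkS4class{SimulationConfig}.
#' @param nItems,nComponents item/component geometry; default from config.
#' @param couplingStates,couplingComponents coupled pairs; default from
#'   config.
#' @param seed seed for the report noise stream; default derived from the
#'   config seed.
#' @return list with \code{items} (subjects x items integer matrix in 1..4),
#'   \code{loadings} (the generating items x components pattern) and
#'   \code{componentScores} (the latent subjects x components scores).
#' @export
simulateReports <- function(dwellTimes, config,
                            nItems = config@nItems,
                            nComponents = config@nComponents,
                            couplingStates = config@couplingStates,
                            couplingComponents = config@couplingComponents,
                            seed = substreamSeed(config@seed, 999983L)) {
  if (!all(is.finite(dwellTimes) | is.na(dwellTimes))) {
    stop("dwell-times must be finite")
  }
  if (!is.finite(config@reportEffectSize)) stop("effect size must be finite")
  n <- nrow(dwellTimes)
  z <- apply(dwellTimes, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    if (popSd(col) == 0) rep(0, length(col)) else zscorePop(col)
  })
  set.seed(seed)
  scores <- matrix(rnorm(n * nComponents, sd = config@noiseSd), n, nComponents)
  for (j in seq_along(couplingStates)) {
    comp <- couplingComponents[j]
    scores[, comp] <- scores[, comp] +
      config@reportEffectSize * z[, couplingStates[j]]
  }
  L <- sparseLoadingPattern(nItems, nComponents)
  latent <- scores %*% t(L) + matrix(rnorm(n * nItems, sd = 0.6), n, nItems)
  items <- apply(latent, 2, function(x) {
    cuts <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    as.integer(1L + findInterval(x, cuts))
  })
  items <- matrix(as.integer(items), n, nItems,
                  dimnames = list(rownames(dwellTimes),
                                  sprintf("item_%02d", seq_len(nItems))))
  list(items = items, loadings = L, componentScores = scores)
}

#' Simulate an orthogonal three-gradient basis
#'
#' Stand-in for the three connectivity-gradient maps the projection consumes:
#' three zero-mean, unit-norm, mutually orthogonal columns over parcels,
#' obtained by QR-orthonormalising a column-centred Gaussian matrix.
#'
#' @param nParcels number of parcels (must be >= 3).
#' @param seed seed for the Gaussian draw.
#' @return nParcels x 3 matrix with columns G1, G2, G3.
#' @export
simulateGradientBasis <- function(nParcels, seed = 1) {
  if (nParcels < 3) stop("need at least 3 parcels for a 3-gradient basis")
  set.seed(seed)
  X <- matrix(rnorm(nParcels * 3), nParcels, 3)
  X <- sweep(X, 2, colMeans(X))  # columns orthogonal to the constant vector
  Q <- qr.Q(qr(X))
  colnames(Q) <- c("G1", "G2", "G3")
  Q
}

#' Simulate per-subject framewise-displacement traces
#'
#' FD values are independent gamma draws: a clean volume has mean
#' \code{motionMeanFdMm} (shape 2), and with probability
#' \code{motionBadFraction} a volume is drawn above the 0.5 mm scrub
#' threshold instead. Only the exclusion rule consumes FD, so no temporal
#' autocorrelation is modelled. Per-subject seed substreams as in
#' [simulateHmmTimeseries()].
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list of \linkS4class{MotionTrace}, one per subject.
#' @export
simulateMotion <- function(config) {
  validObject(config)
  N <- as.integer(config@nSubjects)
  Tn <- as.integer(config@nTimepoints)
  out <- vector("list", N)
  for (i in seq_len(N)) {
    set.seed(substreamSeed(config@seed, 1048576 + i))
    bad <- runif(Tn) < config@motionBadFraction
    fd <- rgamma(Tn, shape = 2, scale = config@motionMeanFdMm / 2)
    fd[bad] <- 0.5 + rgamma(sum(bad), shape = 1.5, scale = 0.1)
    out[[i]] <- new("MotionTrace", subjectId = sprintf("sub-%03d", i),
                    fdMm = fd, scrubThresholdMm = 0.5)
  }
  out
}

#' Simulate cohort demographics
#'
#' Age drawn from a normal distribution matching the study cohort (mean
#' 20.7 years, SD 2.4) and gender as a binary draw with the cohort's female
#' proportion (169/256).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return data.frame with subjectId, age and gender (1 = female).
#' @export
simulateDemographics <- function(config) {
  N <- as.integer(config@nSubjects)
  set.seed(substreamSeed(config@seed, 999959L))
  data.frame(subjectId = sprintf("sub-%03d", seq_len(N)),
             age = rnorm(N, mean = 20.7, sd = 2.4),
             gender = rbinom(N, 1, 169 / 256))
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running every generator with consistent seeds: parcel
#' time series with ground-truth state paths, motion traces, experience
#' reports coupled to the configured dwell-times, well-being questionnaires
#' for the configured sub-cohort (coupled to the last configured state), and
#' an orthogonal gradient basis.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{timeSeries}, \code{motion},
#'   \code{reports}, \code{wellbeing} (items for the first
#'   \code{wellbeingSubjects} subjects), \code{demographics},
#'   \code{gradientBasis} and \code{groundTruth}.
#' @export
simulateCohort <- function(config) {
  sim <- simulateHmmTimeseries(config)
  motion <- simulateMotion(config)
  dwell <- sim$groundTruth@trueDwellTimes
  reports <- simulateReports(dwell, config)
  nw <- as.integer(config@wellbeingSubjects)
  wbStates <- config@couplingStates[length(config@couplingStates)]
  wellbeing <- simulateReports(
    dwell[seq_len(nw), , drop = FALSE], config,
    nItems = config@wellbeingItems,
    nComponents = config@wellbeingComponents,
    couplingStates = wbStates, couplingComponents = 1,
    seed = substreamSeed(config@seed, 999979L))
  basis <- simulateGradientBasis(config@nParcels,
                                 seed = substreamSeed(config@seed, 999961L))
  truth <- sim$groundTruth
  truth@trueComponentScores <- reports$componentScores
  list(timeSeries = sim$timeSeries, motion = motion, reports = reports,
       wellbeing = wellbeing, demographics = simulateDemographics(config),
       gradientBasis = basis, groundTruth = truth)
}
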