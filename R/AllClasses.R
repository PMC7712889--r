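#' @include neurostates-package.R
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Simulation configuration for the synthetic-data generator
#'
#' Holds every parameter of the synthetic cohort: acquisition geometry
#' (subjects, volumes, repetition time, parcels), the hidden Markov process
#' generating the parcel time series (number of states, transition matrix,
#' per-state Gaussian means and covariances), the coupling between state
#' dwell-times and latent report components, and the motion model. Use
#' [simulationConfig()] to construct one; the defaults reproduce the study
#' geometry (256 subjects, a 9-minute run at TR = 3 s giving 180 volumes,
#' 17 parcels, 7 states).
#'
#' @slot nSubjects number of simulated subjects.
#' @slot nTimepoints volumes per subject.
#' @slot nParcels number of parcels (observed dimensions).
#' @slot trSeconds repetition time in seconds.
#' @slot scanMinutes run duration in minutes (determines \code{nTimepoints}
#'   unless overridden).
#' @slot nStates number of hidden states K.
#' @slot transitionMatrix K x K row-stochastic transition matrix.
#' @slot stateMeans K x P matrix of state mean-activity maps.
#' @slot stateCovs list of K symmetric positive-definite P x P covariances.
#' @slot nItems number of Likert report items.
#' @slot nComponents number of latent report components.
#' @slot couplingStates,couplingComponents parallel integer vectors naming
#'   the (state, component) pairs whose dwell-time drives the component.
#' @slot reportEffectSize linear coefficient of standardised dwell-time on
#'   each coupled component.
#' @slot noiseSd standard deviation of component-level noise.
#' @slot motionMeanFdMm expected framewise displacement (mm) of clean volumes.
#' @slot motionBadFraction expected fraction of volumes exceeding the 0.5 mm
#'   scrub threshold.
#' @slot wellbeingSubjects number of subjects (taken from the start of the
#'   cohort) with well-being questionnaires.
#' @slot wellbeingItems,wellbeingComponents questionnaire geometry.
#' @slot seed base seed; per-subject substreams are derived from it.
#' @seealso [simulationConfig()], [simulateCohort()]
#' @export
setClass("SimulationConfig",
  representation(
    nSubjects = "numeric", nTimepoints = "numeric", nParcels = "numeric",
    trSeconds = "numeric", scanMinutes = "numeric",
    nStates = "numeric", transitionMatrix = "matrix",
    stateMeans = "matrix", stateCovs = "list",
    nItems = "numeric", nComponents = "numeric",
    couplingStates = "numeric", couplingComponents = "numeric",
    reportEffectSize = "numeric", noiseSd = "numeric",
    motionMeanFdMm = "numeric", motionBadFraction = "numeric",
    wellbeingSubjects = "numeric", wellbeingItems = "numeric",
    wellbeingComponents = "numeric",
    seed = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  K <- object@nStates
  P <- object@nParcels
  if (K < 1) msg <- c(msg, "nStates must be >= 1")
  A <- object@transitionMatrix
  if (!all(dim(A) == c(K, K))) {
    msg <- c(msg, sprintf("transitionMatrix must be %d x %d", K, K))
  } else {
    if (any(A < 0)) msg <- c(msg, "transitionMatrix has negative entries")
    if (any(abs(rowSums(A) - 1) > 1e-12)) {
      msg <- c(msg, "transitionMatrix rows must sum to 1 (within 1e-12)")
    }
  }
  if (!all(dim(object@stateMeans) == c(K, P))) {
    msg <- c(msg, sprintf("stateMeans must be %d x %d", K, P))
  }
  if (length(object@stateCovs) != K) {
    msg <- c(msg, "need one covariance per state")
  } else {
    for (s in seq_len(K)) {
      S <- object@stateCovs[[s]]
      if (!is.matrix(S) || !all(dim(S) == c(P, P))) {
        msg <- c(msg, sprintf("covariance of state %d must be %d x %d", s, P, P))
      } else if (max(abs(S - t(S))) > 1e-8) {
        msg <- c(msg, sprintf("covariance of state %d is not symmetric", s))
      } else if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
        msg <- c(msg, sprintf("covariance of state %d is not positive definite", s))
      }
    }
  }
  if (object@motionBadFraction < 0 || object@motionBadFraction > 1) {
    msg <- c(msg, "motionBadFraction must lie in [0, 1]")
  }
  if (object@motionMeanFdMm < 0) msg <- c(msg, "motionMeanFdMm must be >= 0")
  if (!is.finite(object@reportEffectSize)) {
    msg <- c(msg, "reportEffectSize must be finite")
  }
  if (length(object@couplingStates) != length(object@couplingComponents)) {
    msg <- c(msg, "couplingStates and couplingComponents must have equal length")
  }
  if (any(object@couplingStates > K) || any(object@couplingStates < 1)) {
    msg <- c(msg, "couplingStates out of 1..K")
  }
  if (any(object@couplingComponents > object@nComponents)) {
    msg <- c(msg, "couplingComponents out of 1..nComponents")
  }
  if (object@wellbeingSubjects > object@nSubjects) {
    msg <- c(msg, "wellbeingSubjects cannot exceed nSubjects")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated cohort
#'
#' Recovery targets stored alongside simulated data: the hidden state path of
#' every subject, the dwell-times implied by those paths, and the latent
#' component scores that generated the reports.
#'
#' @slot statePaths list of integer vectors (one per subject, values in 1..K).
#' @slot trueDwellTimes subjects x K matrix of mean dwell-times (TRs); NA for
#'   states a subject never visits.
#' @slot trueComponentScores subjects x components matrix of latent scores.
#' @export
setClass("GroundTruth",
  representation(
    statePaths = "list",
    trueDwellTimes = "matrix",
    trueComponentScores = "matrix"
  )
)

#' Parcel-level BOLD time series for one subject
#'
#' @slot subjectId subject identifier.
#' @slot values timepoints x parcels numeric matrix (no missing values).
#' @slot trSeconds repetition time in seconds.
#' @export
setClass("ParcelTimeSeries",
  representation(subjectId = "character", values = "matrix", trSeconds = "numeric")
)

setValidity("ParcelTimeSeries", function(object) {
  msg <- character()
  if (anyNA(object@values)) msg <- c(msg, "time series contains missing values")
  if (nrow(object@values) < 2) msg <- c(msg, "need at least 2 timepoints")
  if (length(msg)) msg else TRUE
})

#' Framewise-displacement trace for one subject
#'
#' @slot subjectId subject identifier.
#' @slot fdMm per-volume framewise displacement in millimetres.
#' @slot scrubThresholdMm FD above which a volume counts as motion-affected
#'   (default 0.5 mm).
#' @export
setClass("MotionTrace",
  representation(subjectId = "character", fdMm = "numeric", scrubThresholdMm = "numeric")
)

setValidity("MotionTrace", function(object) {
  msg <- character()
  if (any(object@fdMm < 0)) msg <- c(msg, "framewise displacement must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Standardised, concatenated group time-series matrix
#'
#' Rows are timepoints stacked over retained subjects in cohort order; each
#' subject's parcel series is z-scored (population SD) before concatenation,
#' so per subject and parcel the rows have mean 0 and SD 1.
#'
#' @slot values (retained subjects x timepoints) x parcels matrix.
#' @slot subjectIndex character vector mapping each row to its subject.
#' @slot retainedIds subject identifiers in concatenation order.
#' @export
setClass("GroupMatrix",
  representation(values = "matrix", subjectIndex = "character", retainedIds = "character")
)

setValidity("GroupMatrix", function(object) {
  msg <- character()
  if (length(object@subjectIndex) != nrow(object@values)) {
    msg <- c(msg, "subjectIndex length must equal row count")
  }
  if (!all(unique(object@subjectIndex) == object@retainedIds)) {
    msg <- c(msg, "subjectIndex order must follow retainedIds")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted group-level Gaussian-observation hidden Markov model
#'
#' One set of state parameters shared by all subjects (group inference);
#' state time courses are decoded per subject. Produced by [fitGroupHmm()].
#'
#' @slot nStates number of states K.
#' @slot means K x P matrix of state means (standardised parcel units); each
#'   row is a state mean-activity map.
#' @slot covariances list of K P x P state covariances.
#' @slot transitionMatrix K x K row-stochastic transition matrix.
#' @slot initialProbs initial state distribution.
#' @slot objectiveTrace per-iteration total log-likelihood of the selected run.
#' @slot runObjectives final objective of every restart.
#' @slot bestRun index of the selected restart.
#' @slot converged did the selected run converge before the iteration cap.
#' @slot regularised was the covariance floor active at convergence.
#' @export
setClass("HmmModel",
  representation(
    nStates = "numeric", means = "matrix", covariances = "list",
    transitionMatrix = "matrix", initialProbs = "numeric",
    objectiveTrace = "numeric", runObjectives = "numeric",
    bestRun = "numeric", converged = "logical", regularised = "logical"
  )
)

setValidity("HmmModel", function(object) {
  msg <- character()
  K <- object@nStates
  if (!all(dim(object@transitionMatrix) == c(K, K))) {
    msg <- c(msg, "transition matrix dimension mismatch")
  } else if (any(abs(rowSums(object@transitionMatrix) - 1) > 1e-10)) {
    msg <- c(msg, "transition matrix rows must sum to 1 (within 1e-10)")
  }
  if (abs(sum(object@initialProbs) - 1) > 1e-10) {
    msg <- c(msg, "initial probabilities must sum to 1")
  }
  if (nrow(object@means) != K) msg <- c(msg, "one mean map per state required")
  if (length(object@covariances) != K) msg <- c(msg, "one covariance per state required")
  if (length(msg)) msg else TRUE
})

#' Decoded state sequence for one subject
#'
#' @slot subjectId subject identifier.
#' @slot posteriors timepoints x K matrix of smoothed state probabilities
#'   (rows sum to 1).
#' @slot viterbiPath most probable state path (integers in 1..K).
#' @export
setClass("StateSequence",
  representation(subjectId = "character", posteriors = "matrix", viterbiPath = "integer")
)

setValidity("StateSequence", function(object) {
  msg <- character()
  if (any(abs(rowSums(object@posteriors) - 1) > 1e-8)) {
    msg <- c(msg, "posterior rows must sum to 1 (within 1e-8)")
  }
  K <- ncol(object@posteriors)
  if (any(object@viterbiPath < 1L | object@viterbiPath > K)) {
    msg <- c(msg, "viterbi path entries out of 1..K")
  }
  if (length(object@viterbiPath) != nrow(object@posteriors)) {
    msg <- c(msg, "path length must equal number of timepoints")
  }
  if (length(msg)) msg else TRUE
})

#' Per-subject state dynamics summaries
#'
#' Mean dwell-time (TRs), fractional occupancy and switching rate computed
#' from hard-classified (Viterbi) state paths by [computeStateMetrics()].
#'
#' @slot meanDwellTime subjects x K matrix; NA where a subject never visits
#'   a state.
#' @slot fractionalOccupancy subjects x K matrix; rows sum to 1.
#' @slot switchingRate per-subject switches per transition opportunity.
#' @slot subjectIds row identifiers.
#' @export
setClass("StateMetrics",
  representation(
    meanDwellTime = "matrix", fractionalOccupancy = "matrix",
    switchingRate = "numeric", subjectIds = "character"
  )
)

setValidity("StateMetrics", function(object) {
  msg <- character()
  if (any(abs(rowSums(object@fractionalOccupancy) - 1) > 1e-10)) {
    msg <- c(msg, "fractional occupancy rows must sum to 1 (within 1e-10)")
  }
  if (any(object@switchingRate < 0 | object@switchingRate > 1)) {
    msg <- c(msg, "switching rate must lie in [0, 1]")
  }
  dt <- object@meanDwellTime
  if (any(dt[!is.na(dt)] < 1)) {
    msg <- c(msg, "mean dwell-time must be >= 1 TR where a state occurs")
  }
  if (length(msg)) msg else TRUE
})

#' Varimax-rotated principal component decomposition of a report matrix
#'
#' Produced by [pcaVarimax()]: correlation-matrix PCA, Kaiser retention
#' (eigenvalue > 1), varimax rotation of the retained loadings, and
#' least-squares component scores.
#'
#' @slot loadings items x k rotated loading matrix.
#' @slot scores subjects x k component scores.
#' @slot eigenvalues all eigenvalues of the item correlation matrix.
#' @slot k number of retained components.
#' @slot varianceExplained proportion of total item variance per rotated
#'   component.
#' @slot itemLabels item names.
#' @export
setClass("ComponentModel",
  representation(
    loadings = "matrix", scores = "matrix", eigenvalues = "numeric",
    k = "numeric", varianceExplained = "numeric", itemLabels = "character"
  )
)

#' Wilks' Lambda MANCOVA results for dwell-time predictors
#'
#' One row per tested predictor: Wilks' Lambda, its exact single-df F
#' transform, degrees of freedom, p-value and partial eta squared, plus the
#' multivariate regression coefficients.
#'
#' @slot table data.frame with columns predictor, wilksLambda, fStat, df1,
#'   df2, pValue, partialEtaSq.
#' @slot betas predictors x outcomes coefficient matrix (all design columns).
#' @slot itemBetas optional predictors x items matrix after back-projection
#'   through component loadings.
#' @slot nTests number of dwell-time predictor tests run (no multiplicity
#'   correction is applied).
#' @export
setClass("MancovaResult",
  representation(
    table = "data.frame", betas = "matrix",
    itemBetas = "matrixOrNULL", nTests = "numeric"
  )
)

#' State maps projected into gradient space
#'
#' Each state mean-activity map is correlated with the three gradient maps;
#' the Fisher-z transformed correlations are the state's coordinates.
#'
#' @slot rawCorrelations K x 3 Pearson correlations in [-1, 1].
#' @slot coordinates K x 3 Fisher-z coordinates (correlations clipped to
#'   |r| <= 1 - 1e-7 before atanh).
#' @slot weightedDistanceSum set-level statistic: each state's distance from
#'   the origin weighted by its maximum coordinate, summed over states.
#' @slot maxRule "signed" (default) or "absolute" maximum in the weighting.
#' @export
setClass("StateProjection",
  representation(
    rawCorrelations = "matrix", coordinates = "matrix",
    weightedDistanceSum = "numeric", maxRule = "character"
  )
)

setValidity("StateProjection", function(object) {
  msg <- character()
  if (any(abs(object@rawCorrelations) > 1)) {
    msg <- c(msg, "raw correlations must lie in [-1, 1]")
  }
  if (!all(is.finite(object@coordinates))) {
    msg <- c(msg, "coordinates must be finite after clipping")
  }
  if (length(msg)) msg else TRUE
})

#' Permutation null for the gradient-space projection
#'
#' Each permutation independently shuffles the parcel weights of every state
#' map, projects the synthetic set and records its weighted distance sum.
#'
#' @slot nPermutations number of permutations.
#' @slot nStates states per permutation (synthetic states =
#'   nPermutations x nStates).
#' @slot syntheticCoords (nPermutations x nStates) x 3 coordinates.
#' @slot nullSums weighted distance sum of each synthetic set.
#' @slot band95 3 x 2 matrix: per-axis central 95% interval of synthetic
#'   state coordinates.
#' @slot seed seed used for the permutation stream.
#' @export
setClass("NullSummary",
  representation(
    nPermutations = "numeric", nStates = "numeric",
    syntheticCoords = "matrix", nullSums = "numeric",
    band95 = "matrix", seed = "numeric"
  )
)

setValidity("NullSummary", function(object) {
  msg <- character()
  if (nrow(object@syntheticCoords) != object@nPermutations * object@nStates) {
    msg <- c(msg, "synthetic state count must equal nPermutations x nStates")
  }
  if (length(object@nullSums) != object@nPermutations) {
    msg <- c(msg, "one null sum per permutation required")
  }
  if (length(msg)) msg else TRUE
})
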