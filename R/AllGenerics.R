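#' @include AllClasses.R
NULL

#' Number of hidden states
#' @param object a \linkS4class{SimulationConfig}, \linkS4class{HmmModel} or
#'   \linkS4class{NullSummary}.
#' @return integer count of states.
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' @rdname nStates
#' @export
setMethod("nStates", "SimulationConfig", function(object) as.integer(object@nStates))
#' @rdname nStates
#' @export
setMethod("nStates", "HmmModel", function(object) as.integer(object@nStates))
#' @rdname nStates
#' @export
setMethod("nStates", "NullSummary", function(object) as.integer(object@nStates))

#' State mean-activity maps
#' @param object a \linkS4class{HmmModel} or \linkS4class{SimulationConfig}.
#' @return K x P matrix; each row is a state's mean map over parcels.
#' @export
setGeneric("stateMeans", function(object) standardGeneric("stateMeans"))

#' @rdname stateMeans
#' @export
setMethod("stateMeans", "HmmModel", function(object) object@means)
#' @rdname stateMeans
#' @export
setMethod("stateMeans", "SimulationConfig", function(object) object@stateMeans)

#' Transition matrix of the hidden Markov chain
#' @param object a \linkS4class{HmmModel} or \linkS4class{SimulationConfig}.
#' @return K x K row-stochastic matrix.
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))

#' @rdname transitionMatrix
#' @export
setMethod("transitionMatrix", "HmmModel", function(object) object@transitionMatrix)
#' @rdname transitionMatrix
#' @export
setMethod("transitionMatrix", "SimulationConfig", function(object) object@transitionMatrix)

#' State covariance matrices
#' @param object a \linkS4class{HmmModel}.
#' @return list of K P x P covariance matrices.
#' @export
setGeneric("stateCovariances", function(object) standardGeneric("stateCovariances"))

#' @rdname stateCovariances
#' @export
setMethod("stateCovariances", "HmmModel", function(object) object@covariances)

#' Mean dwell-time matrix (TRs)
#' @param object a \linkS4class{StateMetrics}.
#' @return subjects x K matrix; NA where a subject never visits a state.
#' @export
setGeneric("meanDwellTime", function(object) standardGeneric("meanDwellTime"))

#' @rdname meanDwellTime
#' @export
setMethod("meanDwellTime", "StateMetrics", function(object) object@meanDwellTime)

#' Fractional occupancy matrix
#' @param object a \linkS4class{StateMetrics}.
#' @return subjects x K matrix of proportions (rows sum to 1).
#' @export
setGeneric("fractionalOccupancy", function(object) standardGeneric("fractionalOccupancy"))

#' @rdname fractionalOccupancy
#' @export
setMethod("fractionalOccupancy", "StateMetrics", function(object) object@fractionalOccupancy)

#' Per-subject switching rate
#' @param object a \linkS4class{StateMetrics}.
#' @return numeric vector of switches per transition opportunity.
#' @export
setGeneric("switchingRate", function(object) standardGeneric("switchingRate"))

#' @rdname switchingRate
#' @export
setMethod("switchingRate", "StateMetrics", function(object) object@switchingRate)

#' Rotated component loadings
#' @param object a \linkS4class{ComponentModel}.
#' @return items x k varimax-rotated loading matrix.
#' @export
setGeneric("componentLoadings", function(object) standardGeneric("componentLoadings"))

#' @rdname componentLoadings
#' @export
setMethod("componentLoadings", "ComponentModel", function(object) object@loadings)

#' Component scores
#' @param object a \linkS4class{ComponentModel}.
#' @return subjects x k matrix of least-squares component scores.
#' @export
setGeneric("componentScores", function(object) standardGeneric("componentScores"))

#' @rdname componentScores
#' @export
setMethod("componentScores", "ComponentModel", function(object) object@scores)

#' Gradient-space coordinates of the states
#' @param object a \linkS4class{StateProjection} or \linkS4class{NullSummary}.
#' @return K x 3 (or synthetic states x 3) matrix of Fisher-z coordinates.
#' @export
setGeneric("coordinates", function(object) standardGeneric("coordinates"))

#' @rdname coordinates
#' @export
setMethod("coordinates", "StateProjection", function(object) object@coordinates)
#' @rdname coordinates
#' @export
setMethod("coordinates", "NullSummary", function(object) object@syntheticCoords)

#' Null distribution of the weighted distance sum
#' @param object a \linkS4class{NullSummary}.
#' @return numeric vector, one weighted distance sum per permutation.
#' @export
setGeneric("nullSums", function(object) standardGeneric("nullSums"))

#' @rdname nullSums
#' @export
setMethod("nullSums", "NullSummary", function(object) object@nullSums)

#' MANCOVA test table
#' @param object a \linkS4class{MancovaResult}.
#' @return data.frame with one row per tested predictor (Wilks' Lambda, F,
#'   df1, df2, p, partial eta squared).
#' @export
setGeneric("mancovaTable", function(object) standardGeneric("mancovaTable"))

#' @rdname mancovaTable
#' @export
setMethod("mancovaTable", "MancovaResult", function(object) object@table)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  cohort : %d subjects x %d volumes (TR %.1f s, %g-min run)\n",
              as.integer(object@nSubjects), as.integer(object@nTimepoints),
              object@trSeconds, object@scanMinutes))
  cat(sprintf("  signal : %d parcels, %d hidden states\n",
              as.integer(object@nParcels), as.integer(object@nStates)))
  cat(sprintf("  reports: %d items -> %d components, effect size %.2f, noise SD %.2f\n",
              as.integer(object@nItems), as.integer(object@nComponents),
              object@reportEffectSize, object@noiseSd))
  cat(sprintf("  motion : mean FD %.2f mm, bad fraction %.2f\n",
              object@motionMeanFdMm, object@motionBadFraction))
  cat(sprintf("  seed   : %d\n", as.integer(object@seed)))
})

setMethod("show", "HmmModel", function(object) {
  cat(sprintf("HmmModel: %d states x %d parcels\n",
              nStates(object), ncol(object@means)))
  cat(sprintf("  best of %d runs (run %d), final log-likelihood %.2f\n",
              length(object@runObjectives), as.integer(object@bestRun),
              object@objectiveTrace[length(object@objectiveTrace)]))
  cat(sprintf("  converged: %s; covariance floor active: %s\n",
              object@converged, object@regularised))
})

setMethod("show", "StateMetrics", function(object) {
  cat(sprintf("StateMetrics: %d subjects x %d states\n",
              nrow(object@meanDwellTime), ncol(object@meanDwellTime)))
  cat(sprintf("  mean dwell-time (TRs): %.2f; mean switching rate: %.3f\n",
              mean(object@meanDwellTime, na.rm = TRUE), mean(object@switchingRate)))
})

setMethod("show", "ComponentModel", function(object) {
  cat(sprintf("ComponentModel: %d items -> %d rotated components\n",
              nrow(object@loadings), as.integer(object@k)))
  cat(sprintf("  eigenvalues > 1: %d of %d; variance explained: %.1f%%\n",
              sum(object@eigenvalues > 1), length(object@eigenvalues),
              100 * sum(object@varianceExplained)))
})

setMethod("show", "MancovaResult", function(object) {
  cat(sprintf("MancovaResult: %d predictor tests (uncorrected)\n",
              as.integer(object@nTests)))
  print(object@table, digits = 4, row.names = FALSE)
})

setMethod("show", "StateProjection", function(object) {
  cat(sprintf("StateProjection: %d states in 3-gradient space (%s maximum)\n",
              nrow(object@coordinates), object@maxRule))
  cat(sprintf("  weighted distance sum: %.4f\n", object@weightedDistanceSum))
})

setMethod("show", "NullSummary", function(object) {
  cat(sprintf("NullSummary: %d permutations x %d states = %d synthetic states\n",
              as.integer(object@nPermutations), as.integer(object@nStates),
              nrow(object@syntheticCoords)))
  cat(sprintf("  null sums: median %.4f, max %.4f\n",
              stats::median(object@nullSums), max(object@nullSums)))
})
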