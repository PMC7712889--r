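#' @include AllClasses.R utils.R
NULL

#' Apply the motion exclusion rule
#'
#' A subject is excluded iff mean FD exceeds \code{fdMeanMax} (default
#' 0.3 mm) or the fraction of volumes with FD above the per-volume scrub
#' threshold exceeds \code{badFracMax} (default 0.15). Both boundaries are
#' exclusive: a subject at exactly 0.3 mm mean FD, or exactly 15% flagged
#' volumes, is retained.
#'
#' @param timeSeries list of \linkS4class{ParcelTimeSeries}.
#' @param motion list of \linkS4class{MotionTrace}; must cover every subject
#'   in \code{timeSeries}.
#' @param fdMeanMax mean-FD exclusion threshold in mm.
#' @param badFracMax maximum tolerated fraction of motion-affected volumes.
#' @return list with \code{retained} (the surviving
#'   \linkS4class{ParcelTimeSeries}, in input order) and \code{report}
#'   (data.frame per subject: meanFd, badFraction, excluded, rule).
#' @examples
#' cfg <- simulationConfig(nSubjects = 3, nStates = 2, nParcels = 4,
#'                         nTimepoints = 30)
#' sim <- simulateHmmTimeseries(cfg)
#' mot <- simulateMotion(cfg)
#' applyExclusion(sim$timeSeries, mot)$report
#' @export
applyExclusion <- function(timeSeries, motion, fdMeanMax = 0.3,
                           badFracMax = 0.15) {
  motIds <- vapply(motion, function(m) m@subjectId, character(1))
  rows <- lapply(timeSeries, function(ts) {
    j <- match(ts@subjectId, motIds)
    if (is.na(j)) stop("missing motion trace for subject ", ts@subjectId)
    m <- motion[[j]]
    if (length(m@fdMm) != nrow(ts@values)) {
      stop("motion trace length mismatch for subject ", ts@subjectId)
    }
    meanFd <- mean(m@fdMm)
    badFrac <- mean(m@fdMm > m@scrubThresholdMm)
    rule <- if (meanFd > fdMeanMax) {
      "mean-fd"
    } else if (badFrac > badFracMax) {
      "bad-fraction"
    } else {
      ""
    }
    data.frame(subjectId = ts@subjectId, meanFd = meanFd,
               badFraction = badFrac, excluded = nzchar(rule), rule = rule,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(retained = timeSeries[!report$excluded], report = report)
}

#' Standardise per subject and concatenate into the group matrix
#'
#' Each subject's parcel series is z-scored per parcel (mean 0, SD 1 with
#' population SD, divisor n) and the subjects are stacked row-wise in input
#' order, producing the (subjects x timepoints) x parcels matrix the
#' group-level HMM consumes.
#'
#' @param retained non-empty list of \linkS4class{ParcelTimeSeries} with a
#'   consistent parcel count.
#' @return a \linkS4class{GroupMatrix}.
#' @export
standardiseConcatenate <- function(retained) {
  if (length(retained) == 0) stop("no retained subjects")
  P <- ncol(retained[[1]]@values)
  blocks <- lapply(retained, function(ts) {
    if (ncol(ts@values) != P) {
      stop("parcel count mismatch for subject ", ts@subjectId)
    }
    v <- ts@values
    for (p in seq_len(P)) {
      if (popSd(v[, p]) == 0) {
        stop("zero-variance parcel ", p, " in subject ", ts@subjectId)
      }
      v[, p] <- zscorePop(v[, p])
    }
    v
  })
  ids <- vapply(retained, function(ts) ts@subjectId, character(1))
  values <- do.call(rbind, blocks)
  idx <- rep(ids, vapply(blocks, nrow, integer(1)))
  new("GroupMatrix", values = values, subjectIndex = idx, retainedIds = ids)
}
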