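#' @include AllClasses.R
NULL

#' Write a simulated cohort to plain-text files
#'
#' Per-subject parcel time series as TSV (rows = timepoints, columns =
#' parcels, header row of parcel labels), motion traces and report items as
#' CSV with a subject-ID column, the gradient basis as TSV, and the ground
#' truth (state paths and dwell-times) as JSON.
#'
#' @param cohort output of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  for (ts in cohort$timeSeries) {
    v <- ts@values
    colnames(v) <- sprintf("parcel_%02d", seq_len(ncol(v)))
    write.table(v, file.path(dir, "timeseries", paste0(ts@subjectId, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  motion <- do.call(rbind, lapply(cohort$motion, function(m) {
    data.frame(subjectId = m@subjectId, volume = seq_along(m@fdMm),
               fdMm = m@fdMm)
  }))
  write.csv(motion, file.path(dir, "motion.csv"), row.names = FALSE)
  rep <- data.frame(subjectId = rownames(cohort$reports$items),
                    cohort$reports$items, check.names = FALSE)
  write.csv(rep, file.path(dir, "reports.csv"), row.names = FALSE)
  wb <- data.frame(subjectId = rownames(cohort$wellbeing$items),
                   cohort$wellbeing$items, check.names = FALSE)
  write.csv(wb, file.path(dir, "wellbeing.csv"), row.names = FALSE)
  write.table(cohort$gradientBasis, file.path(dir, "gradients.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- cohort$groundTruth
  jsonlite::write_json(
    list(statePaths = gt@statePaths,
         trueDwellTimes = gt@trueDwellTimes),
    file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}

#' Read per-subject parcel time series from a directory of TSV files
#'
#' @param dir directory containing one \code{<subjectId>.tsv} per subject.
#' @param trSeconds repetition time recorded on each series.
#' @return list of \linkS4class{ParcelTimeSeries}, sorted by subject ID.
#' @export
readParcelTimeSeries <- function(dir, trSeconds = 3) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no .tsv time-series files in ", dir)
  lapply(files, function(f) {
    v <- as.matrix(read.delim(f, check.names = FALSE))
    if (anyNA(v)) stop("missing values in ", f)
    new("ParcelTimeSeries", subjectId = sub("\\.tsv$", "", basename(f)),
        values = v, trSeconds = trSeconds)
  })
}

#' Read motion traces from the cohort CSV
#'
#' @param file CSV with columns subjectId, volume, fdMm.
#' @param scrubThresholdMm per-volume threshold recorded on each trace.
#' @return list of \linkS4class{MotionTrace}.
#' @export
readMotion <- function(file, scrubThresholdMm = 0.5) {
  d <- read.csv(file)
  lapply(split(d, d$subjectId), function(s) {
    new("MotionTrace", subjectId = s$subjectId[1],
        fdMm = s$fdMm[order(s$volume)], scrubThresholdMm = scrubThresholdMm)
  })
}

#' Read a report (or well-being) matrix from CSV
#'
#' @param file CSV whose first column is the subject ID; remaining columns
#'   are item scores.
#' @return numeric matrix with subject IDs as row names.
#' @export
readReports <- function(file) {
  d <- read.csv(file, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Read a parcels x 3 gradient basis from TSV
#'
#' @param file TSV with header G1, G2, G3.
#' @return numeric matrix.
#' @export
readGradientBasis <- function(file) {
  m <- as.matrix(read.delim(file))
  if (ncol(m) != 3) stop("gradient basis must have 3 columns")
  m
}

#' Save a fitted HMM as JSON
#'
#' @param model a \linkS4class{HmmModel}.
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeHmmModel <- function(model, file) {
  jsonlite::write_json(
    list(nStates = model@nStates, means = model@means,
         covariances = model@covariances,
         transitionMatrix = model@transitionMatrix,
         initialProbs = model@initialProbs,
         objectiveTrace = model@objectiveTrace,
         runObjectives = model@runObjectives, bestRun = model@bestRun,
         converged = model@converged, regularised = model@regularised),
    file, digits = NA)
  invisible(file)
}

#' Load a fitted HMM from JSON
#'
#' @param file path written by [writeHmmModel()].
#' @return a \linkS4class{HmmModel}.
#' @export
readHmmModel <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  covs <- lapply(seq_len(j$nStates), function(s) {
    m <- j$covariances[s, , ]
    matrix(m, nrow = dim(j$covariances)[2])
  })
  new("HmmModel", nStates = j$nStates, means = j$means, covariances = covs,
      transitionMatrix = j$transitionMatrix, initialProbs = j$initialProbs,
      objectiveTrace = j$objectiveTrace, runObjectives = j$runObjectives,
      bestRun = j$bestRun, converged = j$converged,
      regularised = j$regularised)
}
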