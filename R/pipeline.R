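#' @include AllClasses.R synth.R ingest.R hmm-fit.R hmm-decode.R behaviour.R
#' @include association.R gradients.R
NULL

#' End-to-end pipeline configuration
#'
#' Bundles the synthetic-cohort configuration with every analysis setting:
#' number of states (default 7, with 9 as the standard robustness
#' alternative), number of HMM restarts (10), number of permutations (300),
#' the motion-exclusion thresholds (mean FD 0.3 mm; more than 15% of volumes
#' above the 0.5 mm scrub threshold), the dwell-time outlier rule (2.5
#' sigma) and the seed.
#'
#' @slot simulation a \linkS4class{SimulationConfig}.
#' @slot nStates states for the HMM fit.
#' @slot nRuns HMM restarts.
#' @slot nPermutations permutations for the gradient-space null.
#' @slot seed analysis seed (fitting and permutations).
#' @slot outlierSigma dwell-time outlier threshold.
#' @slot fdMeanMax,badFracMax,scrubThresholdMm motion-exclusion thresholds.
#' @slot maxRule weighting rule for the distance sum ("signed" or
#'   "absolute").
#' @export
setClass("PipelineConfig",
  representation(
    simulation = "SimulationConfig",
    nStates = "numeric", nRuns = "numeric", nPermutations = "numeric",
    seed = "numeric", outlierSigma = "numeric",
    fdMeanMax = "numeric", badFracMax = "numeric",
    scrubThresholdMm = "numeric", maxRule = "character"
  )
)

#' Construct a pipeline configuration
#'
#' @param simulation a \linkS4class{SimulationConfig}; default
#'   [simulationConfig()].
#' @param nStates HMM states (default: the simulation's state count).
#' @param nRuns HMM restarts (default 10).
#' @param nPermutations permutations for the null (default 300).
#' @param seed analysis seed.
#' @param outlierSigma dwell-time outlier threshold (default 2.5).
#' @param fdMeanMax mean-FD exclusion threshold in mm (default 0.3).
#' @param badFracMax maximum tolerated motion-affected fraction (default
#'   0.15).
#' @param scrubThresholdMm per-volume FD threshold (default 0.5).
#' @param maxRule "signed" or "absolute" maximum in the distance weighting.
#' @return a \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(simulation = simulationConfig(),
                           nStates = NULL,
                           nRuns = 10, nPermutations = 300, seed = 1,
                           outlierSigma = 2.5, fdMeanMax = 0.3,
                           badFracMax = 0.15, scrubThresholdMm = 0.5,
                           maxRule = "signed") {
  if (is.null(nStates)) nStates <- simulation@nStates
  new("PipelineConfig", simulation = simulation, nStates = nStates,
      nRuns = nRuns, nPermutations = nPermutations, seed = seed,
      outlierSigma = outlierSigma, fdMeanMax = fdMeanMax,
      badFracMax = badFracMax, scrubThresholdMm = scrubThresholdMm,
      maxRule = maxRule)
}

pipelineStage <- function(name, expr, verbose) {
  if (verbose) message("[", name, "] ...")
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  if (verbose) {
    message(sprintf("[%s] done in %.1f s", name,
                    proc.time()[["elapsed"]] - t0))
  }
  out
}

#' Run the full synthetic-replication pipeline
#'
#' Executes simulate -> exclusion/standardisation -> group HMM fit ->
#' decoding and state metrics -> report decomposition -> dwell-time MANCOVA
#' (experience and well-being) -> gradient projection and permutation null.
#' The returned bundle carries every intermediate object plus a manifest
#' recording the package version and all seeds and thresholds, sufficient to
#' re-run the pipeline bit-identically.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param verbose print per-stage progress (default TRUE).
#' @return named list: cohort, exclusion, groupMatrix, model, sequences,
#'   metrics, dwellZ, reportModel, mancova, wellbeingModel,
#'   wellbeingMancova, projection, null, exceedance, manifest.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(is(config, "PipelineConfig"))
  sim <- config@simulation

  cohort <- pipelineStage("simulate", simulateCohort(sim), verbose)

  excl <- pipelineStage("ingest", {
    applyExclusion(cohort$timeSeries, cohort$motion,
                   fdMeanMax = config@fdMeanMax,
                   badFracMax = config@badFracMax)
  }, verbose)
  group <- pipelineStage("standardise", standardiseConcatenate(excl$retained),
                         verbose)

  model <- pipelineStage("fit", {
    fitGroupHmm(group, nStates = config@nStates, nRuns = config@nRuns,
                seed = config@seed)
  }, verbose)

  seqs <- pipelineStage("decode", decodeStates(model, group), verbose)
  metrics <- computeStateMetrics(lapply(seqs, function(s) s@viterbiPath),
                                 nStates = config@nStates)
  dwellZ <- standardiseDwellTimes(metrics, sigma = config@outlierSigma)

  retained <- group@retainedIds
  demo <- cohort$demographics[match(retained, cohort$demographics$subjectId), ]
  meanFd <- vapply(cohort$motion[match(retained,
    vapply(cohort$motion, function(m) m@subjectId, character(1)))],
    function(m) mean(m@fdMm), numeric(1))

  reportModel <- pipelineStage("decompose", {
    pcaVarimax(cohort$reports$items[retained, , drop = FALSE])
  }, verbose)

  mancova <- pipelineStage("associate", {
    design <- buildDesignMatrix(dwellZ, motion = meanFd, age = demo$age,
                                gender = demo$gender)
    fitMancova(componentScores(reportModel), design,
               componentModel = reportModel)
  }, verbose)

  wbIds <- intersect(rownames(cohort$wellbeing$items), retained)
  wellbeingModel <- NULL
  wellbeingMancova <- NULL
  if (length(wbIds) >= 10) {
    wellbeingModel <- pipelineStage("decompose-wellbeing", {
      pcaVarimax(cohort$wellbeing$items[wbIds, , drop = FALSE])
    }, verbose)
    wellbeingMancova <- pipelineStage("associate-wellbeing", {
      i <- match(wbIds, retained)
      design <- buildDesignMatrix(dwellZ[i, , drop = FALSE],
                                  motion = meanFd[i], age = demo$age[i],
                                  gender = demo$gender[i])
      fitMancova(componentScores(wellbeingModel), design,
                 componentModel = wellbeingModel)
    }, verbose)
  }

  projection <- pipelineStage("project", {
    projectStates(model, cohort$gradientBasis, maxRule = config@maxRule)
  }, verbose)
  null <- pipelineStage("null", {
    permutationNull(model, cohort$gradientBasis,
                    nPermutations = config@nPermutations,
                    seed = config@seed, maxRule = config@maxRule)
  }, verbose)
  exceedance <- exceedanceTest(projection, null)

  manifest <- list(
    package = "neurostates",
    version = as.character(utils::packageVersion("neurostates")),
    simulationSeed = sim@seed, analysisSeed = config@seed,
    nSubjects = sim@nSubjects, nTimepoints = sim@nTimepoints,
    nParcels = sim@nParcels, trSeconds = sim@trSeconds,
    nStates = config@nStates, nRuns = config@nRuns,
    nPermutations = config@nPermutations,
    outlierSigma = config@outlierSigma,
    fdMeanMax = config@fdMeanMax, badFracMax = config@badFracMax,
    scrubThresholdMm = config@scrubThresholdMm,
    maxRule = config@maxRule,
    nRetained = length(retained),
    nExcluded = sum(excl$report$excluded)
  )

  list(cohort = cohort, exclusion = excl, groupMatrix = group, model = model,
       sequences = seqs, metrics = metrics, dwellZ = dwellZ,
       reportModel = reportModel, mancova = mancova,
       wellbeingModel = wellbeingModel, wellbeingMancova = wellbeingMancova,
       projection = projection, null = null, exceedance = exceedance,
       manifest = manifest)
}
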