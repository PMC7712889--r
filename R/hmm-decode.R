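#' @include AllClasses.R hmm-fit.R
NULL

#' Viterbi-decode a subject's state path
#'
#' Maximum-probability state sequence under the fitted model, computed in log
#' space. Ties are broken toward the lowest state index, so the output is
#' deterministic even for exactly symmetric states.
#'
#' @param model a \linkS4class{HmmModel}.
#' @param values timepoints x parcels matrix (standardised, same convention
#'   as the fitting data) or a \linkS4class{ParcelTimeSeries}.
#' @return integer vector of states in 1..K.
#' @export
viterbiDecode <- function(model, values) {
  if (is(values, "ParcelTimeSeries")) values <- values@values
  values <- as.matrix(values)
  if (ncol(values) != ncol(model@means)) {
    stop("parcel count mismatch: model has ", ncol(model@means),
         ", data has ", ncol(values))
  }
  logB <- gaussianLogDensities(values, model@means, model@covariances)
  as.integer(.viterbi_cpp(logB, log(pmax(model@initialProbs, 1e-300)),
                          log(pmax(model@transitionMatrix, 1e-300))))
}

#' Decode state sequences for every subject in a group matrix
#'
#' Runs the forward-backward smoother (posterior state probabilities) and
#' Viterbi decoding per subject under the shared group model.
#'
#' @param model a \linkS4class{HmmModel}.
#' @param group a \linkS4class{GroupMatrix}.
#' @return named list of \linkS4class{StateSequence}, one per subject.
#' @export
decodeStates <- function(model, group) {
  stopifnot(is(group, "GroupMatrix"))
  X <- group@values
  blocks <- split(seq_len(nrow(X)),
                  factor(group@subjectIndex, levels = group@retainedIds))
  logB <- gaussianLogDensities(X, model@means, model@covariances)
  logpi <- log(pmax(model@initialProbs, 1e-300))
  logA <- log(pmax(model@transitionMatrix, 1e-300))
  out <- lapply(names(blocks), function(id) {
    b <- blocks[[id]]
    fb <- .fb_cpp(logB[b, , drop = FALSE], logpi, model@transitionMatrix)
    new("StateSequence", subjectId = id, posteriors = fb$gamma,
        viterbiPath = as.integer(.viterbi_cpp(logB[b, , drop = FALSE],
                                              logpi, logA)))
  })
  names(out) <- names(blocks)
  out
}

# Mean dwell-time per state for one path: mean length (in TRs) of maximal
# runs of each state; NA for states never visited. Truncated runs at the
# start/end of the path count as visits.
meanDwellFromPath <- function(path, K) {
  r <- rle(path)
  out <- rep(NA_real_, K)
  for (s in seq_len(K)) {
    len <- r$lengths[r$values == s]
    if (length(len)) out[s] <- mean(len)
  }
  out
}

#' Compute per-subject state dynamics metrics
#'
#' From hard-classified (Viterbi) paths: mean dwell-time per state (mean
#' length, in TRs, of maximal runs of that state; NA where a subject never
#' visits a state), fractional occupancy (proportion of TRs in the state),
#' and switching rate (state changes per transition opportunity,
#' \code{(number of t with path[t] != path[t+1]) / (T - 1)}).
#'
#' @param paths list of integer state paths (or of
#'   \linkS4class{StateSequence}).
#' @param nStates number of states K.
#' @return a \linkS4class{StateMetrics}.
#' @examples
#' computeStateMetrics(list(s1 = c(1, 1, 2, 2, 2, 1)), nStates = 2)
#' @export
computeStateMetrics <- function(paths, nStates) {
  if (length(paths) == 0) stop("no paths supplied")
  ids <- names(paths)
  paths <- lapply(paths, function(p) {
    if (is(p, "StateSequence")) p@viterbiPath else as.integer(p)
  })
  if (any(vapply(paths, length, integer(1)) == 0)) stop("empty path")
  if (is.null(ids)) ids <- sprintf("sub-%03d", seq_along(paths))
  K <- nStates
  dwell <- t(vapply(paths, meanDwellFromPath, numeric(K), K = K))
  occ <- t(vapply(paths, function(p) tabulate(p, K) / length(p), numeric(K)))
  sw <- vapply(paths, function(p) {
    if (length(p) < 2) 0 else mean(p[-1] != p[-length(p)])
  }, numeric(1))
  rownames(dwell) <- rownames(occ) <- ids
  new("StateMetrics", meanDwellTime = dwell, fractionalOccupancy = occ,
      switchingRate = unname(sw), subjectIds = ids)
}

#' Standardise dwell-times with outlier substitution
#'
#' Per state, dwell-times are z-scored across subjects and any value beyond
#' \code{sigma} standard deviations is substituted with the mean (0), the
#' outlier rule applied before the dwell-times enter the regressions.
#' Never-visited states (NA dwell-time) are mean-imputed first, which lands
#' them at 0 after standardisation — the same substitution the outlier rule
#' applies.
#'
#' @param metrics a \linkS4class{StateMetrics} or subjects x K matrix.
#' @param sigma outlier threshold in standard deviations (default 2.5).
#' @return subjects x K matrix of standardised dwell-times (columns mean
#'   approximately 0).
#' @export
standardiseDwellTimes <- function(metrics, sigma = 2.5) {
  dt <- if (is(metrics, "StateMetrics")) metrics@meanDwellTime else as.matrix(metrics)
  if (nrow(dt) < 3) stop("need at least 3 subjects to standardise")
  out <- dt
  for (s in seq_len(ncol(dt))) {
    col <- dt[, s]
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    if (popSd(col) == 0) stop("zero variance across subjects for state ", s)
    z <- zscorePop(col)
    z[abs(z) > sigma] <- 0
    out[, s] <- z
  }
  out
}

# Maximum-sum one-to-one assignment by dynamic programming over column
# subsets (O(K^2 2^K)); exact, no LP solver needed for the K <= ~15 used here.
solveAssignment <- function(score) {
  K <- nrow(score)
  nMask <- bitwShiftL(1L, K)
  dp <- rep(-Inf, nMask)
  parent <- integer(nMask)
  dp[1] <- 0
  popcount <- vapply(0:(nMask - 1), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(K - 1))) > 0), integer(1))
  for (mask in 0:(nMask - 2)) {
    if (!is.finite(dp[mask + 1])) next
    i <- popcount[mask + 1] + 1L  # next row to assign
    for (j in seq_len(K)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0) {
        nm <- bitwOr(mask, bit)
        v <- dp[mask + 1] + score[i, j]
        if (v > dp[nm + 1]) { dp[nm + 1] <- v; parent[nm + 1] <- j }
      }
    }
  }
  perm <- integer(K)
  mask <- nMask - 1L
  for (i in K:1) {
    j <- parent[mask + 1]
    perm[i] <- j
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  perm
}

#' Match states between two models by their mean maps
#'
#' Optimal one-to-one assignment maximising the summed Pearson correlation
#' between state mean-activity maps, used to align restarts or split halves
#' before comparing solutions.
#'
#' @param a,b \linkS4class{HmmModel}s (or K x P mean matrices) with equal K
#'   and parcel count.
#' @return list with \code{permutation} (state i of \code{a} matches state
#'   \code{permutation[i]} of \code{b}) and \code{correlations} (per matched
#'   pair).
#' @export
matchStates <- function(a, b) {
  A <- if (is(a, "HmmModel")) a@means else as.matrix(a)
  B <- if (is(b, "HmmModel")) b@means else as.matrix(b)
  if (nrow(A) != nrow(B) || ncol(A) != ncol(B)) {
    stop("state count or parcel count mismatch")
  }
  C <- cor(t(A), t(B))
  perm <- solveAssignment(C)
  list(permutation = perm,
       correlations = C[cbind(seq_len(nrow(A)), perm)])
}
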