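#' @include AllClasses.R utils.R
NULL

fisherZ <- function(r, clip = 1 - 1e-7) atanh(pmin(pmax(r, -clip), clip))

# K x 3 raw correlations between state mean maps (rows) and gradient columns.
stateGradientCor <- function(stateMeans, basis) {
  M <- as.matrix(stateMeans)
  G <- as.matrix(basis)
  if (ncol(M) != nrow(G)) {
    stop("parcel count mismatch: states have ", ncol(M),
         ", basis has ", nrow(G))
  }
  sds <- apply(M, 1, popSd)
  if (any(sds == 0)) {
    stop("zero-variance state map: state ",
         paste(which(sds == 0), collapse = ", "))
  }
  cor(t(M), G)
}

#' Project state mean maps into gradient space
#'
#' Each state's coordinate on a gradient is the Fisher-z transformed Pearson
#' correlation between the state's mean-activity map and that gradient map,
#' with correlations clipped to |r| <= 1 - 1e-7 so degenerate (perfectly
#' correlated) inputs stay finite.
#'
#' @param stateMeans K x P matrix of state mean maps, or a
#'   \linkS4class{HmmModel}.
#' @param basis parcels x 3 gradient matrix (columns G1, G2, G3).
#' @param maxRule "signed" (default; the equation's literal maximum) or
#'   "absolute" maximum used in the distance weighting.
#' @return a \linkS4class{StateProjection}.
#' @examples
#' basis <- simulateGradientBasis(10, seed = 2)
#' projectStates(matrix(rnorm(30), 3, 10), basis)
#' @export
projectStates <- function(stateMeans, basis, maxRule = c("signed", "absolute")) {
  maxRule <- match.arg(maxRule)
  if (is(stateMeans, "HmmModel")) stateMeans <- stateMeans@means
  if (ncol(as.matrix(basis)) != 3) stop("basis must have 3 gradient columns")
  if (nrow(as.matrix(basis)) < 3) stop("need at least 3 parcels")
  r <- stateGradientCor(stateMeans, basis)
  z <- fisherZ(r)
  dimnames(z) <- list(sprintf("state%d", seq_len(nrow(z))), c("G1", "G2", "G3"))
  new("StateProjection", rawCorrelations = r, coordinates = z,
      weightedDistanceSum = weightedDistanceSum(z, maxRule = maxRule),
      maxRule = maxRule)
}

#' Weighted distance sum over a set of states
#'
#' Set-level statistic of how far a set of states sits from the origin of
#' gradient space: each state's Euclidean distance from the origin is
#' weighted by its maximum coordinate, and the weighted distances are summed
#' over states,
#' \deqn{\sum_i \sqrt{S_{iG1}^2 + S_{iG2}^2 + S_{iG3}^2} \cdot
#'   \max(S_{iG1}, S_{iG2}, S_{iG3}).}
#' The weight differentiates points lying on the surface of the same sphere.
#' The literal (signed) maximum is the default; \code{maxRule = "absolute"}
#' weights by the largest absolute coordinate instead.
#'
#' @param coords K x 3 matrix of Fisher-z coordinates, or a
#'   \linkS4class{StateProjection}.
#' @param maxRule "signed" or "absolute".
#' @return the weighted distance sum (a single number).
#' @examples
#' weightedDistanceSum(rbind(c(0.3, 0.4, 0)))  # 0.5 * 0.4 = 0.2
#' @export
weightedDistanceSum <- function(coords, maxRule = c("signed", "absolute")) {
  maxRule <- match.arg(maxRule)
  if (is(coords, "StateProjection")) coords <- coords@coordinates
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  d <- sqrt(rowSums(coords^2))
  w <- if (maxRule == "signed") {
    apply(coords, 1, max)
  } else {
    apply(abs(coords), 1, max)
  }
  sum(d * w)
}

#' Permutation null for the gradient-space projection
#'
#' Per permutation, the parcel weights of each state map are independently
#' shuffled (each state's weight multiset is conserved), the synthetic set is
#' projected into gradient space and its weighted distance sum recorded.
#' With K states, \code{nPermutations} permutations produce
#' \code{nPermutations * K} synthetic states; the per-axis central 95%
#' interval of their coordinates is also returned.
#'
#' @param stateMeans K x P matrix or \linkS4class{HmmModel}.
#' @param basis parcels x 3 gradient matrix.
#' @param nPermutations number of permutations (default 300).
#' @param seed seed for the permutation stream.
#' @param maxRule passed to [weightedDistanceSum()].
#' @return a \linkS4class{NullSummary}.
#' @export
permutationNull <- function(stateMeans, basis, nPermutations = 300, seed = 1,
                            maxRule = c("signed", "absolute")) {
  maxRule <- match.arg(maxRule)
  if (is(stateMeans, "HmmModel")) stateMeans <- stateMeans@means
  stopifnot(nPermutations >= 1)
  M <- as.matrix(stateMeans)
  K <- nrow(M)
  P <- ncol(M)
  if (any(apply(M, 1, popSd) == 0)) {
    stop("constant state map is permutation-invariant (zero variance)")
  }
  set.seed(seed)
  coords <- matrix(NA_real_, nPermutations * K, 3)
  sums <- numeric(nPermutations)
  for (b in seq_len(nPermutations)) {
    Mp <- t(apply(M, 1, function(w) w[sample.int(P)]))
    z <- fisherZ(stateGradientCor(Mp, basis))
    coords[(b - 1) * K + seq_len(K), ] <- z
    sums[b] <- weightedDistanceSum(z, maxRule = maxRule)
  }
  colnames(coords) <- c("G1", "G2", "G3")
  band <- t(apply(coords, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
  dimnames(band) <- list(c("G1", "G2", "G3"), c("lower", "upper"))
  new("NullSummary", nPermutations = nPermutations, nStates = K,
      syntheticCoords = coords, nullSums = sums, band95 = band, seed = seed)
}

#' Exceedance test of the observed weighted distance sum
#'
#' One-sided add-one permutation p-value,
#' \code{p = (1 + #(null >= observed)) / (nPermutations + 1)} (never exactly
#' zero), with the verdict \code{"exceeds-all"} when the observed sum is
#' larger than every null sum.
#'
#' @param observed observed weighted distance sum (or a
#'   \linkS4class{StateProjection}).
#' @param null a \linkS4class{NullSummary}.
#' @return list with \code{pValue} and \code{verdict} ("exceeds-all" or
#'   "within-null").
#' @export
exceedanceTest <- function(observed, null) {
  if (is(observed, "StateProjection")) observed <- observed@weightedDistanceSum
  stopifnot(is(null, "NullSummary"), length(null@nullSums) >= 1)
  p <- (1 + sum(null@nullSums >= observed)) / (null@nPermutations + 1)
  list(pValue = p,
       verdict = if (observed > max(null@nullSums)) "exceeds-all" else "within-null")
}
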