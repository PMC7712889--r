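#' @include AllClasses.R utils.R
NULL

#' Correlation-matrix PCA with varimax rotation and Kaiser retention
#'
#' Eigendecomposes the item correlation matrix (items standardised, since
#' Likert items share no natural scale), retains components with eigenvalue
#' strictly greater than 1 (Kaiser criterion), varimax-rotates the retained
#' loadings (Kaiser row-normalisation, convergence 1e-8) and computes
#' component scores by least-squares projection of the standardised items.
#' Each rotated component is sign-flipped so its largest-magnitude loading
#' is positive.
#'
#' @param reports subjects x items numeric matrix (e.g. 1-4 Likert scores).
#' @param itemLabels optional item names; defaults to column names.
#' @return a \linkS4class{ComponentModel}.
#' @examples
#' set.seed(1)
#' block <- matrix(rnorm(60), 60, 1)[, rep(1, 3)] + matrix(rnorm(180, sd = .2), 60, 3)
#' pcaVarimax(cbind(block, matrix(rnorm(180), 60, 3)))
#' @export
pcaVarimax <- function(reports, itemLabels = colnames(reports)) {
  X <- as.matrix(reports)
  if (nrow(X) < 3) stop("need at least 3 subjects")
  if (is.null(itemLabels)) itemLabels <- sprintf("item_%02d", seq_len(ncol(X)))
  sds <- apply(X, 2, popSd)
  if (any(sds == 0)) {
    stop("constant item(s): ", paste(itemLabels[sds == 0], collapse = ", "))
  }
  Z <- scale(X, center = TRUE, scale = apply(X, 2, sd))
  R <- cor(X)
  e <- eigen(R, symmetric = TRUE)
  eigenvalues <- e$values
  # strict Kaiser criterion; the 1e-8 guard keeps eigenvalues that equal 1
  # up to floating-point rounding (identity correlation) out of retention
  k <- sum(eigenvalues > 1 + 1e-8)
  if (k == 0) {
    stop("no component has eigenvalue > 1; nothing to retain")
  }
  # unrotated loadings: eigenvectors scaled by sqrt(eigenvalue)
  L <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eigenvalues[seq_len(k)]), k)
  if (k > 1) {
    rot <- varimax(L, normalize = TRUE, eps = 1e-8)
    L <- L %*% rot$rotmat
  }
  # sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(k)) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  scores <- Z %*% L %*% solve(crossprod(L))
  dimnames(L) <- list(itemLabels, sprintf("C%d", seq_len(k)))
  colnames(scores) <- colnames(L)
  rownames(scores) <- rownames(X)
  new("ComponentModel", loadings = L, scores = scores,
      eigenvalues = eigenvalues, k = k,
      varianceExplained = colSums(L^2) / ncol(X),
      itemLabels = itemLabels)
}

#' Map component-space regression coefficients back to item space
#'
#' Item-space betas are the component-space betas pushed through the
#' transpose of the rotated loading matrix, giving, per predictor, an
#' item-level map interpretable as the pattern of answers the predictor is
#' associated with.
#'
#' @param betas predictors x k matrix of component-space coefficients.
#' @param model a \linkS4class{ComponentModel} (or items x k loading matrix).
#' @return predictors x items matrix.
#' @export
backProjectBetas <- function(betas, model) {
  L <- if (is(model, "ComponentModel")) model@loadings else as.matrix(model)
  betas <- as.matrix(betas)
  if (ncol(betas) != ncol(L)) {
    stop("component count mismatch: betas have ", ncol(betas),
         ", loadings have ", ncol(L))
  }
  out <- betas %*% t(L)
  colnames(out) <- rownames(L)
  out
}
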