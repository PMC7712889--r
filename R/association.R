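#' @include AllClasses.R behaviour.R
NULL

#' Assemble the MANCOVA design matrix
#'
#' Columns: intercept, the K standardised dwell-times (one per state), then
#' any covariates of no interest. Motion (mean FD) and age are z-scored;
#' gender enters as a single binary column.
#'
#' @param dwellZ subjects x K matrix of standardised dwell-times (see
#'   [standardiseDwellTimes()]).
#' @param motion optional per-subject mean framewise displacement.
#' @param age optional per-subject age.
#' @param gender optional binary coding (0/1).
#' @return subjects x (1 + K + covariates) numeric matrix.
#' @export
buildDesignMatrix <- function(dwellZ, motion = NULL, age = NULL, gender = NULL) {
  dwellZ <- as.matrix(dwellZ)
  n <- nrow(dwellZ)
  X <- cbind("(Intercept)" = rep(1, n), dwellZ)
  colnames(X)[1 + seq_len(ncol(dwellZ))] <- sprintf("state%d", seq_len(ncol(dwellZ)))
  addCov <- function(X, v, name, standardise = TRUE) {
    if (is.null(v)) return(X)
    stopifnot(length(v) == n)
    if (standardise) v <- as.numeric(scale(v))
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- name
    X
  }
  X <- addCov(X, motion, "motion")
  X <- addCov(X, age, "age")
  X <- addCov(X, gender, "gender", standardise = FALSE)
  X
}

#' Multivariate multiple regression with per-predictor Wilks' Lambda tests
#'
#' Fits an ordinary least-squares multivariate regression of the outcome
#' block (component scores) on the full design, then tests each requested
#' predictor as a single-df multivariate contrast with all other columns
#' retained: Wilks' Lambda = det(E) / det(E + H), with E the residual SSCP
#' and H the hypothesis SSCP of that coefficient row. For a single-df
#' hypothesis the F transform is exact:
#' F = ((1 - Lambda) / Lambda) * (df2 / df1) with df1 = p (number of
#' outcomes) and df2 = n - rank(X) - p + 1, and partial eta squared equals
#' 1 - Lambda. No multiplicity correction is applied across the tested
#' predictors; \code{nTests} records how many were run.
#'
#' @param outcomes subjects x p matrix of outcome variables.
#' @param design subjects x q design matrix including the intercept (see
#'   [buildDesignMatrix()]).
#' @param testColumns columns of \code{design} to test; default every column
#'   whose name starts with "state", or all non-intercept columns if none
#'   match.
#' @param componentModel optional \linkS4class{ComponentModel}; when given,
#'   the tested predictors' betas are back-projected to item space.
#' @return a \linkS4class{MancovaResult}.
#' @examples
#' set.seed(1)
#' X <- buildDesignMatrix(matrix(rnorm(200), 50, 4))
#' Y <- matrix(rnorm(150), 50, 3)
#' mancovaTable(fitMancova(Y, X))
#' @export
fitMancova <- function(outcomes, design, testColumns = NULL,
                       componentModel = NULL) {
  Y <- as.matrix(outcomes)
  X <- as.matrix(design)
  n <- nrow(Y)
  p <- ncol(Y)
  q <- ncol(X)
  if (nrow(X) != n) stop("outcomes and design must be row-aligned")
  if (qr(X)$rank < q) stop("design matrix is rank deficient")
  if (n <= q + p) {
    stop("need n > rank(design) + p; have n = ", n, ", require n > ", q + p)
  }
  if (is.null(testColumns)) {
    testColumns <- grep("^state", colnames(X))
    if (!length(testColumns)) testColumns <- setdiff(seq_len(q), 1)
  }
  if (is.character(testColumns)) testColumns <- match(testColumns, colnames(X))

  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)
  rownames(B) <- colnames(X)
  E <- crossprod(Y - X %*% B)
  detE <- det(E)
  df1 <- p
  df2 <- n - q - p + 1

  rows <- lapply(testColumns, function(j) {
    H <- tcrossprod(B[j, ]) / XtXinv[j, j]
    lambda <- detE / det(E + H)
    f <- ((1 - lambda) / lambda) * (df2 / df1)
    data.frame(predictor = colnames(X)[j], wilksLambda = lambda, fStat = f,
               df1 = df1, df2 = df2,
               pValue = pf(f, df1, df2, lower.tail = FALSE),
               partialEtaSq = 1 - lambda, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)

  itemBetas <- NULL
  if (!is.null(componentModel)) {
    itemBetas <- backProjectBetas(B[testColumns, , drop = FALSE], componentModel)
    rownames(itemBetas) <- colnames(X)[testColumns]
  }
  new("MancovaResult", table = tab, betas = B, itemBetas = itemBetas,
      nTests = length(testColumns))
}
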