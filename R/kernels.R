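#' Radial basis function kernel
#'
#' K_ij = exp(-sigma * ||x_i - x_j||^2); the diagonal is exactly 1.
#'
#' @param X numeric matrix (samples x features).
#' @param sigma positive scaling parameter.
#' @param Y optional second matrix; when given the (nrow(Y) x nrow(X))
#'   cross-kernel block K(y_i, x_j) is returned.
#' @return kernel matrix.
#' @export
rbfKernel <- function(X, sigma, Y = NULL) {
  if (sigma <= 0) stop("sigma must be positive")
  if (is.null(Y)) {
    sq <- rowSums(X^2)
    D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(X)
    D2[D2 < 0] <- 0
    K <- exp(-sigma * D2)
    diag(K) <- 1
  } else {
    D2 <- outer(rowSums(Y^2), rowSums(X^2), `+`) - 2 * tcrossprod(Y, X)
    D2[D2 < 0] <- 0
    K <- exp(-sigma * D2)
  }
  K
}

#' Linear kernel K_ij = <x_i, x_j>
#'
#' @inheritParams rbfKernel
#' @return kernel matrix (or cross-kernel block when \code{Y} is given).
#' @export
linearKernel <- function(X, Y = NULL) {
  if (is.null(Y)) tcrossprod(X) else tcrossprod(Y, X)
}

#' Median-distance heuristic grid for the RBF scaling parameter
#'
#' Centers the grid at 1 / median(||x_i - x_j||^2) and spans powers of two
#' around it.
#'
#' @param X numeric matrix (samples x features).
#' @param powers exponents of 2 to span (default -4..4).
#' @return numeric grid of candidate sigmas.
#' @export
sigmaGrid <- function(X, powers = -4:4) {
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(X)
  med <- median(D2[upper.tri(D2)])
  if (!is.finite(med) || med <= 0) med <- 1
  (1 / med) * 2^powers
}

#' Median-heuristic single sigma
#'
#' @param X numeric matrix.
#' @return 1 / median squared pairwise distance.
#' @export
sigmaHeuristic <- function(X) sigmaGrid(X, powers = 0)

#' Tune the RBF sigma by k-fold cross-validation
#'
#' Maximizes mean CV accuracy of a single-kernel soft-margin SVM over the
#' grid; ties break toward the smaller sigma.
#'
#' @param X training feature matrix.
#' @param y training labels in \{-1, +1\}.
#' @param grid candidate sigmas (default \code{\link{sigmaGrid}(X)}).
#' @param k folds (default 5).
#' @param C box constraint of the CV classifier.
#' @param seed RNG seed for fold assignment.
#' @return the selected sigma.
#' @export
tuneSigma <- function(X, y, grid = NULL, k = 5L, C = 1, seed = 1L) {
  if (is.null(grid)) grid <- sigmaGrid(X)
  grid <- sort(grid)
  set.seed(seed)
  folds <- stratifiedFolds(y, k)
  acc <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    correct <- 0L; total <- 0L
    for (fold in seq_len(k)) {
      hold <- which(folds == fold)
      tr <- which(folds != fold)
      if (length(unique(y[tr])) < 2L) next
      Ktr <- rbfKernel(X[tr, , drop = FALSE], grid[gi])
      model <- fitSdpSvm(list(Ktr), y[tr], C = C)
      Kte <- rbfKernel(X[tr, , drop = FALSE], grid[gi],
                       Y = X[hold, , drop = FALSE])
      pred <- predictSdpSvm(model, list(Kte))
      correct <- correct + sum(predictedLabels(pred) == y[hold])
      total <- total + length(hold)
    }
    acc[gi] <- if (total) correct / total else 0
  }
  grid[which.max(acc)]
}
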