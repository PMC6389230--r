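#' Sample-similarity weight matrix from feature-profile correlation
#'
#' W_ij = max(cor(x_i., x_j.), 0) for i != j, i.e. the pairwise correlation
#' between the feature profiles of samples i and j with negative entries
#' zeroed (edge weights must be non-negative) and the diagonal forced to 0
#' (a self-correlation of 1 would otherwise dominate the node degrees).
#'
#' @param X numeric matrix (samples x features), at least 2 features.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return symmetric non-negative weight matrix with zero diagonal and the
#'   sample IDs as dimnames.
#' @export
correlationWeights <- function(X, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (ncol(X) < 2L) stop("need at least 2 features per sample")
  zeroVar <- apply(X, 1L, function(r) var(r) < .Machine$double.eps)
  W <- suppressWarnings(cor(t(X), method = method))
  if (any(zeroVar)) {
    warning(sum(zeroVar), " sample(s) with zero-variance profiles; ",
            "their correlations set to 0")
    W[zeroVar, ] <- 0
    W[, zeroVar] <- 0
  }
  W[is.na(W)] <- 0
  W[W < 0] <- 0
  diag(W) <- 0
  W <- (W + t(W)) / 2  # guard against asymmetric rounding
  dimnames(W) <- list(rownames(X), rownames(X))
  W
}

#' Graph Laplacian L = D - W
#'
#' D = diag(d_i) with d_i the row sums of W. For symmetric W the Laplacian
#' is positive semidefinite and its quadratic form f'Lf equals
#' sum_{i<j} w_ij (f_i - f_j)^2, the smoothness penalty of label
#' propagation.
#'
#' @param W non-negative weight matrix (symmetric or sharpened/directed).
#' @return the Laplacian matrix, same dimnames as \code{W}.
#' @export
laplacianMatrix <- function(W) {
  if (any(W < 0)) stop("weight matrix must be non-negative")
  diag(rowSums(W)) - W
}
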