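#' Label-derived target network
#'
#' T_ij depends only on the pair's labels and the class proportions:
#' (n+/n)^2 for negative-negative pairs, (n-/n)^2 for positive-positive
#' pairs, and n+ n- / n^2 for mixed pairs (the published convention, under
#' which the mixed-pair target is positive). \code{mixedSign = "negative"}
#' switches to the original association-network convention
#' -n+ n- / n^2 for mixed pairs.
#'
#' @param y label vector over the training nodes, values in \{-1, +1\},
#'   both classes present.
#' @param mixedSign \code{"paper"} (positive mixed target, default) or
#'   \code{"negative"}.
#' @return symmetric matrix with at most three distinct values.
#' @export
targetNetwork <- function(y, mixedSign = c("paper", "negative")) {
  mixedSign <- match.arg(mixedSign)
  if (!all(y %in% c(-1, 1))) stop("target network requires labels in {-1,+1}")
  nPos <- sum(y == 1); nNeg <- sum(y == -1); n <- length(y)
  if (nPos == 0L || nNeg == 0L) stop("both classes must be present")
  mixed <- nPos * nNeg / n^2
  if (mixedSign == "negative") mixed <- -mixed
  T <- matrix(mixed, n, n)
  negneg <- outer(y == -1, y == -1, `&`)
  pospos <- outer(y == 1, y == 1, `&`)
  T[negneg] <- (nPos / n)^2
  T[pospos] <- (nNeg / n)^2
  T
}

#' Least-squares composite network weights
#'
#' Fits alpha in min_alpha || Omega alpha - vec(T) ||^2 with
#' Omega = [1, vec(W_1), ..., vec(W_m)] (bias column of ones; vec stacks
#' the full matrix, both triangles and diagonal) via the normal equations.
#' Negative fitted source weights are set to zero; when all fitted weights
#' are non-positive the uniform fallback alpha_i = 1/m overwrites them. The
#' bias alpha_0 is reported but discarded when combining networks.
#'
#' @param Ws list of weight matrices restricted to the training nodes.
#' @param T target network from \code{\link{targetNetwork}} (or any
#'   conformable symmetric matrix).
#' @param ridge ridge guard added to Omega'Omega when it is numerically
#'   singular (collinear or constant sources).
#' @return a \code{CompositeNetworkModel} with empty score slots (weights
#'   only); see \code{\link{fitCompositeNetwork}} for the full classifier.
#' @export
compositeWeights <- function(Ws, T, ridge = 1e-8) {
  m <- length(Ws)
  stopifnot(m >= 1L)
  Omega <- cbind(1, vapply(Ws, as.numeric, numeric(length(T))))
  tT <- as.numeric(T)
  G <- crossprod(Omega)
  rhs <- crossprod(Omega, tT)
  sol <- tryCatch(solve(G, rhs), error = function(e) NULL)
  if (is.null(sol) || rcond(G) < 1e-12) {
    warning("near-singular normal equations; applying ridge guard")
    sol <- solve(G + diag(ridge, ncol(G)), rhs)
  }
  alpha0 <- sol[1L]
  alpha <- sol[-1L]
  fallback <- all(alpha <= 0)
  if (fallback) alpha <- rep(1 / m, m) else alpha[alpha < 0] <- 0
  new("CompositeNetworkModel", alphas = as.numeric(alpha),
      alpha0 = as.numeric(alpha0), fallbackUsed = fallback,
      f = numeric(), trainIdx = integer())
}

#' Composite association network classifier
#'
#' Regresses the per-source training-node weight matrices onto the
#' label-derived target network, combines the full weight matrices with the
#' fitted non-negative weights, and runs single-network label propagation
#' with c = 1 on the composite graph; classification is by median cut-off.
#' The regression sees training nodes only (the target is undefined for
#' unlabelled nodes); the learned weights are then applied to the full
#' matrices, so no test label is ever read.
#'
#' @param Ws list of full (train + test) weight matrices.
#' @param y label vector over all nodes (0 = unlabelled/test).
#' @param c propagation trade-off, fixed at 1 for this method.
#' @param mixedSign passed to \code{\link{targetNetwork}}.
#' @return a \code{CompositeNetworkModel} with function scores in slot
#'   \code{f}.
#' @export
fitCompositeNetwork <- function(Ws, y, c = 1, mixedSign = "paper") {
  trainIdx <- which(y != 0)
  Wtr <- lapply(Ws, function(W) W[trainIdx, trainIdx, drop = FALSE])
  T <- targetNetwork(y[trainIdx], mixedSign)
  model <- compositeWeights(Wtr, T)
  Wbar <- Reduce(`+`, Map(`*`, Ws, model@alphas))
  f <- gsslSolveSingle(laplacianMatrix(Wbar), y, c)@f
  model@f <- f
  model@trainIdx <- as.integer(trainIdx)
  model
}
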