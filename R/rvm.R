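sigmoid <- function(x) 1 / (1 + exp(-x))

#' Relevance vector machine for binary classification
#'
#' Sparse Bayesian learning over the kernel expansion
#' Y(x; w) = sum_i w_i k(x, x_i): each weight carries an independent
#' Gaussian prior with precision a_i; the precisions are updated by type-II
#' maximum likelihood with a Laplace approximation of the logistic
#' likelihood (targets t = (y+1)/2), and weights whose precision exceeds
#' the pruning threshold are removed. The surviving training samples are
#' the relevance vectors.
#'
#' @param K training kernel matrix (n x n).
#' @param y labels in \{-1, +1\}, both classes present.
#' @param maxIter outer precision updates (default 500).
#' @param tol convergence on max |delta log precision| (default 1e-3).
#' @param pruneThreshold precisions above this are pruned (default 1e9).
#' @return an \code{RVMModel}.
#' @export
rvmFit <- function(K, y, maxIter = 500L, tol = 1e-3,
                   pruneThreshold = 1e9) {
  stopifnot(any(y == 1), any(y == -1), nrow(K) == length(y))
  n <- length(y)
  t <- (y + 1) / 2
  active <- seq_len(n)
  a <- rep(1e-2, n)
  w <- rep(0, n)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    Phi <- K[, active, drop = FALSE]
    A <- a[active]
    # Laplace: Newton/IRLS for the posterior mode of the active weights
    wa <- w[active]
    for (nw in 1:50) {
      eta <- as.numeric(Phi %*% wa)
      p <- sigmoid(eta)
      g <- crossprod(Phi, t - p) - A * wa
      if (max(abs(g)) < 1e-6) break
      B <- pmax(p * (1 - p), 1e-10)
      H <- crossprod(Phi, Phi * B) + diag(A, length(A))
      delta <- tryCatch(solve(H, g), error = function(e)
        solve(H + diag(1e-8, nrow(H)), g))
      objOld <- sum(t * eta - log1p(exp(eta))) - 0.5 * sum(A * wa^2)
      stepSize <- 1
      repeat {
        cand <- wa + stepSize * as.numeric(delta)
        etaC <- as.numeric(Phi %*% cand)
        objNew <- sum(t * etaC - log1p(exp(etaC))) - 0.5 * sum(A * cand^2)
        if (objNew >= objOld || stepSize < 1e-8) break
        stepSize <- stepSize / 2
      }
      wa <- cand
    }
    eta <- as.numeric(Phi %*% wa)
    p <- sigmoid(eta)
    B <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Phi, Phi * B) + diag(A, length(A))
    Sigma <- tryCatch(solve(H), error = function(e)
      solve(H + diag(1e-8, nrow(H))))
    gamma <- 1 - A * diag(Sigma)
    aNew <- pmin(pmax(gamma / pmax(wa^2, 1e-300), 1e-12), 1e12)
    change <- max(abs(log(aNew) - log(A)))
    w[active] <- wa
    a[active] <- aNew
    keep <- aNew < pruneThreshold
    if (!any(keep)) keep[which.min(aNew)] <- TRUE  # never prune everything
    active <- active[keep]
    w[setdiff(seq_len(n), active)] <- 0
    if (change < tol) { converged <- TRUE; break }
  }
  new("RVMModel", relevanceIdx = as.integer(active),
      weights = as.numeric(w[active]), iterations = iter,
      converged = converged)
}

#' RVM class probabilities
#'
#' P(y = 1 | x) = 1 / (1 + exp(-Y(x; w))) with Y the kernel expansion over
#' the relevance vectors.
#'
#' @param model an \code{RVMModel}.
#' @param Ktest (n_test x n_train) cross-kernel block against the full
#'   training set the model was fitted on.
#' @return numeric probabilities in (0, 1).
#' @export
rvmPredictProb <- function(model, Ktest) {
  sigmoid(as.numeric(Ktest[, model@relevanceIdx, drop = FALSE] %*%
                       model@weights))
}

#' Average per-source probabilities and classify at 0.5
#'
#' Pbar = (P_1 + ... + P_k)/k; a sample is classified +1 when its mean
#' probability exceeds 0.5, otherwise -1 (exactly 0.5 goes to -1).
#'
#' @param Ps list of equal-length probability vectors (one per source).
#' @param sampleIds optional sample IDs.
#' @return a \code{PredictionResult} with \code{scoreKind}
#'   \code{"probability"}.
#' @export
integrateProbabilities <- function(Ps, sampleIds = character()) {
  stopifnot(length(Ps) >= 1L)
  lens <- lengths(Ps)
  stopifnot(all(lens == lens[1L]))
  pbar <- Reduce(`+`, Ps) / length(Ps)
  PredictionResult(ifelse(pbar > 0.5, 1, -1), pbar, "probability",
                   sampleIds)
}
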