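# learner weight from a weighted error < 0.5
boostAlpha <- function(eps) 0.5 * log((1 - eps) / eps)

# multiplicative sample-weight update, then renormalization to sum 1
boostUpdateWeights <- function(wts, mis, alphaT) {
  wts <- wts * ifelse(mis, exp(alphaT), exp(-alphaT))
  wts / sum(wts)
}

#' Ada-boost ensemble of relevance vector machines
#'
#' Sample weights start uniform at 1/N. Each iteration draws a subsample
#' without replacement, fits an RVM on it, and computes the weighted
#' misclassification error eps_t = sum of the weights of the misclassified
#' samples over the FULL training set. Iterations with eps_t >= 0.5 are
#' skipped (weights unchanged); otherwise the learner is stored with
#' alpha_t = 0.5 ln((1 - eps_t)/eps_t), sample weights are multiplied by
#' exp(alpha_t) (misclassified) or exp(-alpha_t) (correct) and renormalized
#' to sum to one. The final model is sum_j alpha_j RVM_j over the stored
#' learners. If every iteration is skipped a single RVM on the full
#' training set is used as fallback.
#'
#' @param K training kernel matrix (N x N).
#' @param y training labels in \{-1, +1\}.
#' @param resampleFraction subsample size as a fraction of N (default 0.4).
#' @param maxIter boosting iterations (default 10).
#' @param seed RNG seed for the subsampling.
#' @return a \code{BoostedRVMModel}.
#' @export
adaboostRvm <- function(K, y, resampleFraction = 0.4, maxIter = 10L,
                        seed = 1L) {
  stopifnot(resampleFraction > 0, resampleFraction <= 1, maxIter >= 1L)
  N <- length(y)
  nSub <- max(4L, round(resampleFraction * N))
  set.seed(seed)
  wts <- rep(1 / N, N)
  learners <- list(); alphas <- numeric(); learnerIdx <- list()
  skipped <- 0L
  for (t in seq_len(maxIter)) {
    sub <- sample(N, nSub)
    tries <- 0L
    while (length(unique(y[sub])) < 2L && tries < 50L) {
      sub <- sample(N, nSub); tries <- tries + 1L
    }
    learner <- rvmFit(K[sub, sub, drop = FALSE], y[sub])
    score <- as.numeric(K[, sub[learner@relevanceIdx], drop = FALSE] %*%
                          learner@weights)
    pred <- ifelse(score > 0, 1, -1)
    mis <- pred != y
    eps <- sum(wts[mis])
    if (eps >= 0.5) { skipped <- skipped + 1L; next }
    eps <- max(eps, 1e-12)          # a perfect learner gets a capped alpha
    alphaT <- boostAlpha(eps)
    learners[[length(learners) + 1L]] <- learner
    learnerIdx[[length(learnerIdx) + 1L]] <- sub
    alphas <- c(alphas, alphaT)
    wts <- boostUpdateWeights(wts, mis, alphaT)
  }
  fallback <- length(learners) == 0L
  if (fallback) {
    warning("all boosting iterations skipped; falling back to a single RVM")
    learners <- list(rvmFit(K, y))
    learnerIdx <- list(seq_len(N))
    alphas <- 1
  }
  new("BoostedRVMModel", learners = learners, alphas = alphas,
      learnerIdx = learnerIdx, skipped = skipped, fallback = fallback)
}

#' Ensemble score of a boosted RVM
#'
#' Weighted vote sum_j alpha_j h_j(x) of the stored learners' hard labels.
#'
#' @param model a \code{BoostedRVMModel}.
#' @param Ktest (n_test x N) cross-kernel block against the full training
#'   set used for boosting.
#' @return numeric ensemble scores.
#' @export
boostedScore <- function(model, Ktest) {
  out <- rep(0, nrow(Ktest))
  for (j in seq_along(model@learners)) {
    learner <- model@learners[[j]]
    idx <- model@learnerIdx[[j]][learner@relevanceIdx]
    s <- as.numeric(Ktest[, idx, drop = FALSE] %*% learner@weights)
    out <- out + model@alphas[j] * ifelse(s > 0, 1, -1)
  }
  out
}

#' Classify with a boosted RVM
#'
#' Label is the sign of the ensemble score (zero goes to -1); the reported
#' probability is the ensemble score mapped through the logistic sigmoid.
#'
#' @inheritParams boostedScore
#' @param sampleIds optional test-sample IDs.
#' @return a \code{PredictionResult} with \code{scoreKind}
#'   \code{"probability"}.
#' @export
predictBoostedRvm <- function(model, Ktest, sampleIds = character()) {
  s <- boostedScore(model, Ktest)
  PredictionResult(ifelse(s > 0, 1, -1), sigmoid(s), "probability",
                   sampleIds)
}

#' Tune boosting resample fraction and iteration count by 5-fold CV
#'
#' Grid search over resampling size \{0.2, 0.4, 0.6, 0.8\} of N and
#' iteration count \{1, 5, 10, 20, 30\}; ties break toward fewer
#' iterations, then the smaller fraction.
#'
#' @param K training kernel matrix.
#' @param y training labels.
#' @param fractions,iters the grids.
#' @param k folds (default 5).
#' @param seed RNG seed.
#' @return list with \code{resampleFraction} and \code{maxIter}.
#' @export
tuneBoost <- function(K, y, fractions = c(0.2, 0.4, 0.6, 0.8),
                      iters = c(1L, 5L, 10L, 20L, 30L), k = 5L, seed = 1L) {
  set.seed(seed)
  folds <- stratifiedFolds(y, k)
  best <- NULL; bestAcc <- -Inf
  for (it in sort(iters)) for (fr in sort(fractions)) {
    correct <- 0L; total <- 0L
    for (fold in seq_len(k)) {
      hold <- which(folds == fold); tr <- which(folds != fold)
      if (length(unique(y[tr])) < 2L) next
      model <- adaboostRvm(K[tr, tr, drop = FALSE], y[tr], fr, it,
                           seed = seed + fold)
      pred <- predictBoostedRvm(model, K[hold, tr, drop = FALSE])
      correct <- correct + sum(predictedLabels(pred) == y[hold])
      total <- total + length(hold)
    }
    acc <- if (total) correct / total else 0
    if (acc > bestAcc + 1e-12) {  # strict: earlier (smaller) grid wins ties
      bestAcc <- acc
      best <- list(resampleFraction = fr, maxIter = it)
    }
  }
  best
}
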