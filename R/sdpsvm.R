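# Soft-margin SVM dual on a fixed kernel:
#   max 2 a'e - a' diag(y) K diag(y) a   s.t. a'y = 0, 0 <= a <= C
# solved as a box/equality QP with kernlab's interior-point solver.
svmDualQP <- function(K, y, C, jitter = 1e-8) {
  n <- length(y)
  G <- (K * tcrossprod(y)) + diag(jitter, n)
  res <- NULL
  # escalate on near-singularity; the large final values only engage on
  # degenerate (e.g. rank-one) kernels where any solution is equivalent
  for (j in c(jitter, 1e-6, 1e-4, 1e-2, 1)) {
    res <- tryCatch(
      kernlab::ipop(c = matrix(-2, n, 1), H = 2 * (K * tcrossprod(y)) +
                      diag(j, n),
                    A = matrix(y, 1, n), b = 0, r = 0,
                    l = matrix(0, n, 1), u = matrix(C, n, 1),
                    sigf = 9, maxiter = 80),
      error = function(e) NULL)
    if (!is.null(res)) break
  }
  if (is.null(res)) stop("SVM dual QP solver failed on a degenerate kernel")
  alpha <- as.numeric(kernlab::primal(res))
  alpha <- pmin(pmax(alpha, 0), C)
  list(alpha = alpha, value = 2 * sum(alpha) - sum(alpha * (G %*% alpha)))
}

# bias for a combined train kernel; standard convention
# b = -(max_{y=-1} g + min_{y=+1} g)/2 with g = K diag(y) alpha;
# bias = "paper" uses the printed double-max variant.
svmBias <- function(g, y, bias = c("standard", "paper")) {
  bias <- match.arg(bias)
  if (bias == "standard")
    -(max(g[y == -1]) + min(g[y == 1])) / 2
  else
    -(max(g[y == -1]) + max(g[y == 1])) / 2
}

#' Multiple-kernel SDP-SVM (QCQP form)
#'
#' Solves the multiple-kernel 1-norm soft-margin SVM
#'   max_{a,t} 2 a'e - c t
#'   s.t. t >= (1/r_i) a' diag(y) K_i diag(y) a,  r_i = trace(K_i),
#'        a'y = 0,  0 <= a <= C
#' whose saddle-point form is min over kernel weights on the simplex
#' \{lambda >= 0, sum lambda = c\} of the single-kernel SVM dual value on
#' the combined kernel sum_i (lambda_i / r_i) K_i. The outer minimization
#' is convex (pointwise max of affine functions) and solved by projected
#' gradient with the envelope gradient -(1/r_i) a' diag(y) K_i diag(y) a;
#' the inner QP uses an interior-point solver. The duals of the quadratic
#' constraints give the kernel weights mu_i = lambda_i / r_i, scaled so
#' trace(sum mu_i K_i) = c; reported \code{mu} is additionally normalized
#' to sum to one.
#'
#' @param Ks list of PSD training kernel matrices (one per source).
#' @param y training labels in \{-1, +1\}.
#' @param C box constraint.
#' @param cTrace trace budget c; defaults to the training-set size.
#' @param bias \code{"standard"} or \code{"paper"} bias convention.
#' @param maxOuter outer projected-gradient iterations.
#' @param tol relative objective tolerance of the outer loop.
#' @return a \code{SdpSvmModel}.
#' @export
fitSdpSvm <- function(Ks, y, C = 1, cTrace = length(y),
                      bias = "standard", maxOuter = 60L, tol = 1e-8) {
  stopifnot(length(Ks) >= 1L, C > 0, all(y %in% c(-1, 1)))
  n <- length(y)
  for (K in Ks) stopifnot(nrow(K) == n, ncol(K) == n)
  m <- length(Ks)
  r <- vapply(Ks, function(K) sum(diag(K)), numeric(1))
  combine <- function(lambda) {
    K <- matrix(0, n, n)
    for (i in seq_len(m)) K <- K + (lambda[i] / r[i]) * Ks[[i]]
    K
  }
  evalInner <- function(lambda) svmDualQP(combine(lambda), y, C)
  lambda <- rep(cTrace / m, m)
  inner <- evalInner(lambda)
  if (m > 1L) {
    step <- cTrace
    for (it in seq_len(maxOuter)) {
      a <- inner$alpha
      grad <- -vapply(seq_len(m), function(i) {
        ya <- y * a
        sum(ya * (Ks[[i]] %*% ya)) / r[i]
      }, numeric(1))
      improved <- FALSE
      s <- step
      for (bt in 1:30) {
        cand <- projectSimplexCap(lambda - s * grad, cTrace)
        cand <- cand * (cTrace / max(sum(cand), .Machine$double.eps))
        candInner <- evalInner(cand)
        if (candInner$value < inner$value - 1e-12) { improved <- TRUE; break }
        s <- s / 2
      }
      if (!improved) break
      conv <- (inner$value - candInner$value) <
        tol * max(1, abs(inner$value))
      lambda <- cand; inner <- candInner; step <- s * 2
      if (conv) break
    }
  }
  coef <- lambda / r                      # mu on the trace scale
  Keff <- combine(lambda)
  alpha <- inner$alpha
  g <- as.numeric(Keff %*% (y * alpha))
  b <- svmBias(g, y, bias)
  model <- new("SdpSvmModel", mu = coef / sum(coef), lambda = coef,
               alpha = alpha, b = b, cTrace = cTrace,
               yTrain = as.numeric(y), objective = inner$value)
  model@C <- C   # set directly: a named `C =` in new() would match Class
  model
}

#' Decision values and labels from a fitted SDP-SVM
#'
#' f(x) = sum_i alpha_i y_i K(x_i, x) + b with
#' K = sum_k mu_k K_k the learned combined kernel; x is classified +1 when
#' f > 0, otherwise -1 (f = 0 goes to -1).
#'
#' @param model a \code{SdpSvmModel}.
#' @param KtestBlocks list of (n_test x n_train) cross-kernel blocks, one
#'   per source, in the order the model was fitted with.
#' @param sampleIds optional test-sample IDs.
#' @return a \code{PredictionResult} with \code{scoreKind}
#'   \code{"decision_value"}.
#' @export
predictSdpSvm <- function(model, KtestBlocks, sampleIds = character()) {
  m <- length(model@lambda)
  stopifnot(length(KtestBlocks) == m)
  nTr <- length(model@alpha)
  Kt <- matrix(0, nrow(KtestBlocks[[1L]]), nTr)
  for (i in seq_len(m)) {
    stopifnot(ncol(KtestBlocks[[i]]) == nTr)
    Kt <- Kt + model@lambda[i] * KtestBlocks[[i]]
  }
  f <- as.numeric(Kt %*% (model@yTrain * model@alpha)) + model@b
  PredictionResult(ifelse(f > 0, 1, -1), f, "decision_value", sampleIds)
}

#' Tune the SVM box constraint C by k-fold cross-validation
#'
#' @param Ks list of training kernel matrices.
#' @param y training labels.
#' @param grid candidate values (default \{0.01, 0.1, 1, 10, 100\}).
#' @param k folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @return the C maximizing mean CV accuracy (ties toward smaller C).
#' @export
tuneSvmC <- function(Ks, y, grid = c(0.01, 0.1, 1, 10, 100), k = 5L,
                     seed = 1L) {
  grid <- sort(grid)
  set.seed(seed)
  folds <- stratifiedFolds(y, k)
  acc <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    correct <- 0L; total <- 0L
    for (fold in seq_len(k)) {
      hold <- which(folds == fold); tr <- which(folds != fold)
      if (length(unique(y[tr])) < 2L) next
      model <- fitSdpSvm(lapply(Ks, function(K) K[tr, tr]), y[tr],
                         C = grid[gi])
      pred <- predictSdpSvm(model,
                            lapply(Ks, function(K) K[hold, tr, drop = FALSE]))
      correct <- correct + sum(predictedLabels(pred) == y[hold])
      total <- total + length(hold)
    }
    acc[gi] <- if (total) correct / total else 0
  }
  grid[which.max(acc)]
}
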