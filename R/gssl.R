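#' Graph semi-supervised learning on a single network
#'
#' Minimizes sum_i (f_i - y_i)^2 + c sum_ij w_ij (f_i - f_j)^2; the closed
#' form is f = (I + cL)^{-1} y, computed by a dense linear solve (never an
#' explicit inverse). Unlabelled nodes carry y_i = 0.
#'
#' @param L Laplacian matrix (n x n).
#' @param y numeric label vector over all n nodes, values in \{-1, 0, +1\}.
#' @param c non-negative smoothness trade-off.
#' @return a \code{GraphSSLModel} with slot \code{f} the function scores.
#' @export
gsslSolveSingle <- function(L, y, c) {
  if (c < 0) stop("c must be non-negative")
  n <- length(y)
  stopifnot(nrow(L) == n, ncol(L) == n)
  f <- solve(diag(n) + c * L, y)
  new("GraphSSLModel", f = as.numeric(f), c = c, alphas = numeric(),
      trainIdx = which(y != 0))
}

#' Median cut-off classification of function scores
#'
#' A node is classified +1 when its score is strictly closer to the median
#' score of the labelled +1 nodes than to the median score of the labelled
#' -1 nodes; ties go to -1 (fixed convention).
#'
#' @param f numeric function scores over nodes.
#' @param y label vector used in the fit (0 = unlabelled); both classes
#'   must be present among labelled nodes.
#' @param idx indices of nodes to classify (default all).
#' @param sampleIds optional IDs for the classified nodes.
#' @return a \code{PredictionResult} with \code{scoreKind}
#'   \code{"function_score"}.
#' @export
medianCutoff <- function(f, y, idx = seq_along(f), sampleIds = character()) {
  if (!any(y == 1) || !any(y == -1))
    stop("both classes must be present among labelled nodes")
  mPos <- median(f[y == 1])
  mNeg <- median(f[y == -1])
  fi <- f[idx]
  lab <- ifelse(abs(fi - mPos) < abs(fi - mNeg), 1, -1)
  PredictionResult(lab, fi, "function_score", sampleIds)
}

# Objective of the multi-network convex weighting: y' (I + sum a_k L_k)^-1 y.
# Symmetrized sharpened Laplacians are not always PSD, so I + sum a L can
# leave the positive-definite cone for large weights; such points get an
# infinite objective and the line search backs away from them.
gsslObjective <- function(alpha, Ls, y) {
  A <- diag(length(y))
  for (k in seq_along(Ls)) A <- A + alpha[k] * Ls[[k]]
  R <- tryCatch(chol((A + t(A)) / 2), error = function(e) NULL)
  if (is.null(R)) return(Inf)
  sum(y * solve(A, y))
}

# Analytic gradient: d/da_k = -y' A^-1 L_k A^-1 y with A = I + sum a L.
gsslGradient <- function(alpha, Ls, y) {
  A <- diag(length(y))
  for (k in seq_along(Ls)) A <- A + alpha[k] * Ls[[k]]
  u <- solve(A, y)
  -vapply(Ls, function(L) sum(u * (L %*% u)), numeric(1))
}

# Euclidean projection onto {a >= 0, sum a <= c}.
projectSimplexCap <- function(v, cap) {
  v <- pmax(v, 0)
  if (sum(v) <= cap) return(v)
  # project onto the simplex sum = cap
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - cap) / seq_along(u) > 0))
  theta <- (css[rho] - cap) / rho
  pmax(v - theta, 0)
}

#' Multi-network graph semi-supervised learning
#'
#' Learns per-network weights alpha by minimizing
#' y' (I + sum_k alpha_k L_k)^{-1} y over \{alpha >= 0, sum alpha <= c\}
#' (the Lagrange-dual weighting of the shared-smoothness-bound
#' formulation), then returns f = (I + sum alpha_k L_k)^{-1} y. The
#' objective is convex and non-increasing in each alpha_k, so the budget
#' constraint is active at the optimum; a projected-gradient method with
#' Armijo backtracking from the uniform feasible start alpha = c/m is used.
#' Networks receiving zero weight are redundant for the solution.
#'
#' @param Ls list of Laplacian matrices of identical dimension.
#' @param y label vector (0 = unlabelled).
#' @param c positive weight budget.
#' @param maxIter,tol projected-gradient iteration cap and relative
#'   objective-change tolerance.
#' @return a \code{GraphSSLModel} with slots \code{f} and \code{alphas}.
#' @export
gsslSolveMulti <- function(Ls, y, c, maxIter = 500L, tol = 1e-12) {
  stopifnot(length(Ls) >= 1L, c > 0)
  n <- length(y)
  for (L in Ls) stopifnot(nrow(L) == n, ncol(L) == n)
  m <- length(Ls)
  alpha <- rep(c / m, m)
  obj <- gsslObjective(alpha, Ls, y)
  while (!is.finite(obj) && max(alpha) > 1e-12) {  # shrink into the PD cone
    alpha <- alpha / 2
    obj <- gsslObjective(alpha, Ls, y)
  }
  step <- c
  for (iter in seq_len(maxIter)) {
    g <- gsslGradient(alpha, Ls, y)
    improved <- FALSE
    s <- step
    for (bt in 1:40) {
      cand <- projectSimplexCap(alpha - s * g, c)
      candObj <- gsslObjective(cand, Ls, y)
      if (candObj < obj - 1e-15) { improved <- TRUE; break }
      s <- s / 2
    }
    if (!improved) break
    converged <- (obj - candObj) < tol * max(1, abs(obj))
    alpha <- cand; obj <- candObj; step <- s * 2
    if (converged) break
  }
  # polish: move budget between coordinate pairs if it helps (handles
  # vertex optima the projected path may approach only asymptotically)
  repeat {
    better <- FALSE
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i == j || alpha[j] <= 0) next
      cand <- alpha
      cand[i] <- cand[i] + alpha[j]; cand[j] <- 0
      co <- gsslObjective(cand, Ls, y)
      if (co < obj - 1e-12) { alpha <- cand; obj <- co; better <- TRUE }
    }
    if (!better) break
  }
  A <- diag(n)
  for (k in seq_len(m)) A <- A + alpha[k] * Ls[[k]]
  f <- solve(A, y)
  new("GraphSSLModel", f = as.numeric(f), c = c, alphas = alpha,
      trainIdx = which(y != 0))
}

#' The cross-validation grid for the smoothness trade-off c
#'
#' @return the default search grid.
#' @export
cGrid <- function() c(0.001, 0.005, 0.01, 0.05, 0.1, 0.25, 0.5, 1, 1.5,
                      5, 10, 25, 50, 100)

# stratified fold assignment; guarantees both classes in every fold when
# each class has >= k members, otherwise folds are as balanced as possible
stratifiedFolds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Tune the trade-off parameter c by repeated stratified k-fold CV
#'
#' Within the labelled training nodes only: each fold's labels are blinded
#' to 0, the graph method is refit transductively on the training subgraph,
#' and the held-out fold is classified by median cut-off. Returns the grid
#' value with the highest mean CV accuracy; ties break toward smaller c.
#'
#' @param study a \code{MultiOmicsStudy} whose non-zero labels are the
#'   training samples.
#' @param method \code{"gssl"} or \code{"sharpening"}.
#' @param grid candidate values, default \code{\link{cGrid}()}.
#' @param k folds (default 5); \code{repeats} repetitions (default 5).
#' @param seed RNG seed for fold assignment.
#' @param corMethod correlation type for the weight matrices.
#' @return the selected c.
#' @export
tuneC <- function(study, method = c("gssl", "sharpening"), grid = cGrid(),
                  k = 5L, repeats = 5L, seed = 1L,
                  corMethod = "pearson") {
  method <- match.arg(method)
  trainIdx <- which(studyLabels(study) != 0)
  y <- studyLabels(study)[trainIdx]
  Ws <- lapply(studySources(study),
               function(X) correlationWeights(X[trainIdx, , drop = FALSE],
                                              corMethod))
  set.seed(seed)
  acc <- matrix(0, length(grid), repeats * k)
  col <- 0L
  for (r in seq_len(repeats)) {
    folds <- stratifiedFolds(y, k)
    for (fold in seq_len(k)) {
      col <- col + 1L
      hold <- which(folds == fold)
      yb <- blindLabels(y, hold)
      if (!any(yb == 1) || !any(yb == -1)) next
      for (gi in seq_along(grid)) {
        fit <- if (method == "gssl")
          gsslSolveMulti(lapply(Ws, laplacianMatrix), yb, grid[gi])
        else {
          Lsh <- lapply(Ws, function(W) laplacianMatrix(sharpenWeights(W, yb)))
          sharpenedSolve(Lsh, yb, grid[gi])
        }
        pred <- medianCutoff(fit@f, yb, hold)
        acc[gi, col] <- mean(predictedLabels(pred) == y[hold])
      }
    }
  }
  grid[which.max(rowMeans(acc))]  # which.max takes the first (smallest) tie
}
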