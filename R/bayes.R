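#' Bonferroni feature filtering by two-sample association test
#'
#' Each feature is tested for association with the binary label by a pooled
#' two-sample t-test; features with p < 0.05 / n_features are kept, with
#' direction the sign of the (positive minus negative) class-mean
#' difference. Zero-variance features are skipped. When nothing passes the
#' Bonferroni threshold, the single smallest-p feature is kept so the
#' classifier always has a score.
#'
#' @param X numeric matrix (samples x features), training rows only.
#' @param y training labels in \{-1, +1\}.
#' @param alpha familywise level before correction (default 0.05).
#' @return list with \code{ids} (selected feature names), \code{directions}
#'   (named sign vector), and \code{pvalues} for all testable features.
#' @export
filterFeatures <- function(X, y, alpha = 0.05) {
  stopifnot(all(y %in% c(-1, 1)), any(y == 1), any(y == -1))
  pos <- y == 1; neg <- y == -1
  n1 <- sum(pos); n2 <- sum(neg)
  m1 <- colMeans(X[pos, , drop = FALSE])
  m2 <- colMeans(X[neg, , drop = FALSE])
  v1 <- apply(X[pos, , drop = FALSE], 2L, var)
  v2 <- apply(X[neg, , drop = FALSE], 2L, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  ok <- is.finite(se) & se > 0
  tstat <- (m1 - m2)[ok] / se[ok]
  p <- 2 * pt(-abs(tstat), df = n1 + n2 - 2)
  names(p) <- colnames(X)[ok]
  thr <- alpha / ncol(X)
  keep <- names(p)[p < thr]
  if (length(keep) == 0L) keep <- names(p)[which.min(p)]
  dirs <- sign((m1 - m2)[keep])
  dirs[dirs == 0] <- 1
  list(ids = keep, directions = dirs, pvalues = p)
}

#' Per-sample source score from selected features
#'
#' score_i = sum_j direction_j * z_ij over the selected features, with z
#' computed from the supplied (training) centers and scales.
#'
#' @param X numeric matrix (any rows) containing the selected features.
#' @param ids selected feature names.
#' @param directions named sign vector over \code{ids}.
#' @param center,scale named training means and standard deviations.
#' @return numeric score per row of \code{X}.
#' @export
sourceScore <- function(X, ids, directions, center, scale) {
  Z <- sweep(sweep(X[, ids, drop = FALSE], 2L, center[ids]), 2L,
             pmax(scale[ids], .Machine$double.eps), `/`)
  as.numeric(Z %*% directions[ids])
}

#' Quartile bin edges from training scores
#'
#' @param scores training score vector.
#' @return the 25/50/75 percent quantiles (linear-interpolation
#'   convention), defining 4 bins; degenerate all-identical scores yield a
#'   single bin with a warning.
#' @export
quartileEdges <- function(scores) {
  if (max(scores) - min(scores) < .Machine$double.eps) {
    warning("all scores identical; single bin")
    return(numeric())
  }
  unname(quantile(scores, c(0.25, 0.5, 0.75), type = 7))
}

#' Assign scores to bins given training edges
#'
#' Boundary values fall in the lower bin; scores below the training minimum
#' go to bin 1, above the maximum to the top bin.
#'
#' @param scores numeric vector.
#' @param edges edges from \code{\link{quartileEdges}}.
#' @return integer bins in 1..(length(edges)+1).
#' @export
binScores <- function(scores, edges) {
  if (length(edges) == 0L) return(rep(1L, length(scores)))
  vapply(scores, function(s) 1L + sum(s > edges), integer(1))
}

#' Dependence edges among source-score variables
#'
#' The conditional (on the class) correlation of each variable pair is the
#' mean of the two within-class Pearson correlations of the binned scores;
#' an edge is added when its absolute value exceeds the threshold.
#'
#' @param binned integer matrix (samples x sources) of training bins.
#' @param y training labels in \{-1, +1\}.
#' @param threshold edge threshold (default 0.3).
#' @return two-column integer matrix of edges (possibly zero rows).
#' @export
buildStructure <- function(binned, y, threshold = 0.3) {
  m <- ncol(binned)
  edges <- matrix(integer(), 0L, 2L)
  if (m < 2L) return(edges)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    rs <- vapply(c(-1, 1), function(cls) {
      b <- binned[y == cls, c(i, j), drop = FALSE]
      if (var(b[, 1L]) == 0 || var(b[, 2L]) == 0) return(0)
      cor(b[, 1L], b[, 2L])
    }, numeric(1))
    if (abs(mean(rs)) > threshold) edges <- rbind(edges, c(i, j))
  }
  edges
}

# connected components of an undirected edge set over m nodes
connectedComponents <- function(m, edges) {
  comp <- seq_len(m)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
    if (a != b) comp[a] <- b
  }
  roots <- vapply(seq_len(m), find, integer(1))
  unname(split(seq_len(m), roots))
}

#' Fit CPTs and prior odds on pre-binned variables
#'
#' The dependent blocks (connected components of the edge set) get joint
#' conditional probability tables over all bin combinations; isolated
#' variables get univariate tables. Every cell carries a Laplace
#' pseudocount so posterior odds are always finite.
#'
#' @param binned integer matrix (samples x variables) of training bins.
#' @param y training labels in \{-1, +1\}.
#' @param edges dependence edges (zero rows = simple/naive model).
#' @param nBins number of bins per variable.
#' @param pseudocount Laplace pseudocount per CPT cell (> 0).
#' @return a \code{BayesNetModel} holding only the CPT layer (slots
#'   \code{cpts}, \code{edges}, \code{priorOdds}, \code{pseudocount},
#'   \code{nBins}); usable directly with \code{\link{posteriorOdds}}.
#' @export
binnedBayes <- function(binned, y, edges = matrix(integer(), 0L, 2L),
                        nBins = 4L, pseudocount = 1) {
  stopifnot(pseudocount > 0, all(y %in% c(-1, 1)))
  m <- ncol(binned)
  comps <- connectedComponents(m, edges)
  if (any(lengths(comps) > 3L))
    warning("a dependent block has more than 3 variables; its joint CPT has ",
            max(lengths(comps)), "^k cells")
  cpts <- lapply(comps, function(vars) {
    k <- length(vars)
    cells <- nBins^k
    lapply(c(`-1` = -1, `1` = 1), function(cls) {
      rows <- which(y == cls)
      idx <- rep(1L, length(rows))
      for (p in seq_len(k))
        idx <- idx + (binned[rows, vars[p]] - 1L) * nBins^(p - 1L)
      counts <- tabulate(idx, nbins = cells) + pseudocount
      counts / sum(counts)
    })
  })
  new("BayesNetModel", filtered = list(), directions = list(),
      centers = list(), scales = list(), binEdges = list(),
      edges = edges, cpts = list(comps = comps, tables = cpts),
      priorOdds = sum(y == 1) / sum(y == -1), pseudocount = pseudocount,
      nBins = as.integer(nBins))
}

#' Posterior odds for pre-binned samples
#'
#' Odds = prior odds times the product over dependent blocks and isolated
#' variables of their class-likelihood ratios; samples with odds > 1 are
#' classified +1, otherwise -1 (odds exactly 1 goes to -1).
#'
#' @param model a \code{BayesNetModel} from \code{\link{binnedBayes}} or
#'   \code{\link{fitBayesNet}}.
#' @param binned integer matrix (samples x variables) of bins.
#' @return a \code{PredictionResult} with \code{scoreKind "odds"}.
#' @export
posteriorOdds <- function(model, binned) {
  comps <- model@cpts$comps
  tables <- model@cpts$tables
  nBins <- model@nBins
  odds <- rep(model@priorOdds, nrow(binned))
  for (ci in seq_along(comps)) {
    vars <- comps[[ci]]
    idx <- rep(1L, nrow(binned))
    for (p in seq_along(vars))
      idx <- idx + (binned[, vars[p]] - 1L) * nBins^(p - 1L)
    odds <- odds * tables[[ci]][["1"]][idx] / tables[[ci]][["-1"]][idx]
  }
  PredictionResult(ifelse(odds > 1, 1, -1), odds, "odds")
}

#' Fit the posterior-odds Bayesian network classifier on a study
#'
#' Per source: Bonferroni feature filtering, signed standardized-score
#' construction, quartile binning with training edges. The simple variant
#' treats all source scores as conditionally independent given the class;
#' the structured variant adds dependence edges where the mean within-class
#' correlation of the binned scores exceeds the threshold and fits joint
#' CPTs per connected component.
#'
#' @param study a \code{MultiOmicsStudy}.
#' @param trainIdx indices of training samples (their labels must be
#'   non-zero).
#' @param variant \code{"simple"} (default) or \code{"structured"}.
#' @param nBins bins per source score (default 4, quartiles).
#' @param pseudocount Laplace pseudocount (default 1).
#' @param edgeThreshold dependence threshold (default 0.3).
#' @return a fitted \code{BayesNetModel}.
#' @export
fitBayesNet <- function(study, trainIdx, variant = c("simple", "structured"),
                        nBins = 4L, pseudocount = 1, edgeThreshold = 0.3) {
  variant <- match.arg(variant)
  y <- studyLabels(study)[trainIdx]
  stopifnot(all(y %in% c(-1, 1)))
  srcs <- studySources(study)
  filtered <- directions <- centers <- scales <- binEdges <- list()
  binned <- matrix(0L, length(trainIdx), length(srcs))
  for (k in seq_along(srcs)) {
    Xtr <- srcs[[k]][trainIdx, , drop = FALSE]
    sel <- filterFeatures(Xtr, y)
    ctr <- colMeans(Xtr[, sel$ids, drop = FALSE])
    scl <- apply(Xtr[, sel$ids, drop = FALSE], 2L, sd)
    sc <- sourceScore(Xtr, sel$ids, sel$directions, ctr, scl)
    edg <- quartileEdges(sc)
    filtered[[k]] <- sel$ids; directions[[k]] <- sel$directions
    centers[[k]] <- ctr; scales[[k]] <- scl; binEdges[[k]] <- edg
    binned[, k] <- binScores(sc, edg)
  }
  edges <- if (variant == "structured")
    buildStructure(binned, y, edgeThreshold) else matrix(integer(), 0L, 2L)
  core <- binnedBayes(binned, y, edges, nBins, pseudocount)
  core@filtered <- filtered; core@directions <- directions
  core@centers <- centers; core@scales <- scales; core@binEdges <- binEdges
  core
}

#' Classify samples with a fitted Bayesian network classifier
#'
#' @param model a \code{BayesNetModel} from \code{\link{fitBayesNet}}.
#' @param study the study the model was fitted on.
#' @param idx indices of the samples to classify.
#' @return a \code{PredictionResult} with posterior odds as scores.
#' @export
predictBayesNet <- function(model, study, idx) {
  srcs <- studySources(study)
  binned <- matrix(0L, length(idx), length(srcs))
  for (k in seq_along(srcs)) {
    sc <- sourceScore(srcs[[k]][idx, , drop = FALSE], model@filtered[[k]],
                      model@directions[[k]], model@centers[[k]],
                      model@scales[[k]])
    binned[, k] <- binScores(sc, model@binEdges[[k]])
  }
  posteriorOdds(model, binned)
}
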