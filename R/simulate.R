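#' Specification of a synthetic multi-omics study
#'
#' Describes a Gaussian class-shift simulation: each source has
#' \code{nInformative} features whose class means sit at +delta/2 (positives)
#' and -delta/2 (negatives) in units of the noise standard deviation, and
#' \code{nFeatures - nInformative} pure-noise features. An optional
#' family/cluster structure adds a per-cluster random intercept
#' (sd = noiseSd/2) shared by all features and sources of a sample.
#'
#' @param nSamples total number of samples.
#' @param sources list of per-source specs, each a list with elements
#'   \code{nFeatures}, \code{nInformative}, \code{delta} (class-mean shift in
#'   sd units) and optionally \code{noiseSd} (default 1).
#' @param classBalance fraction of positive samples, in (0, 1).
#' @param nClusters optional number of clusters/families.
#' @param seed integer RNG seed; the study is fully reproducible from it.
#' @return a list of class \code{"SimulationSpec"}.
#' @export
simulationSpec <- function(nSamples, sources, classBalance = 0.5,
                           nClusters = NULL, seed = 1L) {
  stopifnot(nSamples >= 4L, classBalance > 0, classBalance < 1,
            length(sources) >= 1L)
  sources <- lapply(sources, function(s) {
    if (is.null(s$noiseSd)) s$noiseSd <- 1
    stopifnot(s$nInformative <= s$nFeatures, s$nInformative >= 0,
              s$noiseSd > 0)
    s
  })
  structure(list(nSamples = as.integer(nSamples), sources = sources,
                 classBalance = classBalance,
                 nClusters = if (is.null(nClusters)) NULL else
                   as.integer(nClusters),
                 seed = as.integer(seed)),
            class = "SimulationSpec")
}

#' Generate a synthetic MultiOmicsStudy
#'
#' @param spec a \code{\link{simulationSpec}}.
#' @return a \code{MultiOmicsStudy}; when clusters were requested the
#'   per-cluster intercepts are attached as
#'   \code{attr(study, "clusterIntercepts")}.
#' @export
generateStudy <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  n <- spec$nSamples
  nPos <- round(spec$classBalance * n)
  nNeg <- n - nPos
  if (nPos < 2L || nNeg < 2L)
    stop("classBalance would leave fewer than 2 samples in a class")
  y <- sample(c(rep(1, nPos), rep(-1, nNeg)))
  ids <- sprintf("s%03d", seq_len(n))
  names(y) <- ids

  clusters <- NULL
  interceptPerSample <- rep(0, n)
  clusterIntercepts <- NULL
  if (!is.null(spec$nClusters)) {
    clusters <- setNames(
      paste0("fam", sample(rep_len(seq_len(spec$nClusters), n))), ids)
    sdInt <- spec$sources[[1L]]$noiseSd / 2
    clusterIntercepts <- setNames(rnorm(spec$nClusters, 0, sdInt),
                                  paste0("fam", seq_len(spec$nClusters)))
    interceptPerSample <- unname(clusterIntercepts[clusters])
  }

  srcs <- list()
  for (k in seq_along(spec$sources)) {
    s <- spec$sources[[k]]
    X <- matrix(rnorm(n * s$nFeatures, 0, s$noiseSd), n, s$nFeatures)
    if (s$nInformative > 0L) {
      shift <- (s$delta * s$noiseSd / 2) * y   # +d/2 positives, -d/2 negatives
      X[, seq_len(s$nInformative)] <-
        X[, seq_len(s$nInformative), drop = FALSE] + shift
    }
    X <- X + interceptPerSample
    dimnames(X) <- list(ids, sprintf("src%d_f%04d", k, seq_len(s$nFeatures)))
    srcs[[paste0("source", k)]] <- X
  }
  study <- MultiOmicsStudy(srcs, y, clusters)
  if (!is.null(clusterIntercepts))
    attr(study, "clusterIntercepts") <- clusterIntercepts
  study
}

#' Subsample a study to an exact class-imbalance ratio
#'
#' Draws the largest achievable study whose positive:negative counts are in
#' the exact ratio \code{posParts:negParts}, sampling without replacement
#' within each class.
#'
#' @param study a \code{MultiOmicsStudy} with no unlabelled samples.
#' @param ratio integer vector \code{c(posParts, negParts)}, e.g.
#'   \code{c(5, 1)}.
#' @param seed RNG seed for the without-replacement draw.
#' @return the subsampled \code{MultiOmicsStudy}, in original sample order.
#' @export
subsampleImbalance <- function(study, ratio, seed = 1L) {
  stopifnot(length(ratio) == 2L, all(ratio >= 1))
  a <- as.integer(ratio[1L]); b <- as.integer(ratio[2L])
  y <- studyLabels(study)
  P <- sum(y == 1); N <- sum(y == -1)
  k <- min(P %/% a, N %/% b)
  if (k < 1L)
    stop(sprintf("ratio %d:%d unachievable; max achievable counts are %d pos, %d neg",
                 a, b, P, N))
  nPos <- a * k; nNeg <- b * k
  set.seed(seed)
  keepPos <- sample(which(y == 1), nPos)
  keepNeg <- sample(which(y == -1), nNeg)
  keep <- sort(c(keepPos, keepNeg))
  src <- lapply(studySources(study), function(X) X[keep, , drop = FALSE])
  cl <- studyClusters(study)
  MultiOmicsStudy(src, y[keep],
                  if (length(cl)) setNames(cl[keep], names(y)[keep]) else NULL)
}

#' Write a study to a directory as plain-text files
#'
#' One TSV per source plus \code{labels.tsv} and (when present)
#' \code{clusters.tsv}, readable back with \code{\link{loadFeatureMatrix}},
#' \code{\link{readLabels}} and \code{\link{readClusters}}.
#'
#' @param study a \code{MultiOmicsStudy}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(studySources(study))) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    writeFeatureMatrix(studySources(study)[[nm]], p)
    paths <- c(paths, p)
  }
  y <- studyLabels(study)
  if (any(y == 0)) stop("cannot write a study with unlabelled samples")
  p <- file.path(dir, "labels.tsv")
  write.table(data.frame(sample_id = names(y), label = y), p, sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  cl <- studyClusters(study)
  if (length(cl)) {
    p <- file.path(dir, "clusters.tsv")
    write.table(data.frame(sample_id = names(y), cluster_id = cl), p,
                sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
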