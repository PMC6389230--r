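#' @import methods
#' @importFrom stats cor median quantile sd var rnorm runif pt qnorm
#'   optim p.adjust setNames predict
#' @importFrom utils head read.table write.table
NULL

#' MultiOmicsStudy: aligned multi-source samples with a binary trait
#'
#' The universal input container: an ordered list of per-source numeric
#' matrices (samples x features) sharing one sample order, a label vector in
#' \{-1, 0, +1\} (0 marks unlabelled/blinded samples), and an optional
#' cluster/family identifier per sample for leave-cluster-out designs.
#'
#' @slot sources named list of numeric matrices, each with rownames equal to
#'   the study sample IDs in identical order.
#' @slot labels numeric vector over samples with values in \{-1, 0, +1\}.
#' @slot clusters character vector of per-sample cluster IDs, or a
#'   zero-length character vector when no cluster structure is present.
#' @exportClass MultiOmicsStudy
setClass("MultiOmicsStudy",
  slots = c(sources = "list", labels = "numeric", clusters = "character"))

setValidity("MultiOmicsStudy", function(object) {
  msg <- character()
  if (length(object@sources) < 1L)
    msg <- c(msg, "at least one data source is required")
  ids <- names(object@labels)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "labels must be named with unique sample IDs")
  if (!all(object@labels %in% c(-1, 0, 1)))
    msg <- c(msg, "labels must take values in {-1, 0, +1}")
  for (k in seq_along(object@sources)) {
    X <- object@sources[[k]]
    if (!is.matrix(X) || !is.numeric(X))
      msg <- c(msg, sprintf("source %d is not a numeric matrix", k))
    else {
      if (!identical(rownames(X), ids))
        msg <- c(msg, sprintf("source %d sample IDs differ from label IDs", k))
      if (anyNA(X))
        msg <- c(msg, sprintf("source %d contains missing values", k))
    }
  }
  if (length(object@clusters) > 0L &&
      length(object@clusters) != length(object@labels))
    msg <- c(msg, "clusters must have one entry per sample")
  if (length(msg)) msg else TRUE
})

#' PredictionResult: predicted labels plus the score that produced them
#'
#' @slot predicted numeric vector in \{-1, +1\}.
#' @slot scores numeric vector (function score, decision value, probability,
#'   or posterior odds, depending on the method).
#' @slot scoreKind one of \code{"function_score"}, \code{"decision_value"},
#'   \code{"probability"}, \code{"odds"}.
#' @slot sampleIds character vector of sample IDs the entries refer to.
#' @exportClass PredictionResult
setClass("PredictionResult",
  slots = c(predicted = "numeric", scores = "numeric",
            scoreKind = "character", sampleIds = "character"))

setValidity("PredictionResult", function(object) {
  msg <- character()
  if (length(object@predicted) != length(object@scores))
    msg <- c(msg, "predicted and scores must have equal length")
  if (!all(object@predicted %in% c(-1, 1)))
    msg <- c(msg, "predicted labels must be -1 or +1")
  if (!object@scoreKind %in%
      c("function_score", "decision_value", "probability", "odds"))
    msg <- c(msg, "invalid scoreKind")
  if (object@scoreKind == "probability" &&
      (any(object@scores < 0) || any(object@scores > 1)))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' EvaluationReport: per-algorithm benchmark metrics with bootstrap CIs
#'
#' @slot metrics data.frame with columns algorithm, metric, mean, lower,
#'   upper (percentile-bootstrap 95\% limits).
#' @slot perRun data.frame of raw per-run metrics (run, algorithm,
#'   accuracy, f1, auc, sensitivity, specificity).
#' @slot nRuns integer, number of evaluation runs attempted.
#' @slot failures named integer vector counting excluded runs per algorithm.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  slots = c(metrics = "data.frame", perRun = "data.frame",
            nRuns = "integer", failures = "integer"))

# --- fitted-model classes -------------------------------------------------

#' Virtual parent of all fitted integrator models
#' @exportClass IntegrationModel
setClass("IntegrationModel", representation("VIRTUAL"))

#' Fitted graph semi-supervised learning model
#'
#' @slot f function scores over all nodes (trained transductively).
#' @slot c trade-off parameter used.
#' @slot alphas per-network weights (length 0 for the single-network solve).
#' @slot trainIdx indices of the labelled nodes used for the median cut-off.
#' @exportClass GraphSSLModel
setClass("GraphSSLModel", contains = "IntegrationModel",
  slots = c(f = "numeric", c = "numeric", alphas = "numeric",
            trainIdx = "integer"))

#' Fitted composite association network model
#'
#' @slot alphas non-negative per-source network weights after the
#'   negativity/fallback rules.
#' @slot alpha0 fitted bias weight (reported, not used when combining).
#' @slot fallbackUsed TRUE when all fitted weights were non-positive and the
#'   uniform 1/m fallback overwrote them.
#' @slot f function scores from label propagation on the composite network.
#' @slot trainIdx labelled node indices.
#' @exportClass CompositeNetworkModel
setClass("CompositeNetworkModel", contains = "IntegrationModel",
  slots = c(alphas = "numeric", alpha0 = "numeric", fallbackUsed = "logical",
            f = "numeric", trainIdx = "integer"))

#' Fitted posterior-odds Bayesian network classifier
#'
#' @slot filtered per-source list of selected feature IDs.
#' @slot directions per-source sign of the class-mean difference for each
#'   selected feature.
#' @slot centers,scales per-source training mean/sd used to standardize.
#' @slot binEdges per-source training quartile cut points.
#' @slot edges two-column matrix of dependence edges among source scores.
#' @slot cpts fitted conditional probability tables per connected component.
#' @slot priorOdds training-count ratio p(y=1)/p(y=-1).
#' @slot pseudocount Laplace pseudocount used in every CPT cell.
#' @exportClass BayesNetModel
setClass("BayesNetModel", contains = "IntegrationModel",
  slots = c(filtered = "list", directions = "list", centers = "list",
            scales = "list", binEdges = "list", edges = "matrix",
            cpts = "list", priorOdds = "numeric", pseudocount = "numeric",
            nBins = "integer"))

#' Fitted multiple-kernel SDP-SVM
#'
#' @slot mu normalized kernel weights (sum to one as reported).
#' @slot lambda raw trace-budget weights; trace(sum lambda_i/r_i K_i) = c.
#' @slot alpha dual vector over training samples.
#' @slot b bias term.
#' @slot C box constraint.
#' @slot cTrace trace budget (training-set size by default).
#' @slot yTrain training labels.
#' @slot objective attained QCQP objective 2 a'e - c t.
#' @exportClass SdpSvmModel
setClass("SdpSvmModel", contains = "IntegrationModel",
  slots = c(mu = "numeric", lambda = "numeric", alpha = "numeric",
            b = "numeric", C = "numeric", cTrace = "numeric",
            yTrain = "numeric", objective = "numeric"))

#' Fitted relevance vector machine (classification)
#'
#' @slot relevanceIdx indices of training samples retained as relevance
#'   vectors.
#' @slot weights coefficients over the relevance vectors.
#' @slot iterations outer hyperparameter updates performed.
#' @slot converged TRUE when the precision updates stabilized.
#' @exportClass RVMModel
setClass("RVMModel", contains = "IntegrationModel",
  slots = c(relevanceIdx = "integer", weights = "numeric",
            iterations = "integer", converged = "logical"))

#' Boosted RVM ensemble
#'
#' @slot learners list of fitted RVMModel weak learners.
#' @slot alphas learner weights alpha_t = 0.5 log((1-eps_t)/eps_t).
#' @slot learnerIdx list of training-subsample indices per stored learner.
#' @slot skipped number of iterations skipped because eps_t >= 0.5.
#' @slot fallback TRUE when all iterations were skipped and a single RVM on
#'   the full training set was used instead.
#' @exportClass BoostedRVMModel
setClass("BoostedRVMModel", contains = "IntegrationModel",
  slots = c(learners = "list", alphas = "numeric", learnerIdx = "list",
            skipped = "integer", fallback = "logical"))

# --- show methods ---------------------------------------------------------

setMethod("show", "MultiOmicsStudy", function(object) {
  cat(sprintf("MultiOmicsStudy: %d samples, %d source(s)\n",
              length(object@labels), length(object@sources)))
  for (nm in names(object@sources))
    cat(sprintf("  %s: %d features\n", nm, ncol(object@sources[[nm]])))
  tab <- table(factor(object@labels, levels = c(-1, 0, 1)))
  cat(sprintf("  labels: %d neg, %d unlabelled, %d pos\n",
              tab[["-1"]], tab[["0"]], tab[["1"]]))
  if (length(object@clusters))
    cat(sprintf("  clusters: %d\n", length(unique(object@clusters))))
})

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult: %d samples, score kind '%s'\n",
              length(object@predicted), object@scoreKind))
  cat(sprintf("  predicted +1: %d, -1: %d\n",
              sum(object@predicted == 1), sum(object@predicted == -1)))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport over %d runs\n", object@nRuns))
  print(object@metrics, digits = 3)
  if (any(object@failures > 0))
    cat("  excluded runs:",
        paste(names(object@failures)[object@failures > 0],
              object@failures[object@failures > 0], collapse = ", "), "\n")
})

setMethod("show", "SdpSvmModel", function(object) {
  cat(sprintf("SdpSvmModel: %d kernels, C = %g, trace budget = %g\n",
              length(object@mu), object@C, object@cTrace))
  cat("  kernel weights mu:", paste(signif(object@mu, 4), collapse = " "),
      "\n")
  cat(sprintf("  support vectors: %d\n", sum(object@alpha > 1e-8)))
})

setMethod("show", "RVMModel", function(object) {
  cat(sprintf("RVMModel: %d relevance vectors, %d iterations (%s)\n",
              length(object@relevanceIdx), object@iterations,
              if (object@converged) "converged" else "not converged"))
})

setMethod("show", "BoostedRVMModel", function(object) {
  cat(sprintf("BoostedRVMModel: %d learners (%d skipped)%s\n",
              length(object@learners), object@skipped,
              if (object@fallback) ", fallback single RVM" else ""))
})

setMethod("show", "GraphSSLModel", function(object) {
  cat(sprintf("GraphSSLModel: %d nodes, c = %g\n",
              length(object@f), object@c))
  if (length(object@alphas))
    cat("  network weights:", paste(signif(object@alphas, 4),
                                    collapse = " "), "\n")
})

setMethod("show", "CompositeNetworkModel", function(object) {
  cat(sprintf("CompositeNetworkModel: %d source(s)%s\n",
              length(object@alphas),
              if (object@fallbackUsed) " (uniform fallback)" else ""))
  cat("  alpha:", paste(signif(object@alphas, 4), collapse = " "), "\n")
})

# --- accessors ------------------------------------------------------------

#' Accessors for MultiOmicsStudy
#'
#' @param x a \code{MultiOmicsStudy}.
#' @return \code{studySources} the list of per-source matrices;
#'   \code{studyLabels} the named label vector; \code{studyClusters} the
#'   cluster IDs (zero-length when absent); \code{sampleIds} the sample IDs;
#'   \code{nSamples}/\code{nSources} the corresponding counts.
#' @name study-accessors
#' @aliases studySources studyLabels studyClusters sampleIds nSamples
#'   nSources
#' @export
studySources <- function(x) x@sources

#' @rdname study-accessors
#' @export
studyLabels <- function(x) x@labels

#' @rdname study-accessors
#' @export
studyClusters <- function(x) x@clusters

#' @rdname study-accessors
#' @export
sampleIds <- function(x) names(x@labels)

#' @rdname study-accessors
#' @export
nSamples <- function(x) length(x@labels)

#' @rdname study-accessors
#' @export
nSources <- function(x) length(x@sources)

#' Accessors for PredictionResult
#'
#' @param x a \code{PredictionResult}.
#' @name prediction-accessors
#' @aliases predictedLabels predictionScores scoreKind
#' @export
predictedLabels <- function(x) x@predicted

#' @rdname prediction-accessors
#' @export
predictionScores <- function(x) x@scores

#' @rdname prediction-accessors
#' @export
scoreKind <- function(x) x@scoreKind

#' Construct a PredictionResult
#'
#' @param predicted numeric vector in \{-1, +1\}.
#' @param scores numeric score vector of equal length.
#' @param scoreKind score interpretation; one of \code{"function_score"},
#'   \code{"decision_value"}, \code{"probability"}, \code{"odds"}.
#' @param sampleIds optional sample IDs.
#' @return a \code{PredictionResult}.
#' @export
PredictionResult <- function(predicted, scores, scoreKind,
                             sampleIds = character()) {
  new("PredictionResult", predicted = as.numeric(predicted),
      scores = as.numeric(scores), scoreKind = scoreKind,
      sampleIds = as.character(sampleIds))
}
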