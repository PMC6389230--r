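# Shared preprocessing: standardize every source with training-row
# statistics only (leakage-free), applied to all rows.
standardizeByTrain <- function(study, trainIdx) {
  lapply(studySources(study), function(X) {
    ctr <- colMeans(X[trainIdx, , drop = FALSE])
    scl <- apply(X[trainIdx, , drop = FALSE], 2L, sd)
    keep <- is.finite(scl) & scl > .Machine$double.eps
    sweep(sweep(X[, keep, drop = FALSE], 2L, ctr[keep]), 2L, scl[keep], `/`)
  })
}

defaultParams <- function(params = list()) {
  defaults <- list(c = 1, corMethod = "pearson", sigma = "median",
                   C = 1, bayesVariant = "simple", nBins = 4L,
                   pseudocount = 1, edgeThreshold = 0.3,
                   mixedSign = "paper", resampleFraction = 0.4,
                   maxIter = 5L, cvK = 5L, cvRepeats = 2L, seed = 1L)
  defaults[names(params)] <- params
  defaults
}

# per-source RBF train/test kernel pairs
sourceKernels <- function(Zs, trainIdx, testIdx, params) {
  lapply(Zs, function(Z) {
    Xtr <- Z[trainIdx, , drop = FALSE]
    sg <- params$sigma
    if (identical(sg, "median")) sg <- sigmaHeuristic(Xtr)
    list(Ktr = rbfKernel(Xtr, sg),
         Kte = rbfKernel(Xtr, sg, Y = Z[testIdx, , drop = FALSE]))
  })
}

# graph-method weight matrices over all nodes (transductive)
sourceWeights <- function(Zs, params)
  lapply(Zs, correlationWeights, method = params$corMethod)

resolveC <- function(study, trainIdx, method, params) {
  if (!identical(params$c, "auto")) return(params$c)
  sub <- subsetStudy(study, trainIdx)
  tuneC(sub, method, k = params$cvK, repeats = params$cvRepeats,
        seed = params$seed, corMethod = params$corMethod)
}

subsetStudy <- function(study, idx) {
  y <- studyLabels(study)[idx]
  src <- lapply(studySources(study), function(X) X[idx, , drop = FALSE])
  cl <- studyClusters(study)
  MultiOmicsStudy(src, y, if (length(cl))
    setNames(cl[idx], names(y)) else NULL)
}

integratorGSSL <- function(study, trainIdx, testIdx, params) {
  yb <- blindLabels(studyLabels(study), testIdx)
  cVal <- resolveC(study, trainIdx, "gssl", params)
  Ws <- sourceWeights(standardizeByTrain(study, trainIdx), params)
  fit <- gsslSolveMulti(lapply(Ws, laplacianMatrix), yb, cVal)
  medianCutoff(fit@f, yb, testIdx, sampleIds(study)[testIdx])
}

integratorSharpening <- function(study, trainIdx, testIdx, params) {
  yb <- blindLabels(studyLabels(study), testIdx)
  cVal <- resolveC(study, trainIdx, "sharpening", params)
  Ws <- sourceWeights(standardizeByTrain(study, trainIdx), params)
  Ls <- lapply(Ws, function(W) laplacianMatrix(sharpenWeights(W, yb)))
  fit <- sharpenedSolveMulti(Ls, yb, cVal)
  medianCutoff(fit@f, yb, testIdx, sampleIds(study)[testIdx])
}

integratorComposite <- function(study, trainIdx, testIdx, params) {
  yb <- blindLabels(studyLabels(study), testIdx)
  Ws <- sourceWeights(standardizeByTrain(study, trainIdx), params)
  fit <- fitCompositeNetwork(Ws, yb, c = 1, mixedSign = params$mixedSign)
  pred <- medianCutoff(fit@f, yb, testIdx, sampleIds(study)[testIdx])
  attr(pred, "alphas") <- fit@alphas
  pred
}

integratorBayes <- function(study, trainIdx, testIdx, params) {
  model <- fitBayesNet(study, trainIdx, params$bayesVariant,
                       params$nBins, params$pseudocount,
                       params$edgeThreshold)
  pred <- predictBayesNet(model, study, testIdx)
  pred@sampleIds <- sampleIds(study)[testIdx]
  pred
}

integratorSdpSvm <- function(study, trainIdx, testIdx, params) {
  Zs <- standardizeByTrain(study, trainIdx)
  y <- studyLabels(study)[trainIdx]
  ks <- sourceKernels(Zs, trainIdx, testIdx, params)
  Ktrs <- lapply(ks, `[[`, "Ktr")
  C <- if (identical(params$C, "auto"))
    tuneSvmC(Ktrs, y, seed = params$seed) else params$C
  model <- fitSdpSvm(Ktrs, y, C = C)
  pred <- predictSdpSvm(model, lapply(ks, `[[`, "Kte"),
                        sampleIds(study)[testIdx])
  attr(pred, "mu") <- model@mu
  pred
}

integratorRvm <- function(study, trainIdx, testIdx, params) {
  Zs <- standardizeByTrain(study, trainIdx)
  y <- studyLabels(study)[trainIdx]
  ks <- sourceKernels(Zs, trainIdx, testIdx, params)
  Ps <- lapply(ks, function(kk) {
    model <- rvmFit(kk$Ktr, y)
    rvmPredictProb(model, kk$Kte)
  })
  integrateProbabilities(Ps, sampleIds(study)[testIdx])
}

integratorAdaboostRvm <- function(study, trainIdx, testIdx, params) {
  Zs <- standardizeByTrain(study, trainIdx)
  y <- studyLabels(study)[trainIdx]
  ks <- sourceKernels(Zs, trainIdx, testIdx, params)
  Ps <- lapply(ks, function(kk) {
    fr <- params$resampleFraction; it <- params$maxIter
    if (identical(fr, "auto") || identical(it, "auto")) {
      tuned <- tuneBoost(kk$Ktr, y, seed = params$seed)
      fr <- tuned$resampleFraction; it <- tuned$maxIter
    }
    model <- adaboostRvm(kk$Ktr, y, fr, it, seed = params$seed)
    sigmoid(boostedScore(model, kk$Kte))
  })
  integrateProbabilities(Ps, sampleIds(study)[testIdx])
}

#' The seven integration algorithms
#'
#' @return named list of integrator functions, each with signature
#'   \code{function(study, trainIdx, testIdx, params)} returning a
#'   \code{PredictionResult} for the test samples. Names:
#'   \code{gssl} (multi-network graph semi-supervised learning),
#'   \code{sharpening} (graph sharpening integration),
#'   \code{composite} (composite association network),
#'   \code{bayes} (posterior-odds Bayesian network),
#'   \code{sdpsvm} (multiple-kernel SDP-SVM),
#'   \code{rvm} (per-source RVMs with probability averaging),
#'   \code{adaboost} (Ada-boost RVM ensembles per source).
#' @export
integrationAlgorithms <- function() {
  list(gssl = integratorGSSL, sharpening = integratorSharpening,
       composite = integratorComposite, bayes = integratorBayes,
       sdpsvm = integratorSdpSvm, rvm = integratorRvm,
       adaboost = integratorAdaboostRvm)
}

resolveAlgorithms <- function(algorithms) {
  registry <- integrationAlgorithms()
  if (is.character(algorithms)) {
    bad <- setdiff(algorithms, names(registry))
    if (length(bad))
      stop("unknown algorithm(s): ", paste(bad, collapse = ", "),
           "; valid names: ", paste(names(registry), collapse = ", "))
    registry[algorithms]
  } else {
    stopifnot(is.list(algorithms), !is.null(names(algorithms)))
    algorithms
  }
}
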