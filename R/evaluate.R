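# collect one run's metrics for every algorithm into a data.frame row set
runAlgorithms <- function(study, algorithms, trainIdx, testIdx, params,
                          run, truth) {
  # the driver blinds the test labels before any integrator sees the study
  blinded <- study
  blinded@labels <- blindLabels(studyLabels(study), testIdx)
  out <- list()
  for (nm in names(algorithms)) {
    res <- tryCatch(
      algorithms[[nm]](blinded, trainIdx, testIdx, params),
      error = function(e) e)
    if (inherits(res, "error")) {
      out[[nm]] <- data.frame(run = run, algorithm = nm, accuracy = NA,
                              f1 = NA, auc = NA, sensitivity = NA,
                              specificity = NA, failed = TRUE)
      next
    }
    cm <- confusionMetrics(res, truth)
    auc <- tryCatch(aucScore(predictionScores(res), truth),
                    error = function(e) NA_real_)
    out[[nm]] <- data.frame(run = run, algorithm = nm,
                            accuracy = cm$accuracy, f1 = cm$f1, auc = auc,
                            sensitivity = cm$sensitivity,
                            specificity = cm$specificity, failed = FALSE)
  }
  do.call(rbind, out)
}

buildReport <- function(perRun, nRuns, seed) {
  perRun <- perRun[order(perRun$run), ]
  failures <- tapply(perRun$failed, perRun$algorithm, sum)
  ok <- perRun[!perRun$failed, ]
  rows <- list()
  for (nm in unique(ok$algorithm)) for (metric in c("accuracy", "f1", "auc")) {
    vals <- ok[ok$algorithm == nm, metric]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) next
    ci <- percentileBootstrapCI(vals, seed = seed)
    rows[[paste(nm, metric)]] <- data.frame(
      algorithm = nm, metric = metric, mean = mean(vals),
      lower = ci[1L], upper = ci[2L])
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else
    data.frame(algorithm = character(), metric = character(),
               mean = numeric(), lower = numeric(), upper = numeric())
  rownames(metrics) <- NULL
  new("EvaluationReport", metrics = metrics, perRun = perRun,
      nRuns = as.integer(nRuns),
      failures = setNames(as.integer(failures), names(failures)))
}

#' Repeated stratified hold-out evaluation
#'
#' Per run: a stratified 75/25 (by default) train/test split is drawn, the
#' test labels are blinded to 0 before any algorithm sees the study
#' (transductive graph methods thus see the test nodes but never their
#' labels; kernel methods fit on training rows only), each algorithm fits
#' and predicts, and accuracy, F1 and AUC are recorded. Means over runs are
#' reported with percentile-bootstrap 95\% confidence intervals (2000
#' resamples of the per-run values). Failed runs are excluded per algorithm
#' with a count in the report.
#'
#' @param study a fully labelled \code{MultiOmicsStudy}.
#' @param algorithms character vector of registry names (see
#'   \code{\link{integrationAlgorithms}}) or a named list of integrator
#'   functions.
#' @param nRuns number of repetitions (200 in the reference protocol).
#' @param trainFrac training fraction (default 0.75).
#' @param seed RNG seed governing all splits.
#' @param params named list overriding \code{defaultParams} entries
#'   (c, sigma, C, bayesVariant, resampleFraction, maxIter, ...).
#' @return an \code{EvaluationReport}.
#' @export
repeatedHoldout <- function(study, algorithms, nRuns = 200L,
                            trainFrac = 0.75, seed = 1L, params = list()) {
  y <- studyLabels(study)
  stopifnot(all(y %in% c(-1, 1)))
  algorithms <- resolveAlgorithms(algorithms)
  params <- defaultParams(params)
  set.seed(seed)
  splitSeeds <- sample.int(.Machine$integer.max, nRuns)
  perRun <- list()
  for (run in seq_len(nRuns)) {
    set.seed(splitSeeds[run])
    testIdx <- sort(unlist(lapply(c(-1, 1), function(cls) {
      idx <- which(y == cls)
      sample(idx, max(1L, round((1 - trainFrac) * length(idx))))
    })))
    trainIdx <- setdiff(seq_along(y), testIdx)
    perRun[[run]] <- runAlgorithms(study, algorithms, trainIdx, testIdx,
                                   params, run, y[testIdx])
  }
  buildReport(do.call(rbind, perRun), nRuns, seed)
}

#' Leave-cluster-out cross-validation
#'
#' Per run, \code{nTrainClusters} clusters are sampled without replacement
#' as the training set and the remaining clusters form the test set; no
#' sample's cluster ever straddles the split. Runs whose test set lacks a
#' class are redrawn (up to 100 retries).
#'
#' @param study a \code{MultiOmicsStudy} with cluster IDs.
#' @param algorithms as in \code{\link{repeatedHoldout}}.
#' @param nTrainClusters clusters assigned to training (e.g. 12 of 17).
#' @param nRuns repetitions.
#' @param seed RNG seed.
#' @param params as in \code{\link{repeatedHoldout}}.
#' @return an \code{EvaluationReport}.
#' @export
leaveClusterOut <- function(study, algorithms, nTrainClusters,
                            nRuns = 200L, seed = 1L, params = list()) {
  cl <- studyClusters(study)
  if (!length(cl)) stop("study has no cluster assignments")
  clusters <- unique(cl)
  stopifnot(nTrainClusters >= 1L, nTrainClusters < length(clusters))
  y <- studyLabels(study)
  algorithms <- resolveAlgorithms(algorithms)
  params <- defaultParams(params)
  set.seed(seed)
  splitSeeds <- sample.int(.Machine$integer.max, nRuns)
  perRun <- list()
  for (run in seq_len(nRuns)) {
    set.seed(splitSeeds[run])
    for (try in 1:100) {
      trainCl <- sample(clusters, nTrainClusters)
      testIdx <- which(!cl %in% trainCl)
      if (any(y[testIdx] == 1) && any(y[testIdx] == -1) &&
          any(y[-testIdx] == 1) && any(y[-testIdx] == -1)) break
      if (try == 100L) stop("could not draw a split with both classes")
    }
    trainIdx <- setdiff(seq_along(y), testIdx)
    perRun[[run]] <- runAlgorithms(study, algorithms, trainIdx, testIdx,
                                   params, run, y[testIdx])
  }
  buildReport(do.call(rbind, perRun), nRuns, seed)
}

#' Write an EvaluationReport to disk
#'
#' Writes \code{report.json} (metrics, failures, run count) and
#' \code{report.tsv} (algorithm x metric table of mean and 95\% limits).
#'
#' @param report an \code{EvaluationReport}.
#' @param dir output directory.
#' @return invisibly, the file paths.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonPath <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(n_runs = report@nRuns, metrics = report@metrics,
         failures = as.list(report@failures)),
    jsonPath, auto_unbox = TRUE, digits = NA)
  tsvPath <- file.path(dir, "report.tsv")
  write.table(report@metrics, tsvPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(jsonPath, tsvPath))
}
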