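#' Confusion counts and derived classification metrics
#'
#' accuracy = (tp + tn)/(tp + fp + tn + fn), F1 = 2tp/(2tp + fp + fn),
#' sensitivity = tp/P, specificity = tn/N.
#'
#' @param pred a \code{PredictionResult} or numeric vector in \{-1, +1\}.
#' @param truth numeric truth vector in \{-1, +1\} (no zeros).
#' @return list with \code{counts} (tp, fp, fn, tn), \code{accuracy},
#'   \code{f1}, \code{sensitivity}, \code{specificity}.
#' @export
confusionMetrics <- function(pred, truth) {
  if (is(pred, "PredictionResult")) pred <- predictedLabels(pred)
  stopifnot(length(pred) == length(truth), all(truth %in% c(-1, 1)))
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == -1)
  fn <- sum(pred == -1 & truth == 1)
  tn <- sum(pred == -1 & truth == -1)
  P <- tp + fn; N <- tn + fp
  list(counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
       accuracy = (tp + tn) / (tp + fp + tn + fn),
       f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn),
       sensitivity = if (P == 0) NA_real_ else tp / P,
       specificity = if (N == 0) NA_real_ else tn / N)
}

#' Area under the ROC curve (rank estimator)
#'
#' Equals (concordant pairs + 0.5 * tied pairs) / (P * N): the probability
#' that a random positive scores above a random negative, with ties
#' counted half. 1 is perfect separation, 0.5 is chance.
#'
#' @param scores numeric scores; higher means more positive.
#' @param truth numeric truth vector in \{-1, +1\}, both classes present.
#' @return the AUC.
#' @export
aucScore <- function(scores, truth) {
  stopifnot(length(scores) == length(truth), all(truth %in% c(-1, 1)))
  P <- sum(truth == 1); N <- sum(truth == -1)
  if (P == 0 || N == 0) stop("AUC undefined with a single class")
  r <- rank(scores)                       # mid-ranks handle ties
  (sum(r[truth == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Percentile-bootstrap confidence interval for a mean
#'
#' Resamples the values with replacement, takes the mean of each resample,
#' and returns the outer percentiles of the bootstrap distribution.
#'
#' @param values numeric vector (e.g. 200 per-run accuracies).
#' @param level confidence level (default 0.95).
#' @param nBoot bootstrap draws (default 2000).
#' @param seed RNG seed.
#' @return numeric \code{c(lower, upper)}.
#' @export
percentileBootstrapCI <- function(values, level = 0.95, nBoot = 2000L,
                                  seed = 1L) {
  stopifnot(length(values) >= 1L)
  set.seed(seed)
  n <- length(values)
  means <- vapply(seq_len(nBoot),
                  function(b) mean(values[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  unname(quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2), type = 7))
}
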