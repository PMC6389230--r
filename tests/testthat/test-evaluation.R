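test_that("confusion metrics match the printed formulas", {
  pred <- c(rep(1, 4), rep(-1, 6))
  truth <- c(1, 1, 1, -1, 1, 1, -1, -1, -1, -1)
  cm <- confusionMetrics(pred, truth)
  expect_equal(unname(cm$counts), c(3, 1, 2, 4))
  expect_equal(cm$accuracy, 0.7)
  expect_equal(cm$f1, 6 / 9)
  expect_equal(cm$sensitivity, 3 / 5)
  expect_equal(cm$specificity, 4 / 5)

  perfect <- confusionMetrics(truth, truth)
  expect_equal(c(perfect$accuracy, perfect$f1, perfect$sensitivity,
                 perfect$specificity), rep(1, 4))

  allNeg <- confusionMetrics(rep(-1, 10), truth)
  expect_equal(allNeg$f1, 0)
  expect_equal(allNeg$specificity, 1)
})

test_that("accuracy decomposes into sensitivity and specificity", {
  set.seed(101)
  for (rep in 1:10) {
    truth <- sample(c(1, -1), 30, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(truth)) < 2) next
    pred <- sample(c(1, -1), 30, replace = TRUE)
    cm <- confusionMetrics(pred, truth)
    P <- sum(truth == 1); N <- sum(truth == -1)
    expect_equal(cm$accuracy,
                 (cm$sensitivity * P + cm$specificity * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("AUC equals the pair-counting oracle and flips under negation", {
  truth <- c(1, 1, 1, -1, -1, -1)
  expect_equal(aucScore(c(5, 4, 3, 2, 1, 0), truth), 1)
  expect_equal(aucScore(rep(2, 6), truth), 0.5)

  scores <- c(3, 2, 2, 1, 4, 0)   # one tie across classes
  bruteAuc <- function(s, t) {
    pos <- s[t == 1]; neg <- s[t == -1]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  expect_equal(aucScore(scores, truth), bruteAuc(scores, truth))

  set.seed(103)
  for (rep in 1:20) {
    s <- round(rnorm(12), 1)
    t <- sample(c(1, -1), 12, replace = TRUE)
    if (length(unique(t)) < 2) next
    expect_equal(aucScore(s, t), bruteAuc(s, t), tolerance = 1e-12)
    expect_equal(aucScore(s, t), 1 - aucScore(-s, t), tolerance = 1e-12)
  }
  expect_error(aucScore(1:3, rep(1, 3)), "single class")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(107)
  s <- rnorm(50)
  t <- sample(c(1, -1), 50, replace = TRUE)
  expect_equal(aucScore(s, t),
               as.numeric(pROC::auc(pROC::roc(t, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("percentile bootstrap CI behaves at the edges and under CLT", {
  expect_equal(percentileBootstrapCI(rep(0.8, 20)), c(0.8, 0.8))
  set.seed(109)
  x <- rnorm(40)
  ci <- percentileBootstrapCI(x, seed = 2)
  expect_lte(ci[1], mean(x))
  expect_gte(ci[2], mean(x))
  # width close to the normal-theory interval at n = 200
  x2 <- rnorm(200)
  ci2 <- percentileBootstrapCI(x2, seed = 3)
  expected <- 2 * 1.96 * sd(x2) / sqrt(200)
  expect_lt(abs((ci2[2] - ci2[1]) - expected) / expected, 0.25)
})

test_that("repeated hold-out aggregates stub algorithms exactly", {
  st <- makeTestStudy(n = 40, seed = 113)
  always1 <- function(study, trainIdx, testIdx, params)
    PredictionResult(rep(1, length(testIdx)), rep(1, length(testIdx)),
                     "decision_value")
  rep2 <- repeatedHoldout(st, list(pos = always1), nRuns = 2, seed = 5)
  perRun <- rep2@perRun
  m <- rep2@metrics
  expect_equal(m$mean[m$metric == "accuracy"], mean(perRun$accuracy))
  # constant metric: degenerate CI
  expect_equal(m$lower[m$metric == "accuracy"],
               m$upper[m$metric == "accuracy"])
})

test_that("a coin-flip stub lands near one half over 200 runs", {
  st <- makeTestStudy(n = 40, seed = 127)
  coin <- function(study, trainIdx, testIdx, params) {
    lab <- sample(c(1, -1), length(testIdx), replace = TRUE)
    PredictionResult(lab, lab, "decision_value")
  }
  repc <- repeatedHoldout(st, list(coin = coin), nRuns = 200, seed = 7)
  acc <- repc@metrics$mean[repc@metrics$metric == "accuracy"]
  expect_gt(acc, 0.44)
  expect_lt(acc, 0.56)
})

test_that("failing algorithms are excluded with a count", {
  st <- makeTestStudy(n = 30, seed = 131)
  boom <- function(study, trainIdx, testIdx, params) stop("nope")
  repf <- repeatedHoldout(st, list(boom = boom), nRuns = 3, seed = 9)
  expect_equal(unname(repf@failures["boom"]), 3L)
})

test_that("hold-out split is stratified at 75/25", {
  st <- makeTestStudy(n = 40, seed = 137)
  sizes <- new.env(); sizes$n <- integer()
  probe <- function(study, trainIdx, testIdx, params) {
    yb <- studyLabels(study)
    stopifnot(all(yb[testIdx] == 0))
    sizes$n <- c(sizes$n, length(testIdx))
    PredictionResult(rep(1, length(testIdx)), rep(1, length(testIdx)),
                     "decision_value")
  }
  invisible(repeatedHoldout(st, list(p = probe), nRuns = 4, seed = 11))
  expect_true(all(sizes$n == 10))   # 25% of 40, stratified 5 + 5
})

test_that("leave-cluster-out always tests whole held-out clusters", {
  st <- makeTestStudy(n = 85, seed = 139, nClusters = 17)
  cl <- studyClusters(st)
  seen <- new.env(); seen$ok <- TRUE
  probe <- function(study, trainIdx, testIdx, params) {
    testCl <- unique(cl[testIdx])
    trainCl <- unique(cl[trainIdx])
    if (length(testCl) != 5 || length(intersect(testCl, trainCl)) > 0 ||
        length(intersect(trainIdx, testIdx)) > 0)
      seen$ok <- FALSE
    PredictionResult(rep(1, length(testIdx)), rep(1, length(testIdx)),
                     "decision_value")
  }
  invisible(leaveClusterOut(st, list(p = probe), nTrainClusters = 12,
                            nRuns = 5, seed = 13))
  expect_true(seen$ok)

  # two clusters, train one: the partition is exactly cluster-wise
  st2 <- makeTestStudy(n = 30, seed = 149, nClusters = 2)
  cl2 <- studyClusters(st2)
  probe2 <- function(study, trainIdx, testIdx, params) {
    stopifnot(length(unique(cl2[testIdx])) == 1,
              length(unique(cl2[trainIdx])) == 1)
    PredictionResult(rep(1, length(testIdx)), rep(1, length(testIdx)),
                     "decision_value")
  }
  expect_s4_class(leaveClusterOut(st2, list(p = probe2), 1, nRuns = 3,
                                  seed = 17), "EvaluationReport")
})

test_that("no integrator reads blinded test labels", {
  st <- makeTestStudy(n = 40, seed = 151)
  y <- studyLabels(st)
  tr <- 1:30; te <- 31:40
  params <- gkintegrate:::defaultParams(list())
  blind <- st; blind@labels <- gkintegrate:::blindLabels(y, te)
  poisoned <- st
  poisoned@labels[te] <- -y[te]           # wrong labels, then blinded
  poisonedBlind <- poisoned
  poisonedBlind@labels <- gkintegrate:::blindLabels(poisoned@labels, te)
  for (nm in names(integrationAlgorithms())) {
    fun <- integrationAlgorithms()[[nm]]
    p1 <- fun(blind, tr, te, params)
    p2 <- fun(poisonedBlind, tr, te, params)
    expect_identical(predictionScores(p1), predictionScores(p2),
                     info = nm)
  }
})
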