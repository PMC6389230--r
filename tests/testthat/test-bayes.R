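test_that("feature filtering keeps signal and respects Bonferroni", {
  set.seed(19)
  n <- 100
  y <- rep(c(1, -1), each = 50)
  # one 3-sd feature among noise
  X <- cbind(sig = rnorm(n) + 1.5 * y, matrix(rnorm(n * 9), n, 10 - 1))
  colnames(X) <- c("sig", paste0("n", 1:9))
  sel <- filterFeatures(X, y)
  expect_true("sig" %in% sel$ids)
  expect_equal(unname(sel$directions["sig"]), 1)

  # a feature identical in both classes is never selected on its own merit
  Xsame <- cbind(flat = rep(c(1, 2), n / 2), X)
  sel2 <- filterFeatures(Xsame, y)
  expect_false("flat" %in% setdiff(sel2$ids, "sig"))
})

test_that("pure-noise filtering usually falls back to a single feature", {
  fewSelected <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    y <- rep(c(1, -1), each = 30)
    X <- matrix(rnorm(60 * 1000), 60, 1000,
                dimnames = list(NULL, paste0("f", 1:1000)))
    sel <- filterFeatures(X, y)
    if (length(sel$ids) <= 2L) fewSelected <- fewSelected + 1L
  }
  expect_gte(fewSelected, 9L)
})

test_that("scores, quartile edges, and binning follow the conventions", {
  # single selected feature with direction +1: score is its z-value
  X <- cbind(f1 = c(1, 2, 3, 4))
  ctr <- c(f1 = 2.5); scl <- c(f1 = sd(1:4))
  sc <- sourceScore(X, "f1", c(f1 = 1), ctr, scl)
  expect_equal(sc, (c(1, 2, 3, 4) - 2.5) / sd(1:4))

  edges <- quartileEdges(1:8)
  expect_equal(edges, c(2.75, 4.5, 6.25))
  bins <- binScores(1:8, edges)
  expect_equal(as.integer(table(bins)), rep(2L, 4))
  expect_equal(binScores(0.5, edges), 1L)     # below training minimum
  expect_equal(binScores(2.75, edges), 1L)    # boundary goes to lower bin
  expect_warning(quartileEdges(rep(3, 5)), "single bin")
})

test_that("structure rule: duplicates connect, threshold 1.1 never does", {
  set.seed(23)
  y <- rep(c(1, -1), each = 100)
  b1 <- sample(1:4, 200, replace = TRUE)
  b2 <- sample(1:4, 200, replace = TRUE)
  binned <- cbind(b1, b1, b2)
  edges <- buildStructure(binned, y)
  expect_true(any(edges[, 1] == 1 & edges[, 2] == 2))  # r = 1
  expect_identical(nrow(buildStructure(binned, y, threshold = 1.1)), 0L)
  # independent pair rarely passes 0.3 at n = 200
  expect_false(any(edges[, 1] == 1 & edges[, 2] == 3))
})

test_that("posterior odds arithmetic matches the factorized form", {
  # balanced prior, single neutral variable: odds 1 -> label -1
  y <- rep(c(1, -1), each = 20)
  binned <- matrix(rep(1:4, 10), ncol = 1)
  model <- binnedBayes(binned, y)
  pred <- posteriorOdds(model, matrix(2, 1, 1))
  expect_equal(predictionScores(pred), 1)
  expect_equal(predictedLabels(pred), -1)

  # hand-set CPTs: one variable with ratio 4 at balanced prior
  model@cpts$tables[[1]][["1"]] <- c(0.8, 0.1, 0.05, 0.05)
  model@cpts$tables[[1]][["-1"]] <- c(0.2, 0.3, 0.25, 0.25)
  pred2 <- posteriorOdds(model, matrix(1, 1, 1))
  expect_equal(predictionScores(pred2), 4)
  expect_equal(predictedLabels(pred2), 1)

  # two independent variables each with ratio 2, prior odds 0.5
  y2 <- rep(c(1, -1), c(10, 20))
  m2 <- binnedBayes(cbind(rep(1L, 30), rep(1L, 30)), y2, nBins = 2)
  m2@priorOdds <- 0.5
  m2@cpts$tables[[1]][["1"]] <- c(0.8, 0.2)
  m2@cpts$tables[[1]][["-1"]] <- c(0.4, 0.6)
  m2@cpts$tables[[2]][["1"]] <- c(0.8, 0.2)
  m2@cpts$tables[[2]][["-1"]] <- c(0.4, 0.6)
  pred3 <- posteriorOdds(m2, matrix(1L, 1, 2))
  expect_equal(predictionScores(pred3), 0.5 * 2 * 2)
  expect_equal(predictedLabels(pred3), 1)
})

test_that("simple and structured variants coincide with no edges", {
  st <- makeTestStudy(n = 50, seed = 29)
  tr <- 1:40
  simple <- fitBayesNet(st, tr, "simple")
  structured <- fitBayesNet(st, tr, "structured", edgeThreshold = 1.1)
  p1 <- posteriorOdds(simple, matrix(c(2L, 3L), 1, 2))
  p2 <- posteriorOdds(structured, matrix(c(2L, 3L), 1, 2))
  expect_identical(predictionScores(p1), predictionScores(p2))
})

test_that("pseudocount keeps every bin pattern finite", {
  y <- rep(c(1, -1), each = 10)
  binned <- cbind(rep(1L, 20), rep(1L, 20))   # only one observed pattern
  model <- binnedBayes(binned, y, edges = cbind(1L, 2L))
  patterns <- as.matrix(expand.grid(1:4, 1:4))
  odds <- predictionScores(posteriorOdds(model, patterns))
  expect_true(all(is.finite(odds) & odds > 0))
})

test_that("fitted classifier separates a clearly shifted study", {
  st <- makeTestStudy(n = 80, seed = 31, delta = 2)
  tr <- 1:60; te <- 61:80
  model <- fitBayesNet(st, tr)
  pred <- predictBayesNet(model, st, te)
  expect_gt(mean(predictedLabels(pred) == studyLabels(st)[te]), 0.8)
})
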