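test_that("single-network solve: identity cases and the 3-node path", {
  y <- c(1, 0, -1)
  L0 <- matrix(0, 3, 3)
  expect_equal(gsslSolveSingle(L0, y, 0)@f, y)          # c = 0
  expect_equal(gsslSolveSingle(L0, y, 5)@f, y)          # empty graph
  Lpath <- laplacianMatrix(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3))
  expect_equal(gsslSolveSingle(Lpath, y, 1)@f, c(0.5, 0, -0.5))
  expect_error(gsslSolveSingle(Lpath, y, -1), "non-negative")
})

test_that("solver residual is tiny on random instances", {
  set.seed(21)
  for (rep in 1:5) {
    W <- randomWeights(15, seed = rep)
    L <- laplacianMatrix(W)
    y <- sample(c(-1, 0, 1), 15, replace = TRUE)
    cv <- runif(1, 0, 10)
    f <- gsslSolveSingle(L, y, cv)@f
    expect_lt(max(abs((diag(15) + cv * L) %*% f - y)), 1e-8)
  }
})

test_that("median cut-off follows the distance rule with ties to -1", {
  # medians: positives at 0.7, negatives at -0.7
  f <- c(0.7, 0.7, -0.7, -0.7, 0.2, 0)
  y <- c(1, 1, -1, -1, 0, 0)
  pred <- medianCutoff(f, y)
  expect_equal(predictedLabels(pred)[5], 1)   # closer to +median
  expect_equal(predictedLabels(pred)[6], -1)  # equidistant -> -1

  set.seed(33)
  f <- rnorm(10); y <- c(1, 1, 1, -1, -1, -1, 0, 0, 0, 0)
  pred <- medianCutoff(f, y)
  mp <- median(f[y == 1]); mn <- median(f[y == -1])
  brute <- ifelse(abs(f - mp) < abs(f - mn), 1, -1)
  expect_equal(predictedLabels(pred), brute)
  expect_error(medianCutoff(f, rep(1, 10)), "both classes")
})

test_that("multi-network solve reduces correctly in degenerate cases", {
  set.seed(7)
  W <- randomWeights(10, seed = 2)
  L <- laplacianMatrix(W)
  y <- c(1, -1, 1, -1, 1, 0, 0, 0, 0, 0)

  # m = 1: budget is exhausted (objective non-increasing in alpha)
  fit <- gsslSolveMulti(list(L), y, c = 2)
  expect_equal(sum(fit@alphas), 2, tolerance = 1e-6)
  # 1-D scan oracle: no grid point beats the returned alpha
  grid <- seq(0, 2, length.out = 21)
  objs <- vapply(grid, function(a) gkintegrate:::gsslObjective(a, list(L), y),
                 numeric(1))
  expect_lte(gkintegrate:::gsslObjective(fit@alphas, list(L), y),
             min(objs) + 1e-8)

  # two identical Laplacians: f equals the m=1 solution at the same budget
  fit2 <- gsslSolveMulti(list(L, L), y, c = 2)
  expect_equal(fit2@f, fit@f, tolerance = 1e-6)

  # informative network plus an empty one: f matches the single solve
  fit3 <- gsslSolveMulti(list(L, matrix(0, 10, 10)), y, c = 2)
  f3single <- gsslSolveSingle(L, y, fit3@alphas[1])@f
  expect_equal(fit3@f, f3single, tolerance = 1e-8)
})

test_that("optimizer beats a coarse simplex grid (m = 2 and 3)", {
  set.seed(12)
  y <- sample(c(1, -1, 0), 12, replace = TRUE)
  y[1:2] <- c(1, -1)
  for (m in 2:3) {
    Ls <- lapply(1:m, function(k) laplacianMatrix(randomWeights(12, k + 30)))
    cBudget <- 3
    fit <- gsslSolveMulti(Ls, y, cBudget)
    objFit <- gkintegrate:::gsslObjective(fit@alphas, Ls, y)
    steps <- seq(0, cBudget, by = cBudget / 10)
    pts <- expand.grid(rep(list(steps), m))
    pts <- pts[rowSums(pts) <= cBudget + 1e-9, , drop = FALSE]
    objs <- apply(pts, 1, function(a)
      gkintegrate:::gsslObjective(as.numeric(a), Ls, y))
    expect_lte(objFit, min(objs) + 1e-7)
  }
})

test_that("multi-network f equals the single solve on the composite", {
  set.seed(5)
  Ls <- lapply(1:2, function(k) laplacianMatrix(randomWeights(9, k)))
  y <- c(1, -1, 1, 0, 0, 0, -1, 0, 1)
  fit <- gsslSolveMulti(Ls, y, 1.5)
  Lcomp <- fit@alphas[1] * Ls[[1]] + fit@alphas[2] * Ls[[2]]
  expect_equal(fit@f, gsslSolveSingle(Lcomp, y, 1)@f, tolerance = 1e-10)
})

test_that("c tuning honors the grid, tie rule, and seed determinism", {
  st <- makeTestStudy(n = 40, seed = 13)
  # degenerate one-value grid
  expect_equal(tuneC(st, "gssl", grid = 0.5, k = 3, repeats = 1), 0.5)
  # duplicated value: the first (smaller index) wins any tie
  expect_equal(tuneC(st, "gssl", grid = c(0.25, 0.25), k = 3, repeats = 1),
               0.25)
  c1 <- tuneC(st, "gssl", grid = c(0.1, 1, 10), k = 3, repeats = 2, seed = 6)
  c2 <- tuneC(st, "gssl", grid = c(0.1, 1, 10), k = 3, repeats = 2, seed = 6)
  expect_identical(c1, c2)
})
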