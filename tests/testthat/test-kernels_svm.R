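test_that("kernels match their closed forms", {
  set.seed(41)
  X <- matrix(rnorm(10 * 5), 10, 5)
  K <- rbfKernel(X, sigma = 1)
  expect_equal(unname(diag(K)), rep(1, 10))
  for (i in 1:10) for (j in 1:10) {
    d2 <- sum((X[i, ] - X[j, ])^2)
    expect_lt(abs(K[i, j] - exp(-d2)), 1e-12)
  }
  # sigma = 1, unit distance
  X2 <- rbind(c(0, 0), c(1, 0))
  expect_equal(rbfKernel(X2, 1)[1, 2], exp(-1))
  expect_error(rbfKernel(X2, 0), "positive")
  expect_equal(linearKernel(X2), tcrossprod(X2))
  # cross block consistency
  Kc <- rbfKernel(X[1:6, ], 0.5, Y = X[7:10, ])
  expect_equal(Kc, rbfKernel(X, 0.5)[7:10, 1:6], tolerance = 1e-12)
})

test_that("single-kernel fit agrees with an independent SMO solver", {
  set.seed(43)
  n <- 30
  y <- rep(c(1, -1), each = n / 2)
  # separable toy with free support vectors on both sides, where the
  # margin-midpoint bias coincides with the KKT bias
  X <- matrix(rnorm(n * 2), n, 2) + 2.5 * y
  K <- rbfKernel(X, 0.2)
  model <- fitSdpSvm(list(K), y, C = 10)
  or <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y = factor(y),
                      type = "C-svc", C = 10, scaled = FALSE, tol = 1e-9)
  # compare decision values up to the sign convention of the factor level
  fOurs <- predictionScores(predictSdpSvm(model, list(K)))
  fOracle <- as.numeric(kernlab::predict(or,
    kernlab::as.kernelMatrix(K[, kernlab::SVindex(or), drop = FALSE]),
    type = "decision"))
  s <- sign(cor(fOurs, fOracle))
  expect_lt(max(abs(fOurs - s * fOracle)), 1e-4)
  # identical hard labels on the toy
  expect_equal(ifelse(fOurs > 0, 1, -1), y)
})

test_that("dual constraints hold at the reported solution", {
  set.seed(47)
  n <- 24
  y <- rep(c(1, -1), each = n / 2)
  X <- matrix(rnorm(n * 3), n, 3) + 1.2 * y
  Ks <- list(rbfKernel(X[, 1:2], 1), linearKernel(X))
  model <- fitSdpSvm(Ks, y, C = 2)
  expect_true(all(model@alpha >= -1e-8 & model@alpha <= 2 + 1e-8))
  expect_lt(abs(sum(model@alpha * y)), 1e-4)
  expect_true(all(model@mu >= 0))
  expect_equal(sum(model@mu), 1, tolerance = 1e-10)
  # trace budget: trace(sum lambda_i K_i) = cTrace
  tr <- sum(vapply(seq_along(Ks),
                   function(i) model@lambda[i] * sum(diag(Ks[[i]])),
                   numeric(1)))
  expect_equal(tr, model@cTrace, tolerance = 1e-6)
})

test_that("identical kernels and kernel scaling leave predictions alone", {
  set.seed(53)
  n <- 20
  y <- rep(c(1, -1), each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4) + y
  K <- rbfKernel(X, 0.5)
  one <- fitSdpSvm(list(K), y, C = 1)
  two <- fitSdpSvm(list(K, K), y, C = 1)
  expect_equal(predictionScores(predictSdpSvm(two, list(K, K))),
               predictionScores(predictSdpSvm(one, list(K))),
               tolerance = 1e-4)
  # scaling all kernels by a constant renormalizes through the trace budget
  scaled <- fitSdpSvm(list(7 * K), y, C = 1)
  expect_equal(predictionScores(predictSdpSvm(scaled, list(7 * K))),
               predictionScores(predictSdpSvm(one, list(K))),
               tolerance = 1e-4)
})

test_that("prediction rules: zero goes negative, training point consistent", {
  set.seed(59)
  n <- 20
  y <- rep(c(1, -1), each = n / 2)
  X <- matrix(rnorm(n * 3), n, 3) + 1.5 * y
  K <- rbfKernel(X, 0.3)
  model <- fitSdpSvm(list(K), y, C = 10)
  # a duplicated training sample gets the training sample's decision value
  fTrain <- predictionScores(predictSdpSvm(model, list(K)))
  fDup <- predictionScores(predictSdpSvm(model, list(K[3, , drop = FALSE])))
  expect_equal(fDup, fTrain[3], tolerance = 1e-10)
  # hand-built zero decision value classifies as -1
  pred0 <- PredictionResult(ifelse(0 > 0, 1, -1), 0, "decision_value")
  expect_equal(predictedLabels(pred0), -1)
})

test_that("sigma tuning returns grid members with deterministic ties", {
  set.seed(61)
  n <- 24
  y <- rep(c(1, -1), each = n / 2)
  X <- matrix(rnorm(n * 2), n, 2) + 1.5 * y
  expect_equal(tuneSigma(X, y, grid = 0.7), 0.7)
  # constant features: every sigma ties, smallest returned
  Xc <- matrix(1, n, 2) + 0
  expect_equal(tuneSigma(Xc, y, grid = c(0.1, 1, 10)), 0.1)
  s1 <- tuneSigma(X, y, grid = c(0.25, 0.5, 1), seed = 5)
  s2 <- tuneSigma(X, y, grid = c(0.25, 0.5, 1), seed = 5)
  expect_identical(s1, s2)
})
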