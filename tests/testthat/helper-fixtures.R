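# Shared fixtures, built in code at test time.

# a small fully labelled study with one informative and one noise source
makeTestStudy <- function(n = 60, seed = 42, delta = 1.5,
                          nClusters = NULL, classBalance = 0.5) {
  generateStudy(simulationSpec(
    n,
    sources = list(
      list(nFeatures = 40, nInformative = 8, delta = delta),
      list(nFeatures = 30, nInformative = 0, delta = 0)),
    classBalance = classBalance, nClusters = nClusters, seed = seed))
}

# a deterministic hand-built study: 2 sources, explicit values
makeTinyStudy <- function() {
  ids <- c("s1", "s2", "s3", "s4")
  X1 <- matrix(as.numeric(1:16), 4, 4, dimnames = list(ids, paste0("a", 1:4)))
  X2 <- matrix(as.numeric(16:1), 4, 4, dimnames = list(ids, paste0("b", 1:4)))
  MultiOmicsStudy(list(s1 = X1, s2 = X2),
                  setNames(c(1, -1, 1, -1), ids))
}

# random symmetric non-negative weight matrix with zero diagonal
randomWeights <- function(n, seed = 1) {
  set.seed(seed)
  W <- matrix(runif(n * n), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

# write a small TSV matrix fixture and return its path
writeTsvFixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
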