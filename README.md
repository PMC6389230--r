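# gkintegrate

Graph- and kernel-based multi-omics data integration classifiers for
binary traits, with the benchmarking protocol to compare them.

## The problem

A study measures the same patients on several omics platforms — say gene
expression, miRNA expression and methylation — together with a binary
outcome (case/control, receptor status, lymphatic invasion). No single
platform tells the whole story, and the platforms live on different
scales, so integration methods first map every source into a common
intermediate representation over *samples*: either a sample-similarity
**graph** (nodes = patients, edge weights = profile similarity) or a
**kernel matrix**. This package implements seven integration classifiers
built on those two representations, plus everything needed to benchmark
them against each other without access-controlled data.

## The seven classifiers

**Graph-based** (transductive: test samples sit in the graph with label 0):

1. *Graph semi-supervised learning* — minimize
   `Σᵢ(fᵢ − yᵢ)² + c Σᵢⱼ wᵢⱼ(fᵢ − fⱼ)²`; closed form
   `f = (I + cL)⁻¹ y` with Laplacian `L = D − W`. Multiple sources enter
   through network weights `α` solving
   `min_α yᵀ(I + Σ αₖ Lₖ)⁻¹ y, Σ αₖ ≤ c`; classification is by median
   cut-off on `f`.
2. *Graph sharpening integration* — removes directed edges from
   unlabelled to labelled nodes and between oppositely labelled nodes,
   then solves `f = [I + ½ Σ αₖ(Lₖ + Lₖᵀ)]⁻¹ y`.
3. *Composite association network* — regresses per-source weight
   matrices on a label-derived three-level target network
   (`α = (ΩᵀΩ)⁻¹ Ωᵀ vec(T)`, negative weights zeroed, uniform fallback),
   then runs single-network propagation with `c = 1`.
4. *Bayesian network classifier* — Bonferroni-filtered features per
   source, signed standardized scores, quartile binning, and a
   posterior-odds rule `Odd_post = Odd_prior × Π p(vᵢ|y=1)/p(vᵢ|y=−1)`
   (> 1 ⇒ positive), with optional dependence edges at conditional
   correlation above 0.3 and joint CPTs per connected block.

**Kernel-based** (inductive):

5. *SDP-SVM* — multiple-kernel 1-norm soft-margin SVM; the QCQP
   `max 2αᵀe − ct, t ≥ (1/rᵢ)αᵀdiag(y)Kᵢdiag(y)α` learns kernel weights
   `μᵢ ≥ 0` under a trace budget.
6. *Relevance vector machine* — sparse Bayesian kernel classifier per
   source, probabilities `P(y=1|x) = 1/(1+e^{−Y(x)})` averaged across
   sources with a 0.5 cut-off.
7. *Ada-boost RVM* — boosted RVM weak learners trained on subsamples,
   weighted by `αₜ = ½ ln((1−εₜ)/εₜ)` with the classic exponential
   weight update.

**Evaluation protocol**: repeated stratified 75/25 hold-out (200 runs in
the reference design), leave-cluster-out cross-validation for family
data, exact-ratio class-imbalance subsampling (e.g. 5:1, 5:2), and
accuracy / F1 / AUC with percentile-bootstrap 95% confidence intervals.
A synthetic multi-omics study generator (Gaussian class-shift model with
controllable signal, imbalance, and family structure) makes every method
testable end to end.

## Worked example

```r
library(gkintegrate)

study <- generateStudy(simulationSpec(
  120,
  sources = list(
    list(nFeatures = 100, nInformative = 10, delta = 1.5),
    list(nFeatures = 50,  nInformative = 8,  delta = 1.2)),
  classBalance = 0.6, seed = 7))
study
#> MultiOmicsStudy: 120 samples, 2 source(s)
#>   source1: 100 features
#>   source2: 50 features
#>   labels: 48 neg, 0 unlabelled, 72 pos

report <- repeatedHoldout(study, c("composite", "bayes", "sdpsvm"),
                          nRuns = 10, seed = 11)
report
#> EvaluationReport over 10 runs
#>   algorithm   metric  mean lower upper
#> 1 composite accuracy 0.973 0.957 0.987
#> 2 composite       f1 0.977 0.963 0.989
#> 3 composite      auc 0.998 0.994 1.000
#> 4     bayes accuracy 0.973 0.953 0.990
#> 5     bayes       f1 0.977 0.960 0.991
#> 6     bayes      auc 0.998 0.994 1.000
#> 7    sdpsvm accuracy 0.977 0.963 0.990
#> 8    sdpsvm       f1 0.980 0.968 0.991
#> 9    sdpsvm      auc 1.000 1.000 1.000
```

Each row is the mean of the per-run metric over the hold-out
repetitions, with percentile-bootstrap 95% limits: on this strongly
informative two-source simulation all three integrators classify nearly
perfectly. `integrationAlgorithms()` lists all seven method names.

A command-line wrapper with `simulate`, `fit`, `predict` and `benchmark`
subcommands is installed at
`system.file("scripts", "gkintegrate", package = "gkintegrate")`, driven
by YAML configs; see `?gkCLI`.

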