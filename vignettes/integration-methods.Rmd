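---
title: "Graph- and kernel-based integration of multi-omics data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph- and kernel-based integration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gkintegrate)
```

# Scope

`gkintegrate` implements seven classifiers that integrate several aligned
omics data sources to predict a binary trait, together with the
evaluation designs used to compare them and a synthetic study generator.
This vignette is the package's account of the underlying models, the
tunable parameters, the numerical decisions, and what our tests do and
do not establish.

# Data model

The central container is the `MultiOmicsStudy`: an ordered list of
per-source numeric matrices (samples × features) sharing one sample
order, a label vector in {−1, 0, +1} where 0 marks blinded/unlabelled
samples, and optional per-sample cluster (family) identifiers. The label
file's order is the canonical study order; `alignStudy()` restricts and
reorders all sources to the common sample intersection. Only the toolkit
sets labels to 0 — users supply ±1 — which prevents accidental use of
test labels during fitting.

All sources are standardized feature-wise (mean 0, sd 1 with the n−1
denominator) before graph or kernel construction. This is a package
convention: correlation- and distance-based similarities are
scale-sensitive, and omics platforms differ in scale by orders of
magnitude. During evaluation the standardization statistics are computed
on training rows only and applied to all rows, so the transductive
methods still never touch test information beyond the unlabelled
feature values they legitimately see.

# Graph-based methods

Each source yields a sample-similarity graph: `W[i,j] =
max(cor(x_i, x_j), 0)` (Pearson by default; Spearman available at
O(n² log n)), with the diagonal forced to zero so self-similarity does
not dominate the node degrees. The Laplacian is `L = D − W`.

**Single network.** Scores solve
`min_f Σ(f_i − y_i)² + c Σ w_ij (f_i − f_j)²`, giving
`f = (I + cL)⁻¹ y`, computed by a dense linear solve (never an explicit
inverse; residual below 1e−8 is asserted in tests). Unlabelled nodes
enter with y = 0 (transductive). A node is classified +1 when its score
is strictly closer to the median score of labelled positives than of
labelled negatives; exact ties go to −1 (an arbitrary but fixed rule).

**Multiple networks.** The networks share a smoothness bound, and the
dual weights solve `min_α yᵀ(I + Σ α_k L_k)⁻¹ y` over
{α ≥ 0, Σα ≤ c}. The objective is convex (a matrix-fractional function
composed with an affine map) and non-increasing in every α_k, so the
budget is active at the optimum. We use projected gradient with the
analytic gradient `−yᵀA⁻¹L_k A⁻¹y`, Armijo backtracking, a uniform
feasible start α = c/m, exact Euclidean projection onto the capped
simplex, and a final pairwise budget-transfer polish so vertex optima
are reached exactly rather than asymptotically. Tests verify the
returned objective beats every point of a step-c/10 simplex grid.

**Worst-case character of the weighting — a known limitation.** Because
the formulation bounds the *worst* per-network smoothness, the weights
concentrate on networks where the labels are *least* smooth: that is
the binding constraint. When one source is pure noise, its dense
truncated-correlation graph binds and receives the weight, and the
propagated scores degrade towards chance. Our integration tests show
this concretely: with one informative and one pure-noise source the
multi-network solver puts its mass on the noise graph and its hold-out
AUC falls well below that of the other integrators, while with several
partially informative sources it performs well. This is a property of
the published formulation that users combining sources of very unequal
quality should know about; the composite association network is the
robust graph-based alternative.

**Graph sharpening.** Reading `w_ij` as edge strength from node j to
node i, edges from unlabelled to labelled nodes are removed, then edges
between oppositely labelled nodes. Retained entries are untouched, so
labelled nodes lose no outgoing influence. The resulting W is
asymmetric; the network weights are optimized with each Laplacian
replaced by its symmetrization (L + Lᵀ)/2 — the only reading under
which `f = [I + ½ Σ α_k (L_k + L_kᵀ)]⁻¹ y` is the stationary point.
Numerically, this symmetrization keeps the *asymmetric* row-sum degrees
and is not always positive semidefinite, so `I + Σ α L` can leave the
positive-definite cone for large α; the optimizer assigns such points an
infinite objective (Cholesky feasibility check) and the line search
backs away. Sharpening is recomputed per train/test split, since it
depends on which labels are visible.

**Composite association network.** The target network over labelled
nodes takes three values determined by the class proportions: (n₊/n)²
for negative–negative pairs, (n₋/n)² for positive–positive pairs, and
n₊n₋/n² for mixed pairs. We implement this printed convention verbatim.
Note its consequence: with exactly balanced classes all three values
coincide and the target carries no contrast, in which case the fitted
source weights are driven by noise and frequently all non-positive,
triggering the documented uniform-1/m fallback. The constructor's
`mixedSign = "negative"` switch flips the mixed-pair value to −n₊n₋/n²,
the convention of the original association-network literature, under
which the target always carries contrast; the source-quality ranking
checks in our test suite use this switch for exactly that reason, while
the package default follows the printed rule. The weights solve the
normal equations `α = (ΩᵀΩ)⁻¹Ωᵀvec(T)` with a leading bias column of
ones; vec() stacks the full matrix (both triangles and the diagonal,
affecting only constant factors). Negative weights are zeroed, an
all-non-positive fit falls back to α = 1/m, the bias is reported but
discarded when combining, and a ridge guard (λ = 1e−8) covers collinear
or constant sources. The regression sees training-node submatrices only
(the target is undefined for unlabelled nodes); the fitted weights then
combine the full matrices and a single-network propagation with c = 1
classifies by median cut-off.

**Bayesian network classifier.** Per source: every feature gets a
pooled two-sample t-test against the label; features passing the
Bonferroni threshold 0.05/n_features are kept with direction
sign(mean₊ − mean₋), and if none pass, the single smallest-p feature is
kept so a score always exists. The per-sample source score is the
signed sum of training-standardized selected features (the construction
is ours; only the existence of "scores" is prescribed). Scores are
discretized into 4 bins at the training quartiles
(linear-interpolation convention; boundary values fall into the lower
bin; out-of-range test scores clamp to the outer bins). The structured
variant adds a dependence edge between two source-score variables when
the mean of their two within-class Pearson correlations exceeds 0.3 in
absolute value — "conditional correlation" is otherwise undefined, so
the within-class mean is our reading — and fits one joint CPT per
connected component (a component of k variables has 4^k cells; above 3
variables we warn). Every CPT cell carries a Laplace pseudocount of 1,
which guarantees finite posterior odds for every bin pattern — the
known failure mode of structured variants at small n is an infinite
odds ratio. Classification: posterior odds = prior odds × product of
component likelihood ratios; odds > 1 ⇒ +1, odds exactly 1 ⇒ −1.

# Kernel-based methods

Kernels are built per source on the training-standardized features:
linear `⟨x_i, x_j⟩` or RBF `exp(−σ‖x_i − x_j‖²)` (default). σ defaults
to the median heuristic 1/median(‖x_i − x_j‖²); `tuneSigma()` does a
5-fold CV grid search over median × 2^(−4..4), ties to the smaller σ.

**SDP-SVM.** The multiple-kernel 1-norm soft-margin SVM is solved in
its QCQP form: `max 2αᵀe − ct` subject to
`t ≥ (1/r_i) αᵀ diag(y) K_i diag(y) α` with `r_i = trace(K_i)`,
`αᵀy = 0`, `0 ≤ α ≤ C`. Its saddle-point form minimizes, over kernel
weights λ on the simplex {λ ≥ 0, Σλ = c}, the single-kernel SVM dual
value on `Σ (λ_i/r_i) K_i`. The outer problem is convex (pointwise max
of affine functions); we use projected gradient with the envelope
gradient, and the inner box/equality QP is solved with kernlab's
interior-point solver (`ipop`), with an escalating diagonal jitter for
degenerate kernels. The trace budget c equals the training-set size, so
the recovered weights μ_i = λ_i/r_i satisfy trace(Σμ_i K_i) = c; the
reported μ is additionally normalized to sum to one. The decision value
is `f(x) = Σ α_i y_i K(x_i, x) + b` — the standard dual expansion with
the labels inside — and the default bias is the margin midpoint
`b = −(max_{y=−1} g + min_{y=+1} g)/2` (a `bias = "paper"` switch
replaces the min by a max for comparison). `f = 0` classifies as −1.
The C grid for cross-validation is {0.01, 0.1, 1, 10, 100}.

**RVM.** Sparse Bayesian learning over `Y(x) = Σ w_i k(x, x_i)`:
independent Gaussian priors with per-weight precisions, type-II maximum
likelihood with a Laplace approximation of the logistic likelihood
(inner Newton/IRLS with step halving), precisions above 1e9 pruned,
convergence when max |Δ log precision| < 1e−3, at most 500 outer
iterations (non-convergence returns the best iterate, flagged). The
surviving samples are the relevance vectors. Class probability is the
logistic sigmoid of the score. With several sources, one RVM is trained
per source and the probabilities are averaged; the 0.5 cut-off
classifies, with exactly 0.5 going to −1.

**Ada-boost RVM.** Sample weights start at 1/N. Each iteration draws a
without-replacement subsample (fraction of N), fits an RVM on it, and
computes the weighted error ε_t over the *full* training set — the
weights are defined on all N samples, so that is where Σ w_i over
misclassified samples lives. Iterations with ε_t ≥ 0.5 are skipped with
weights untouched; stored learners get α_t = ½ln((1−ε_t)/ε_t), weights
are multiplied by e^{±α_t} and renormalized to sum to one. The ensemble
score is Σ α_t h_t(x) over the stored learners' hard votes; its sign
classifies (0 ⇒ −1) and the logistic sigmoid of the score serves as the
reported probability. With several sources we boost per source and
average the probabilities, mirroring the per-source RVM design; whether
the original procedure boosts per source or on a combined kernel is not
specified, and per-source is our documented choice. If every iteration
is skipped, a single RVM on the full training set is the fallback. The
CV grids are resampling fraction {0.2, 0.4, 0.6, 0.8} and iterations
{1, 5, 10, 20, 30}, ties resolved towards fewer iterations, then the
smaller fraction.

# Evaluation protocol

`repeatedHoldout()` draws stratified 75/25 splits (stratification is our
addition; it prevents empty-class test sets at the sample sizes these
methods target), blinds the test labels to 0 *before* any integrator
sees the study, fits, predicts, and records accuracy, F1, AUC,
sensitivity and specificity per run. The reference design uses 200
runs. AUC is the rank-based estimator (concordant + half of tied pairs
over P·N). Confidence intervals are percentile bootstrap over the
per-run metric values (2000 resamples, fixed seed) — the bootstrap unit
is the run, a documented choice. Failed runs are excluded per algorithm
and counted. `leaveClusterOut()` samples training clusters without
replacement (e.g. 12 of 17 families, always testing on the remaining
5); splits never divide a cluster, and splits lacking a class are
redrawn. `subsampleImbalance()` reduces a study to the largest
achievable exact positive:negative ratio by without-replacement
sampling; whether the original design fixed total n or maximized it is
unstated, and we maximize.

A registry-level leakage test fits every integrator on studies whose
blinded test labels have been poisoned and asserts bit-identical
predictions.

# The synthetic study generator

`generateStudy()` draws, per source, `nInformative` features whose
class means sit at ±Δ/2 (in units of the noise sd) and the rest at 0,
all with independent Gaussian noise. An optional family structure adds
a per-cluster random intercept (sd = noiseSd/2) shared by every feature
and source of a sample, emulating related-individual data for
leave-cluster-out designs. Class balance is controlled exactly (to one
sample); everything is reproducible from a single integer seed.

What the generator emulates: aligned samples, heterogeneous source
dimensionalities, controllable per-source signal, imbalance, and family
structure. What it does not: feature–feature correlation structure
within a source, non-Gaussian marginals (counts, beta-valued
methylation), batch effects, and missingness. Passing tests therefore
establish correctness of the algorithms and protocol on a favourable,
well-specified data model — not performance claims on any particular
real cohort.

# Numerical choices and degenerate inputs

* Dense solves throughout: the intended regime is n of a few hundred.
* Zero-variance features are dropped with a warning before
  standardization; zero-variance sample profiles get zero correlation.
* Median cut-off, posterior-odds = 1, probability = 0.5, and decision
  value = 0 all resolve to −1, fixed and documented.
* Degenerate (e.g. rank-one) kernels escalate a diagonal jitter inside
  the QP solver; genuinely constant problems then tie, and grid ties
  resolve towards the smaller parameter everywhere.
* The composite-network normal equations fall back to a λ = 1e−8 ridge
  when rcond < 1e−12 (duplicated omics sources are common).
* RVM precisions are clamped to [1e−12, 1e12] and at least one weight
  always survives pruning.

# Problem sizes used by the automated checks

The test suite exercises: solver-equivalence and optimizer-optimality
on 100 and 20 random 15–20-node instances; source-quality ranking over
50 seeded 150-sample two-source draws (composite weights and SDP-SVM
kernel weights); hold-out AUC of all seven integrators over 10 runs on
a 150-sample study with one informative and one pure-noise source, with
a permuted-label control over 10 fresh permutations × 2 runs (a fresh
permutation per run matters: any single permutation retains chance
feature–label association of order 1/√n that classifiers reproduce
across splits); Bayesian-classifier odds convergence at n = 10,000 with
binary bins so that every CPT cell holds thousands of observations; and
the full protocol drivers with stub classifiers at 200 runs. These
sizes are the package's chosen balance between statistical power and a
test suite that runs in minutes.

# Known limitations

* The multi-network smoothness weighting is worst-case by construction
  and is misled by entirely uninformative sources (see above); the
  composite association network does not share this failure mode.
* The printed three-level target network is contrast-free under exact
  class balance; use `mixedSign = "negative"` when source-weight
  interpretability matters on balanced designs.
* Structured Bayesian networks with large dependent blocks need 4^k CPT
  cells; the pseudocount keeps odds finite but estimates become diffuse.
* RVM training is O(n³) per precision update; several hundred training
  samples is the practical ceiling of this implementation.
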