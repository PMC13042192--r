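---
title: "Network Skeleton Extraction: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network Skeleton Extraction: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gene co-expression graphs start life complete: every pair of genes in a set
gets an edge weighted by the absolute correlation of their expression,
`w_ij = |cor(x_i, x_j)|`. Complete graphs are uninterpretable; the question
is which edges to drop. Thresholding on weight is the common answer, but it
severs weak ties — a low-correlation edge that is the only connection
between two modules is structurally critical even though its weight is
small — and thresholded networks fragment early.

`netskeleton` sparsifies spectrally instead. Each edge is scored by its
importance

\[ I_{ij} = w_{ij} R_{ij}, \qquad
   R_{ij} = (e_i - e_j)^\top L^{+} (e_i - e_j), \]

where `L = D - W` is the unnormalized graph Laplacian and `R_ij` the
effective resistance: the two-point resistance of the electrical network in
which every edge is a resistor of conductance `w_ij`. A bridge has
`R = 1/w` and importance exactly 1; an edge with many parallel alternatives
has small `R` and, if also weak, small importance. On a connected graph the
importances sum to `N - 1` (Foster's theorem), which the package logs as a
numerical health check.

The deterministic engine (`greedy_sparsify()`) removes the edge of minimal
current importance, then recomputes **all** resistances on the reduced graph
before the next selection — removal closes alternative paths, so the ranking
genuinely changes every step. Ties are broken by the smallest `(i, j)` pair
in node order, making the procedure fully reproducible. The probabilistic
engine (`probabilistic_sparsify()`) draws distinct edges sequentially with
probability proportional to importance until a target count is reached; it
is the randomized counterpart used for null models.

## Stopping: the median-MSE elbow

Sparsification stops where the graph stops being *predictive*. For every
gene, an ordinary-least-squares model (with intercept) predicts its
expression from its current neighbors; the median across genes of the
in-sample mean squared error is tracked along the removal order
(`mse_trajectory()`). The curve is truncated at the last step before the
graph would fragment (fragmentation is detected combinatorially, and
equivalently as the spectral gap reaching zero), and the elbow of the
truncated curve sets the sparsification level. The resulting skeleton is
always a single component with a positive spectral gap.

Numerical and design choices here, with reasons:

* **OLS, in-sample, divide-by-`n` MSE.** The minimal reading of "a
  regression model"; in-sample error makes the curve a deterministic
  function of the data. When a gene has at least `n - 1` neighbors the fit
  is saturated and the MSE is 0 (rank-revealing QR attains the minimal
  residual norm for any design); a gene with no neighbors falls back to the
  intercept-only model, i.e. its population variance. A k-fold
  cross-validated MSE would penalize useless predictors rather than reward
  them, but makes the curve depend on fold assignment; it is deliberately
  not the default.
* **Elbow = continuous two-segment fit.** For each candidate junction
  checkpoint (each segment at least 3 points), a broken-stick model
  `y = a + b_1 (x - x_k)^- + b_2 (x - x_k)^+` is fitted by least squares
  and the junction with minimal SSE wins, ties going to the smaller
  junction (less sparsification). The two lines meet at the junction by
  construction. We first implemented the unconstrained variant — two
  independent lines, elbow at their crossing — and found a real failure
  mode: on curves with a saturated flat-zero start the best-fit lines can
  cross *outside* the data range, and clamping collapses the elbow to step
  0 (no sparsification at all). The constrained fit has no such
  degeneracy and recovers exact piecewise-linear junctions perfectly.
* **Checkpoint stride 1** (every removal) by default; configurable for
  large sets.
* **Zero eigenvalues.** Component counts are always taken from
  breadth-first traversal, never from the spectrum; the eigendecomposition
  uses the tolerance `1e-9 * max(1, lambda_max)` only to clip the
  pseudoinverse and for the diagnostic multiplicity check. Cross-component
  effective resistances are reported as `Inf` (the pseudoinverse formula
  does not apply across components, and electrically there is no path).
* **Exactly-zero correlations** yield weight 0 and are treated as absent
  edges: a zero-conductance resistor is no edge. In continuous data exact
  zeros essentially never occur, so the "complete" graph is genuinely
  all-to-all in practice.
* **Full recomputation, not incremental updates.** One eigendecomposition
  per removal is `O(E N^3)` overall — entirely comfortable for gene sets
  up to a few hundred nodes, which is the intended regime. Reference
  semantics beat a faster rank-one-update variant that would need its own
  equivalence proof.

## Comparing skeletons across conditions

Three metrics, each capturing a different axis:

* **Normalized Hamming distance** (binarized adjacencies): fraction of node
  pairs whose edge presence differs. Insensitive to overall sparsity.
* **Jaccard index** of edge sets: overlap relative to the union. Sensitive
  to sparsity; two empty edge sets are defined as identical (the raw ratio
  is 0/0 and the identity reading matches "no difference").
* **Spectral distance**: `|lambda_2(A) - lambda_2(B)|`, the difference in
  algebraic connectivity — a global cohesion comparison blind to edge
  identity.

Significance is assessed against spectrally-matched random graphs. Per
permutation: every gene is mean-centered within each condition (so
differential expression cannot masquerade as co-expression), the pooled
samples are reassigned to pseudo-conditions preserving group sizes, a
complete graph is rebuilt from each pseudo-condition, and each is
probabilistically sparsified to the corresponding observed skeleton's edge
count. The null statistic is the metric *between the two members of each
pair*.

The pairing matters, and we chose it deliberately. Anchoring the null to
one fixed observed skeleton (null statistic: distance from condition A's
skeleton to each random graph) looks natural but is not calibrated: the
observed statistic is a distance between *two* independently extracted
skeletons, and its variance — dominated at small sample sizes by
instability in each skeleton's elbow, hence density — is not represented in
an anchored null. On no-effect synthetic data the anchored design produces
spurious "more different than chance" calls at many times the nominal rate,
while the paired design keeps them at nominal; the acceptance suite
computes this spurious-difference rate directly.

Empirical p-values use the add-one convention `p = (1 + r)/(1 + n)` with
ties counted in the tail, so p is never 0 and the test is valid at finite
permutation counts. For Hamming and spectral distance the "difference" tail
is high; for Jaccard it is low; the opposite tails quantify conservation.
No multiple-testing correction is applied across gene sets by default
(`p.adjust` composes trivially downstream).

### What a green test does and does not establish

Calibration under the null is one-sided in a meaningful way. Under no
condition effect, two greedy skeletons are systematically *more similar to
each other* than two importance-sampled random graphs are — deterministic
extraction concentrates on the same strong-edge core, while probabilistic
sparsification scatters. The low tail of the null therefore fires well
above its nominal rate even without any condition effect; this is the
"conservation" signal, not an error, and it is exactly the behavior the
subsampling experiments quantify (biologically equivalent subsets sit far
below the random-graph yardstick). The flip side is limited power for
*difference* detection at desk scale: a planted rewiring must displace more
edge mass than the probabilistic sampler's own scatter before the high tail
can see it. On 12-gene sets with 40 samples per condition and four rewired
cross-block pairs at the PSD-feasibility cap, measured power is essentially
zero. Detecting differences of this kind at this scale requires either
larger gene sets, stronger rewiring, or a null built with the deterministic
extractor (at substantially higher cost).

## The synthetic world

`sim_spec()` describes a Gaussian expression model: blocks of genes with
equicorrelation `rho` inside each block, optional cross-block bridge pairs,
optional condition-specific rewiring, optional per-condition mean profiles,
i.i.d. samples. The canonical fixture is two 10-gene blocks at
`rho = 0.8` joined by a single `rho = 0.3` bridge with 200 samples — the
minimal world in which the "strength of weak ties" is testable: the bridge
is the sole connector, carries maximal effective resistance, and must
survive sparsification.

Two honesty notes. First, a strong bridge between tight blocks is often
*infeasible* as a literal correlation entry: the two-block-plus-bridge
template above has minimum eigenvalue −0.071. The constructor therefore
validates positive semi-definiteness and, by default, rejects infeasible
templates naming the offending pairs; `psd = "nearest"` instead projects to
the nearest correlation matrix (Higham), which realizes the fixture
faithfully (within-block ≈ 0.80, bridge ≈ 0.245, other cross-block entries
≈ 0). Second, feasibility caps planted effects: four disjoint rewired
cross-block pairs in 6-gene `rho = 0.7` blocks admit at most
`rho_b = 0.3`.

The reproducibility fixture adds what pure block-covariance worlds lack:
condition-driven mean structure. Real developmental data are dominated by
stage and lineage trajectories, and pooled-sample correlations inherit
that structure, which is why balanced subsamples reproduce the reference
network so well. The fixture emulates this with 24
conditions (4 lineages × 6 stages, 4 replicates) and per-gene stage ramps
of 0.8–1.6 residual standard deviations, opposite in sign for the two
blocks. Features of real data the generator does *not* emulate: count
noise and library-size effects (inputs are assumed correlation-ready),
heavy-tailed expression, gene-specific variances, and any non-Gaussian
dependence. A green test on this world establishes the algorithmic claims
(determinism, connectivity, weak-tie retention, orderings), not biological
validity.

## Known limitations

* In-sample MSE includes a mechanical overfitting ramp (≈ `sigma^2 p / n`
  per predictor), which flattens the elbow when samples barely exceed
  neighbors; elbow placement is then unstable across replicate draws, and
  skeleton density varies with it. This is the dominant source of variance
  in all downstream comparisons at small `n`.
* The elbow is a global property of the median curve; no per-gene stopping
  is attempted.
* The probabilistic null's extra scatter makes difference tests
  conservative (see above); conservation tests are correspondingly
  liberal and should be read as descriptive.
* Dense eigendecompositions bound practical gene-set size to a few hundred
  nodes.
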