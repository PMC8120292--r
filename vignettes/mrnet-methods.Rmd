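---
title: "Methods and design of mrnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of mrnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrnet)
```

# The model

`mrnet` treats a set of genetic variants and molecular phenotypes as
nodes of a mixed graph: a directed edge i → j states that i is causal to
j, and an undirected edge states an association whose direction the data
cannot identify. The adjacency convention is row = parent, column =
child, with a symmetric pair of 1s encoding one undirected edge. Three
assumptions underlie the inference:

* **Causal sufficiency** — relevant confounders are among the observed
  variables; nothing latent drives two observed nodes.
* **Faithfulness / Markov** — conditional independencies in the data
  reflect d-separations of the true graph, testable by partial
  correlations (continuous) or stratified G² statistics (discrete).
* **The principle of Mendelian randomization (PMR)** — alleles are
  randomized at meiosis, so a variant can be a cause but never an effect
  of a phenotype, and causal direction between two variants is not
  meaningful.

Under PMR, a variant acts as an instrument that breaks Markov
equivalence: among three-node models over (V1, T1, T2) —
see `basicModelCatalog()` — the chain, collider and fork all become
distinguishable, except for the fork-with-edge model whose two fully
directed versions remain equivalent and whose T1–T2 edge therefore stays
undirected.

# Step I: skeleton search with online FDR control

The level-wise search is the *stable* PC variant: adjacency sets are
frozen at the start of each level, so removals within a level cannot
influence which tests other pairs face. Together with a fixed canonical
enumeration order — nodes sorted lexicographically; pairs by (smaller,
larger) label; conditioning subsets of the smaller-label node's
neighbourhood in lexicographic combination order — this makes the entire
procedure, including the sequential threshold stream, a pure function of
the labelled data. Permuting input columns cannot change any decision,
which is what the node-ordering stability counter verifies empirically.

The number of independence tests is unknown in advance (each removal
cancels future tests), so multiple-testing control must be *online*. The
LOND rule assigns test *t* the threshold

$$\alpha_t = \beta_t\,(D_{t-1} + 1),$$

where $D_{t-1}$ is the number of rejections so far. Any nonnegative
sequence with $\sum_t \beta_t = \alpha$ controls the overall FDR at
$\alpha$. The default is

$$\beta_t = \frac{\alpha\,C}{t\,\ln(\max(t,2))^2},$$

with $C$ normalizing the sum over a horizon of $10^6$ tests — a standard
summable choice; the horizon only fixes $C$ and is configurable
(`londState()`). Thresholds start around $\alpha/2$, shrink along a null
stream, and scale back up with each discovery. `fdrControl = "fixed"`
switches to a constant per-test level, the behaviour of classic PC
implementations, for comparison runs.

Numerical details: partial correlations are computed by inverting the
correlation submatrix on {i, j} ∪ S and normalizing the precision-matrix
entry (standard in PC implementations, and checked in the tests against
the textbook recursive elimination to 1e-10); a singular submatrix raises
a collinearity error with the pair and set in the message. A (partial)
correlation of magnitude 1 yields p = 0 with a warning rather than an
error, so simulation sweeps do not abort. The Fisher-z test requires
n − |S| − 3 ≥ 1. In the G² test, zero-count cells contribute nothing,
empty strata are skipped, and a nonpositive degrees-of-freedom count
(a constant variable) returns p = 1 with a warning.

# Step II: orientation

1. **PMR.** Variant–phenotype edges are directed to the phenotype;
   variant–variant edges are fixed undirected.
2. **V-structures.** For each candidate triplet X−Y−Z (X, Z non-adjacent,
   both adjacent to Y), the decision uses the test of X ⟂ Z given
   exactly {Y} — conditioning on supersets is deliberately not
   consulted. If Step I never ran that test, it is run now, consuming
   the next LOND threshold in triplet-canonical order so the FDR
   bookkeeping stays coherent. Only a rejection (conditional dependence)
   orients X → Y ← Z. This on-demand test is the correction over the
   classic sepset shortcut: absence of Y from a separation set can mean
   the conditional test was simply never performed, which is no evidence
   of a collider. Triplets whose middle node is a variant are skipped —
   its phenotype edges already point away and variant edges must stay
   undirected — as are triplets with an edge already directed away from
   Y. If two triplets demand opposite directions for one edge, the edge
   is reset to undirected with a warning and excluded from further
   orientation; the procedure itself gives no principled winner.
3. **Iterative orientation.** Repeated canonical sweeps consider each
   undirected phenotype edge a−b: if some X → a exists with X, b
   non-adjacent and the ledger holds a *non-rejected* test of X ⟂ b
   given {a}, the only basic model consistent with the record is the
   chain, so a → b — unless that would create a new untested collider at
   b, close a directed cycle, or the mirror triplet supports the
   opposite direction (the Markov-ambiguous situation, left undirected).
   Sweeps repeat to a fixpoint; re-running the step is a no-op, and
   orientation never adds or removes adjacencies.

The `classic` mode orients colliders purely from separation sets
(claimed whenever Y ∉ sepset(X, Z); a pair with no recorded sepset — only
possible for hand-constructed inputs — claims nothing) and then applies
Meek's rules to closure. All four rules are implemented with their
standard statements; starting from sepset-claimed colliders alone the
fourth rule cannot fire (it needs externally injected directions), but it
is kept for completeness.

# The simulator

`simulateDagData()` draws nodes in topological order: parentless variants
from the Hardy–Weinberg multinomial with allele frequency q, parentless
phenotypes from N(m, σ²), and any node with parents from
N(γ₀ + Σ γₗ Xₗ, σ²). Defaults — q = 0.45, γ₀ = 0, m = 0, σ = 1,
n = 1000, a common coefficient γ on every edge with the sweep grid
{1.0, 0.5, 0.2} for strong/moderate/weak signal — are the study
conditions for all benchmark tables; only γ, the graph and n are varied
there.

Two conventions deserve comment:

* **Undirected edges.** A variant–variant undirected edge gets a random
  direction per dataset, after which the child variant, like any node
  with parents, follows the conditional normal (its marginal is then
  continuous; at the correlation level this preserves the γ-scaled edge
  strength that the benchmark sweeps rely on). An undirected
  phenotype–phenotype edge is a genuine per-sample 50:50 mixture: data
  are generated under both orientations and each sample independently
  keeps one pair of values, which is what leaves conditional T1–T2
  dependence intact in the fork-with-edge model. With k such edges the
  mixture enumerates 2^k orientation combinations (capped at 12).
* **Outliers.** The contamination model replaces the phenotype values of
  k uniformly chosen samples by draws centred 10 column-standard
  deviations above the mean. The count (10 per 1000 samples) follows the
  benchmark experiment; the generation rule itself is this package's
  choice, since only the count is stated in that experiment.

Reproducibility: a spec with a seed yields bit-identical data;
`sweepAccuracy()` derives one seed per replicate from the master seed so
cells are independently reproducible.

What the simulator deliberately does *not* emulate: linkage
disequilibrium beyond explicit variant–variant edges, nonlinear or
non-Gaussian structural equations, measurement error, and latent
confounding. Passing benchmarks on these simulations therefore
demonstrates correctness of the algorithmic machinery under the stated
model, not robustness to the violations real expression data can show.

# Robust correlation

For contaminated data, `robustCorrelation()` computes an iteratively
reweighted location/scatter estimate with Tukey-biweight weights on
Mahalanobis distances (cutoff c = 2·sqrt(χ²₀.₉₉₉,p); median-χ²
rescaling of the scatter each iteration; convergence at relative
Frobenius change < 1e-6 or 100 iterations). Samples get weights in
[0, 1]; gross outliers land near 0, and on clean Gaussian data the
estimate stays within sampling error of Pearson (both properties are
tested). Any affine-equivariant weight-producing robust scatter would
serve; this one was chosen for simplicity and transparency. When variant
columns are present the reweighting applies to the phenotype block only —
the estimator assumes continuous margins — and variant rows/columns of
the correlation matrix remain Pearson.

# Evaluation tools

Recall and precision compare unordered adjacencies with an orientation
state: full credit for a matching state, weight w = 0.5 for a recovered
edge with wrong or missing direction (the two are deliberately pooled),
zero for a missed edge; precision of an empty inferred graph is defined
as 0 so sweep aggregation stays total. The adjusted structural Hamming
distance charges 1.0 per presence/absence mismatch and 0.5 per
orientation mismatch. An `ignoreVVDirection` switch scores
variant–variant edges as undirected on both sides, for fair comparison
against methods that orient them arbitrarily.

Module clustering uses shortest-path distance ignoring orientation, with
disconnected pairs set to the node count (a finite sentinel exceeding any
real path). Average linkage is the default — no particular linkage is
canonical for this task, and it is configurable. The dendrogram is cut at
the cluster count that maximizes the number of clusters reaching the
minimum module size (smallest such cut on ties); nodes outside qualifying
clusters stay unassigned in module 0.

# Benchmark graphs

The three-node basic models and the two four-node stability graphs are
fully specified by their definitions. The 22-node complex benchmark
(`exampleComplexGraph()`) and the five-node outlier benchmark
(`exampleOutlierGraph()`) are *synthetic stand-ins* constructed for this
package: the complex graph has 14 variants and 8 phenotypes arranged in
four separated groups of 5–6 nodes (so distance clustering at minimum
module size 5 yields exactly four modules), containing chain and collider
motifs and ten undirected variant–variant edges; the outlier graph pairs
a chain with an unrelated variant–phenotype pair so that co-occurring
contamination induces spurious phenotype–phenotype edges under Pearson
correlation.

# Problem sizes in the shipped tests

The test suite runs 200 replicates per cell for the three-node models,
100 per cell for the 22-node graph, 20 datasets × 20 permutations per
graph for stability, 50 replicates for the outlier experiment, and 200
streams of 400 null p-values for FDR control — sizes chosen to keep
Monte-Carlo error comfortably inside the asserted tolerance bands while
the whole suite stays fast on a single CPU.

# Known limitations

* Sequential LOND thresholds preclude parallel testing inside one
  inference; parallelism belongs at the replicate level.
* Large dense graphs face the usual exponential subset growth of
  PC-style search; `maxCondSize` caps the conditioning-set size at the
  cost of possibly retaining extra edges.
* The on-demand v-structure test conditions only on the middle node; in
  dense neighbourhoods a larger separating superset could in principle
  reverse a decision, a trade-off accepted for determinism and FDR
  coherence.
* Mixed continuous–discrete data and rank-based tests are out of scope;
  inputs are either all-Gaussian or all-categorical.
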