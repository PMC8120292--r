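# mrnet: causal network learning with Mendelian randomization constraints

`mrnet` learns causal graphs from individual-level genomic data — genotypes
at genetic variants together with molecular phenotypes such as gene
expression — or from a correlation matrix with a sample size. It is aimed
at systems-biology settings where an expression quantitative trait locus
(eQTL) acts as a natural randomized instrument: because alleles are
randomized at meiosis, an edge between a variant V and a phenotype T can
only point V → T (the principle of Mendelian randomization, PMR), which
turns otherwise indistinguishable Markov-equivalent structures into
identifiable causal models.

## The method

Inference is a PC-style constraint-based search in two steps.

**Step I — skeleton.** Starting from the complete graph, pairs of nodes
are tested for marginal independence, then conditional independence given
one node, two nodes, and so on (Fisher-z tests on partial correlations for
continuous data, G² tests for discrete data). A non-significant test
removes the edge and records the conditioning set as the pair's separation
set. Unlike classic PC implementations, which fix a per-test type-I level,
every test here receives its own threshold from the LOND rule
(significance **L**evels based **O**n the **N**umber of **D**iscoveries):
at test *t* the threshold is

α_t = β_t (D(t−1) + 1),

where D(t−1) counts rejections so far and {β_t} is a summable sequence
with Σβ_t = α, so the *overall* false discovery rate of the whole test
stream — whose length is unknown in advance — is controlled at α
(default 0.05).

**Step II — orientation.** (1) Every variant–phenotype edge is directed
toward the phenotype; variant–variant edges stay undirected. (2) Candidate
triplets X−Y−Z with X, Z non-adjacent are checked for a v-structure
X → Y ← Z by the *conditional* test X ⟂ Z | Y; if Step I never ran that
test (e.g. the edge X−Z fell to a marginal test), it is run now on the
same online-FDR stream. Only a rejected test — actual conditional
dependence — orients the collider. (3) Remaining undirected edges are
oriented iteratively where exactly one direction is consistent with the
recorded test results (chain propagation without creating untested
colliders or cycles); edges whose direction the data cannot identify stay
undirected. A `classic` mode instead reproduces the original PC
orientation (collider claimed whenever Y is absent from the separation
set, then Meek's rules), including its documented false-v-structure
behaviour, for comparison studies.

All enumeration — pairs, conditioning subsets, triplets, and hence the
LOND threshold stream — follows the lexicographic node order, so results
are invariant to the column order of the input data.

The package also ships a linear-Gaussian structural-equation simulator
with Hardy–Weinberg genotypes (X_i ~ N(m_i, σ_i²) for parentless nodes,
X_j ~ N(γ_0 + Σ_l γ_l X_l, σ_j²) given parents, genotype frequencies
(1−q)², 2q(1−q), q²), per-sample 50:50 mixtures for undirected phenotype
edges, outlier injection and quantile discretization; robust correlation
(iteratively reweighted Tukey-biweight scatter) for contaminated data; and
evaluation tools: direction-weighted recall/precision, adjusted structural
Hamming distance (aSHD), node-ordering stability counting and
distance-based module clustering.

## Worked example

Simulate the canonical eQTL chain V1 → T1 → T2 (γ = 1, n = 1000) and
infer the graph back:

```r
library(mrnet)
truth <- basicModelGraph("M1")
d <- simulateDagData(simulationSpec(truth, gamma = 1, n = 1000, seed = 42))
fit <- inferCausalGraph(d, nGenotypes = 1)
fit
#> CausalFit (mode = mrpc , alpha = 0.05 )
#> CausalGraph with 3 nodes ( 1 genotype, 2 phenotype ) and 2 edges ( 2 directed, 0 undirected )
#>   T1 -> T2
#>   V1 -> T1
#> Tests performed: 6

ledgerData(testLedger(fit))
#>    i  j sizeS  S   estimate             p   threshold rejected
#> 1 T1 T2     0    0.76348535 8.779087e-221 0.025267125     TRUE
#> 2 T1 V1     0    0.57381280  1.649545e-94 0.025267125     TRUE
#> 3 T2 V1     0    0.45358166  7.945991e-54 0.010058144     TRUE
#> 4 T1 T2     1 V1 0.68943601 2.280788e-157 0.006316781     TRUE
#> 5 T1 V1     1 T2 0.39527823  9.611027e-40 0.004686604     TRUE
#> 6 T2 V1     1 T1 0.02927463  3.554053e-01 0.003781354    FALSE

recallPrecision(truth, fittedGraph(fit))
#>    recall precision
#>         1         1
```

The ledger shows the whole decision history: three marginal tests (all
rejected under the early, generous LOND thresholds), then the conditional
tests; the partial correlation of T2 and V1 given T1 is 0.03 (p = 0.36),
so that edge is removed with separation set {T1}. PMR directs V1 → T1,
and the recorded conditional independence V1 ⟂ T2 | T1 identifies the
chain, orienting T1 → T2. Recall and precision of 1 mean the truth was
recovered exactly.

The same machinery is available from a shell:

```sh
Rscript inst/exec/mrnet.R simulate --model M1 --gamma 1.0 --n 1000 --seed 42 --out sim/
Rscript inst/exec/mrnet.R infer --input sim/data_001.tsv --n-genotypes 1 \
    --output graph.tsv --ledger ledger.tsv
Rscript inst/exec/mrnet.R sweep --model M2 --gammas 1.0,0.5,0.2 --reps 200 --seed 7
```

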