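# nhmc — network-aware predictive clustering trees for hierarchical multi-label classification

`nhmc` learns decision trees for **hierarchical multi-label
classification (HMC)**: prediction tasks where each example carries a
*set* of classes drawn from a tree- or DAG-structured hierarchy (FunCat
categories, Gene Ontology terms), subject to the hierarchical
constraint that any assigned class implies all of its ancestors. The
motivating application is gene function prediction in yeast, where a
protein–protein interaction (PPI) network links the examples and
interacting proteins tend to share function (guilt by association).

The learner is a **predictive clustering tree (PCT)**: internal nodes
hold attribute tests, leaves hold the mean class vector of their
training examples, read as per-class membership scores. What makes it
network-aware is the split heuristic. Each example's label set is a
binary vector L over the K classes, compared with the
hierarchy-weighted distance

    d(L1, L2) = sqrt( Σ_k ω(c_k) (L1,k − L2,k)² ),
    ω(c) = ω0 · avg_j ω(p_j(c)),   ω(top-level) = ω0,  0 < ω0 < 1,

so disagreement on shallow, general classes costs more than on deep,
specific ones. A candidate split of the node's examples U into U1, U2
is scored by

    h = α · [ Var′(U) − ( |U1| Var′(U1) + |U2| Var′(U2) ) / |U| ]
      + (1 − α) · [ |U1| A_Y(U1) + |U2| A_Y(U2) ] / |U|

where Var(U) = (1/|U|) Σ_i d(L_i, L̄)² is the class-vector variance
(min-max normalized over the candidate tests of the node, written
Var′), and A_Y is a network autocorrelation statistic adapted from
Geary's C to hierarchy-weighted label vectors:

    A_Y(U) = 1 − [ (N−1) Σ_i Σ_j w_ij d(L_i, L_j)² ]
                 / [ 4 Σ_i Σ_j w_ij · Σ_i d(L_i, L̄)² ]

with w_ij the network edge weights inside U. A_Y lives on [0, 1]: 1 is
strong positive autocorrelation (linked examples share labels), 0.5 is
none, 0 is strong negative. At α = 1 the learner degenerates exactly to
the classical variance-reduction PCT (no network influence); at α = 0
it splits purely to keep linked, like-labelled examples together. The
network is **training-time background knowledge only** — predictions
for new examples use attributes alone, so models apply to proteins with
no known interactions.

Pre-pruning uses a minimum leaf size (default 5) and an F-test on the
variance reduction of the chosen split; the significance level can be
fixed or selected from {0.001, 0.005, 0.01, 0.05, 0.1, 0.125} by
internal 3-fold cross-validation. Evaluation follows the standard HMC
protocol: per-class precision–recall curves over thresholds τ = 0,
0.02, …, 1 and their uniformly weighted average area (averaged AUPRC).

## Worked example

The package ships a synthetic benchmark generator that emulates all
three inputs — hierarchy, labelled attribute table, and a PPI-like
network with planted guilt-by-association structure — so the full
pipeline runs without any downloads:

```r
library(nhmc)

cfg   <- synth_config(n = 200, depth = 2, branching = 2,
                      p_in = 0.3, p_out = 0.01, seed = 42)
bench <- gen_benchmark(cfg)
bench$hierarchy
#> Class hierarchy (tree): 6 classes, 2 top-level, w0 = 0.75
bench$network
#> Example-linkage network: 194 nodes, 1552 edges (binary weights)

st <- partition_stats(bench$dataset$labels, bench$hierarchy$weights,
                      restrict(bench$network, bench$dataset$ids))
autocorrelation(st)
#> [1] 0.627

res <- holdout_protocol(bench$dataset, bench$network, alpha = 0.5,
                        significance = 0.05, seed = 42)
res$model
#> Predictive clustering tree for HMC
#>   classes: 6, training examples: 133
#>   alpha = 0.5, min_leaf = 5, F-test level = 0.05, heuristic = combined
#>   internal nodes: 10, leaves: 11
res$evaluation
#> HMC evaluation: averaged AUPRC = 0.5971 (uniform weights, 6 classes included, 0 excluded)
```

The measured A_Y of 0.627 (> 0.5) confirms the planted autocorrelation:
linked examples share labels more than chance. The model is trained on
a seeded 2/3 split with the network restricted to training ids, and
scored on the held-out third. The same protocol with α = 1 — identical
data, network ignored — yields an averaged AUPRC of 0.5746, below the
network-aware 0.5971:

```r
res1 <- holdout_protocol(bench$dataset, bench$network, alpha = 1,
                         significance = 0.05, seed = 42)
res1$evaluation$average
#> [1] 0.5746
```

## Command line

A thin CLI wraps the same functions (installed at
`system.file("exec/nhmc", package = "nhmc")`):

```sh
nhmc simulate --n 200 --seed 42 --data d.arff --network e.tsv
nhmc train    --data d.arff --network e.tsv --alpha 0.5 --model m.json
nhmc predict  --model m.json --data d.arff --scores s.tsv
nhmc evaluate --scores s.tsv --data d.arff --report r.json
nhmc netstats --data d.arff --network e.tsv
```

Datasets use the CLUS-style ARFF dialect with a `hierarchical` class
attribute (slash-delimited paths; `@`-separated class sets per row;
`?` for missing values); networks are whitespace-delimited edge lists;
models and reports are JSON. See `?read_arff_hmc`, `?load_edgelist`,
`?save_model`.

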