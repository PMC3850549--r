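---
title: "Methods: network-aware predictive clustering trees for HMC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-aware predictive clustering trees for HMC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nhmc)
```

# The task and the model

Hierarchical multi-label classification (HMC) assigns each example a
*set* of classes from a partially ordered hierarchy — a tree (FunCat-style
catalogues) or a DAG (Gene Ontology, where a term may have several
parents). The label sets obey the hierarchical constraint: a class
implies all its ancestors. We encode an example's labels as a binary
vector $L_i \in \{0,1\}^K$ over the $K$ classes, closed under
ancestors. The implicit virtual root is *not* a component: it is 1 for
every example and would contribute nothing to any distance or variance.

A predictive clustering tree (PCT) partitions the examples top-down;
each leaf stores the mean class vector $\bar L$ of its training
examples, whose $k$-th entry is read as the membership score of class
$c_k$ — the fraction of training examples at the leaf annotated with
$c_k$. Because every training vector is ancestor-closed, these scores
are automatically monotone along the hierarchy
(score(ancestor) $\ge$ score(descendant)), so thresholding at any
scalar $\tau$ yields an ancestor-closed prediction.

Label vectors are compared with a hierarchy-weighted Euclidean
distance,
$$d(L_1, L_2) = \sqrt{\textstyle\sum_k \omega(c_k)\,(L_{1,k}-L_{2,k})^2},$$
with class weights decaying with depth:
$\omega(c) = \omega_0 \cdot \mathrm{avg}_j\,\omega(p_j(c))$ over the
parents of $c$, $\omega(c) = \omega_0$ for top-level classes, and
$0<\omega_0<1$. The arithmetic mean (not min or max) over multiple
parents keeps the recursion linear and order-independent for DAGs. The
default $\omega_0 = 0.75$ is the long-standing convention in the
CLUS-HMC family; it keeps three hierarchy levels within one order of
magnitude of weight ($0.75, 0.56, 0.42$), matching the intuition that
mistakes on general functions matter more but specific functions still
count.

# The split heuristic

At a node with examples $U$, every candidate test splits $U$ into
$(U_1, U_2)$ and is scored by
$$h \;=\; \alpha\,\Big[\mathrm{Var}'(U) - \frac{|U_1|\,\mathrm{Var}'(U_1) + |U_2|\,\mathrm{Var}'(U_2)}{|U|}\Big]
\;+\; (1-\alpha)\,\frac{|U_1| A_Y(U_1) + |U_2| A_Y(U_2)}{|U|},$$
a convex combination of hierarchy-weighted variance reduction and
network autocorrelation. $\alpha = 1$ is the classical
variance-reduction PCT learner (the network is ignored and never
loaded); $\alpha = 0$ splits purely to maximize within-child
autocorrelation; the default $\alpha = 0.5$ weights both equally.

**Variance.** $\mathrm{Var}(U) = \frac{1}{|U|}\sum_i d(L_i,\bar L)^2$.
Because variances and autocorrelations are on different scales, each
$\mathrm{Var}(\cdot)$ entering $h$ is min-max normalized
($\mathrm{Var}'$). The normalization range is a genuinely open design
point: we take $\delta_{\min}, \delta_{\max}$ over the set
$\{\mathrm{Var}(U)\} \cup \{\mathrm{Var}(U_1), \mathrm{Var}(U_2)
: \text{all candidate tests at the node}\}$, computed in a first pass
before any test is scored. Normalizing each term (rather than the
reduction as a whole) keeps the $\alpha=1$ ranking identical to the raw
variance-reduction ranking, since the map is a positive affine
transformation shared by all candidates of the node — this is also what
makes the exact $\alpha=1$ degeneration testable.

**Autocorrelation.** For an undirected, non-negatively weighted network
$w_{ij}$ over the examples (a PPI network in the motivating
application),
$$A_Y(U) = 1 - \frac{(N-1)\sum_i\sum_j w_{ij}\, d(L_i,L_j)^2}
                   {4 \sum_i\sum_j w_{ij} \cdot \sum_i d(L_i, \bar L)^2},$$
a Geary-style statistic mapped onto $[0,1]$: 1 means linked examples
carry identical labels, 0.5 is the no-autocorrelation expectation
(verified empirically by the permutation test in the acceptance suite),
0 is strong negative autocorrelation. Only edges with both endpoints
inside the partition contribute; edges crossing a split boundary count
for neither child, which is the only reading consistent with evaluating
$A_Y(U_1)$ and $A_Y(U_2)$ per child. Degenerate partitions — no
internal edges, fewer than two examples, or zero label variance —
return the neutral 0.5, so the heuristic neither rewards nor punishes
partitions the network says nothing about. The raw formula can leave
$[0,1]$ on adversarial weight configurations; values are clamped to the
stated range.

The network influences **training only**. A fitted model contains the
tree, the hierarchy and the attribute schema — no network — and the
test suite asserts that a serialized and reloaded model predicts
bit-identically.

## Incremental computation

Evaluating every threshold of every attribute from scratch would cost
$O(N^2)$ per test. Instead each attribute is processed as a sweep: all
examples start in one side and move across one at a time in sorted
order, and both children's statistics are updated per move in
$O(\mathrm{degree} + K)$:

* per-class bit sums and sums of squares give the weighted sum of
  squared distances to the mean in closed form,
  $\sum_i d(L_i,\bar L)^2 = \sum_k \omega_k\,(S^{(2)}_k - S_k^2/n)$ —
  the standard one-pass variance identity applied per class and
  weighted;
* the edge sums $\sum w_{ij}$ and $\sum w_{ij} d(L_i,L_j)^2$ gain/lose
  the moving example's edge terms to members of the side it
  joins/leaves. Pairwise distances for connected pairs are precomputed
  once per node.

The test suite checks this machinery against a literal brute-force
double-loop implementation of the definitions on random partitions at
$10^{-9}$ relative tolerance, after arbitrary move sequences.

## Search space and tie-breaking

Continuous attributes contribute tests $X \le \beta$ with $\beta$ the
midpoints between consecutive distinct observed values ($b$ distinct
values, $b-1$ thresholds); missing values are excluded from threshold
computation. Discrete attributes contribute subset tests
$X \in B$ grown greedily: start from the best-scoring singleton and add
values while $h$ improves, never reaching the full domain. During the
greedy growth the variance term is normalized against the node variance
(the global $\delta$-range is only known after all candidates exist);
the chosen subsets are then re-scored in the global pass — a pragmatic
two-stage interpretation of using $h$ as the greedy criterion.

The best candidate wins by highest $h$; ties resolve to the lower
attribute index, then the lower threshold / earlier subset, implemented
by generating candidates in exactly that order and replacing the
incumbent only on strict improvement. Deterministic tie-breaking is
what allows the $\alpha=1$ tree to be compared node-for-node with the
variance-only learner.

**Missing values.** An example missing the test attribute follows the
child that received more non-missing training examples; the route is
stored in the node. During split *scoring*, missing-valued examples are
left out of the children's statistics (they carry no information about
the test) and are only routed after the test is chosen; leaf-size
constraints are checked on the final routed child sizes.

## Stopping

A node becomes a leaf when its labels are pure, when no admissible test
leaves both children with at least `min_leaf` training examples
(default 5), or when no candidate's variance reduction passes an F-test
at the configured significance level. We use the one-way ANOVA
convention for a binary split: with pooled child variance $v_c$ and
parent variance $v_p$ over $n$ examples,
$F = (n-2)(v_p - v_c)/v_c$ against the $F_{1,\,n-2}$ upper critical
value. This convention has the power appropriate to the setting: the
class-vector variance aggregates $K$ classes, and a single binary split
typically improves a few of them at a time, so conventions that demand
a large reduction of the *total* variance ratio (e.g. treating the two
variances as independent sample variances on $n-1$ and $n-2$ degrees of
freedom) reject essentially every split and collapse the tree to a
stump. The endpoints are convention-independent: no reduction is never
accepted, a perfect split (zero pooled child variance) always is, and
acceptance is monotone in the level. The F-test gates on variance
reduction only — not on $h$ — so even at small $\alpha$ a split must
demonstrably improve label homogeneity. Candidates failing the gate are
discarded before ranking. The level can be fixed or chosen from
{0.001, 0.005, 0.01, 0.05, 0.1, 0.125} by internal 3-fold
cross-validation maximizing averaged AUPRC (ties to the smaller level,
i.e. the stronger pruning).

# Prediction and evaluation

Scores are the reached leaf's prototype. `binarize()` predicts a class
when its score strictly exceeds $\tau$; scalar thresholds give
ancestor-closed sets by score monotonicity, and per-class threshold
maps are validated to be ancestor-monotone
($\tau_{\text{ancestor}} \le \tau_{\text{descendant}}$).

Per-class precision–recall curves are traced over the grid
$\tau = 0, 0.02, \ldots, 1$ — both endpoints included, 51 points.
Precision at zero predicted positives is defined as 1, the curve is
anchored at (recall 0, precision 1), and the area is the trapezoidal
integral over recall after de-duplication. Two consequences worth
knowing: (i) the finite grid slightly inflates areas near recall 0
(a constant score equal to the class prevalence $\pi$ scores
$(1+\pi)/2$, not $\pi$); (ii) the area is invariant only to monotone
score transforms that preserve the grid crossings. Classes with no
positive test example have an undefined curve and are excluded; the
uniform average weights each *included* class $1/|C|$. A
frequency-weighted average (weights proportional to positive counts) is
available for comparison.

`holdout_protocol()` implements the standard split: a seeded 2/3–1/3
partition (or explicit id lists, e.g. train on highly connected genes,
test on the rest), the network restricted to training ids before any
statistic is computed, and evaluation on the held-out third.

# The synthetic benchmark

`gen_benchmark()` emulates the three inputs:

* **Hierarchy** — a complete $b$-ary tree of depth $D$; with
  probability `dag_prob` a non-top class gains a second parent from the
  previous level, giving GO-like DAGs.
* **Labels** — top-down path sampling: each top-level class is kept
  with probability `pi_child`, each child with the same probability
  given its parent, then ancestor closure; a fraction `rho` of bits is
  flipped and re-closed (noise).
* **Attributes** — each class shifts a random subset of continuous
  attributes by `delta` over unit-variance Gaussian noise for its
  positives; discrete attributes are tilted towards a class-specific
  preferred category.
* **Network** — planted partition: pairs sharing at least one
  *most-specific* class are linked with probability `p_in`, all others
  with `p_out`. Tying edges to most-specific classes (not any shared
  ancestor) concentrates autocorrelation in the deepest labels, the
  regime where functional coherence in real PPI networks is local.

One global seed fans out to fixed per-component sub-seeds, so changing
the attribute count does not perturb the network draw, and everything
is bit-reproducible.

Default conditions — $n = 200$ examples, depth-2 binary hierarchy
(6 classes), 8 continuous + 2 discrete attributes, `delta = 1` (a
one-standard-deviation shift: informative but far from separable),
`p_in = 0.3`, `p_out = 0.01`, `rho = 0.05` — were chosen once as a
plausible desk-scale analogue of the motivating task: moderate
attribute signal, strong guilt-by-association, mild annotation noise.
The no-autocorrelation control uses `p_in = p_out = 0.08`, matching the
planted configuration's overall edge density. Test problem sizes
(tens to hundreds of examples, 10 replicate seeds for the directional
comparison, 1000 examples for the hierarchy-consistency sweep) are
sized so the whole suite exercises every code path in about two
minutes.

What the generator does **not** emulate: scale-free PPI degree
distributions, correlated attribute blocks, hierarchies with hundreds
of classes and extreme class imbalance, and systematically missing
attribute values. Passing the synthetic suite therefore demonstrates
the correctness of the machinery and the *direction* of the
network-autocorrelation benefit under planted guilt-by-association —
not performance levels on real gene-function data.

# Numerical and degenerate-input choices

* Min-max normalization of a constant vector returns all zeros (the
  variance term then contributes nothing at that node).
* $A_Y$ of an unsupported partition is 0.5 (neutral); $A_Y$ is clamped
  to $[0,1]$.
* Edge sums are floored at 0 after incremental subtraction to absorb
  floating-point cancellation drift.
* A constant or all-missing attribute contributes no tests; a dataset
  whose labels are pure yields a single-leaf tree.
* Duplicate network edges keep the maximum weight; self-loops are
  dropped with a warning; binary mode forces all weights to 1.
* Model JSON uses 17 significant digits, making
  save → load → predict bit-identical.
* Network "function-relevance" (the share of edges whose endpoints have
  at least one annotated class in common) counts shared classes over
  the full ancestor closure, excluding only the virtual root — the
  closure is what the learner actually sees, and the root is shared
  trivially.

# Known limitations

* Tree hierarchies only on the ARFF *writer* side would be a
  limitation; instead DAGs are serialized as one slash-path per
  parent-child edge, which round-trips but is more verbose than a
  dedicated DAG format.
* The discrete greedy subset search is deliberately non-optimal (its
  provisional normalization differs from the final global one), which
  can miss the best subset on attributes with many categories.
* No post-pruning, ensembles, multi-way splits, or regression targets.
* PR areas inherit the threshold-grid artifacts described above; with
  very few test examples per class the grid resolution dominates.
* The per-node two-pass evaluation stores per-candidate child
  statistics; nodes with millions of candidate thresholds would need
  the streaming variant (keeping only the running $\delta$ range and
  re-sweeping), which this implementation does not include.
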