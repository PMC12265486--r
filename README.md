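# j1balance

Tree balance quantifies how evenly a rooted tree distributes its leaves
(or, more generally, its node sizes) among its branches. Biologists use
balance indices to compare phylogenies and clone trees against
null models of evolution; computer scientists use the same underlying
quantity — via weight-balanced search trees and Huffman coding — to keep
path lengths short. Classical biological indices (Sackin, Colless) break
down as soon as trees differ in outdegree distribution or carry node
sizes. `j1balance` implements the index that does not: the universal
tree balance index **J1**, defined for any rooted tree with non-negative
node sizes as the weighted mean of per-node normalized Shannon entropy
scores,

    J1(T) = ( Σ_{i∈Ṽ} S*_i · W_i ) / ( Σ_{i∈Ṽ} S*_i ),
    W_i   = Σ_{j∈C(i)} −(S_j/S*_i) · log_{d⁺(i)} (S_j/S*_i),

where `S*_i` is the size sum of node `i`'s descendants, `d⁺(i)` its
outdegree (outdegree-1 nodes score 0), and `Ṽ` the internal nodes with
positively sized descendants. `J1 ∈ [0,1]`; it is 0 exactly on chains
and 1 exactly when every split is into equal-magnitude subtrees.

The package is aimed at researchers who need J1 values for real trees
plus the reference points that make them interpretable:

* **Core index** — `j_one()`, `balance_report()`, `sackin()`,
  `generalized_sackin()`, `node_balance()` on size-annotated trees;
  Newick I/O with an NHX-style `[&&NHX:size=x]` dialect
  (`parse_newick()`, `write_newick()`).
* **Null models** — exact shape enumeration and exact `E[J1]` under the
  Yule and uniform (PDA) models (`yule_shape_distribution()`,
  `exact_expected_j1()`), closed-form first/second-order approximations
  and their Jensen gaps (`expected_sackin()`, `jensen_gap()`), and
  seeded samplers with Monte Carlo moments (`sample_yule()`,
  `sample_uniform()`, `monte_carlo_moments()`).
* **Extremal analysis** — Huffman construction of the maximally balanced
  bifurcating tree for given leaf sizes (`huffman_tree()`,
  `verify_optimality()`), and the minimally balanced *broom* trees:
  closed form `jb1(n, k, p)`, minimizer `kstar()`, region classification
  `classify_region()`, crossover and asymptotic checks, plus the
  exhaustive `min_balance_search()` over all series-reduced shapes.

## Worked example

```r
library(j1balance)

# a four-leaf tree, two leaves carrying explicit sizes
tr <- parse_newick("((A[&&NHX:size=4],B[&&NHX:size=2]),(C,D));")
balance_report(tr)
#> J1 = 0.875  Sackin = 8  generalized Sackin = 16
```

The root splits its descendants 6 against 2 (entropy score 0.81), the
(A,B) node 4 against 2 (0.92), the (C,D) cherry evenly (1.00); weighting
the scores by the subtree magnitudes 8, 6, 2 gives J1 = 0.875, below the
maximum 1 that a perfectly even size assignment would reach.

Reference points for a 9-leaf tree with equal leaves:

```r
j_one(build_fixture("caterpillar", 9))   # least balanced bifurcating: 0.6484
kstar(9, 1)                               # least balanced overall is a broom
#> k_star = 5, r_star = 0.556, jb1_min = 0.6263, region = "R2"
jensen_gap("yule", 8)                     # exact vs first-order E[J1]
#> exact 0.879153, approx 0.873181, gap 0.005972
monte_carlo_moments("yule", 8, 1e5, seed = 1)
#> mean J1 = 0.879223 (SE 0.00022)  mean IS = 27.4826  var IS = 5.46387
```

So a 9-leaf caterpillar (J1 = 0.648) is *not* the least balanced
9-leaf tree once multifurcations are allowed: the broom with a 5-leaf
star head reaches 0.626 — `min_balance_search(9)` finds the same tree by
exhaustion. And a Yule-typical 8-leaf tree sits near 0.879, which the
closed-form approximation matches to within the Jensen gap 0.006.

Maximal balance for unequal leaf sizes comes from Huffman merging:

```r
h <- huffman_tree(c(4, 2, 1, 1))
write_newick(h)
#> (t1[&&NHX:size=4],(t2[&&NHX:size=2],(t3,t4)));
j_one(h)                # 1 — every split is equal-magnitude
generalized_sackin(h)   # 14, the minimal weighted path length
```

A thin command-line wrapper covers the same ground
(`exec/j1balance compute|sample|expect|gap|broom|minsearch|huffman`),
e.g. `j1balance gap --model yule --n 4`.

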