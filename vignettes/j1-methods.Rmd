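---
title: "Methods: the universal tree balance index J1, its null-model expectations, and minimally balanced trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the universal tree balance index J1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(j1balance)
```

## The index

A rooted tree carries a non-negative size $w_i$ on every node; in the
*leafy* (cladogram) convention internal nodes have size zero and leaves
carry the population they represent. Write $S_i$ for the magnitude (size
sum) of the subtree at node $i$, $S_i^*$ for the same sum excluding $i$
itself, and $d^+(i)$ for the outdegree. The balance score of an internal
node is the normalized Shannon entropy of its child subtree magnitudes,

$$W_i = \sum_{j \in C(i)} -\frac{S_j}{S_i^*}
  \log_{d^+(i)} \frac{S_j}{S_i^*}, \qquad d^+(i) > 1,$$

with $W_i = 0$ for outdegree-1 nodes and the convention
$0 \log 0 = 0$. The index is the weighted mean of these scores over
$\tilde V(T)$, the internal nodes whose descendants are not all of zero
size, with weights $g_i = S_i^*$:

$$J_1(T) = \frac{\sum_{i \in \tilde V} S_i^* W_i}
  {\sum_{i \in \tilde V} S_i^*}.$$

The normalizing factor is the generalized Sackin index (weighted path
length) $I_{S,\mathrm{gen}} = \sum_i w_i \nu(i)$, with $\nu$ the node
depth. $J_1$ lies in $[0, 1]$ for every rooted tree, regardless of
degree distribution or node sizes, which is what makes it usable where
classical indices (Sackin, Colless) are not: those are comparable only
within a fixed outdegree regime.

Two structural facts drive everything else in the package.

* **Extremes.** $J_1 = 0$ exactly on linear (chain) trees — an
  outdegree-1 node keeps its weight $S_i^*$ while scoring zero, which is
  easy to get wrong in an implementation; `j_one()` therefore includes
  such nodes in the weighted mean rather than skipping them. $J_1 = 1$
  exactly when every node of $\tilde V$ splits its descendants into at
  least two equal-magnitude subtrees.
* **The leafy tree identity.** On leafy full $m$-ary trees,
  $J_1 = H_m(T)\, S(T) / I_{S,\mathrm{gen}}(T)$ with $H_m$ the base-$m$
  entropy of the relative leaf sizes; with $n$ equal leaves this
  collapses to $J_1 = n \log_m n / I_S$. The identity turns expectations
  of $J_1$ under bifurcating null models into expectations of $1/I_S$,
  and it is what links maximal balance to minimal weighted path length —
  hence to Huffman coding (`huffman_tree()` maximizes $J_1$ for a given
  leaf size multiset because Huffman merging minimizes
  $I_{S,\mathrm{gen}}$; `verify_optimality()` confirms this by
  exhaustion for up to 7 leaves).

## Exact null-model expectations

The two standard null models generate unit-leaf leafy bifurcating trees:
the Yule process grows a cherry by repeatedly replacing a uniformly
chosen leaf with a cherry; the uniform (PDA) model makes every
leaf-labelled topology equally likely.

`yule_shape_distribution()` runs the growth process as an exact dynamic
program over unlabelled shapes. Transitions are applied per leaf (each
leaf of a $j$-leaf shape is replaced with probability $1/j$ and the
resulting shapes are grouped by canonical key), which is arithmetically
identical to grouping leaves into automorphism orbits first.
Probabilities are kept as integer numerators over the common denominator
$2 \cdot 3 \cdots (n-1)$; under the uniform model the probability of a
shape with $s$ symmetric internal nodes is $2^{\,n-1-s}/C_{n-1}$
(Catalan denominator). All of these integers stay far below $2^{53}$
within the enumeration caps, so holding them in doubles is exact — R has
no rational type in this package's dependency set, and none is needed at
these sizes. Each distribution is verified in the test suite against an
independent closed form (for Yule,
$P(\text{shape}) = 2^{\,n-1-s} \prod_v 1/(\lambda_v - 1)$ over internal
subtree leaf counts $\lambda_v$; for the uniform model, the
labelled-topology weighting $(n!/2^s)/(2n-3)!!$).

The exact expectation is then
$E[J_1] = n \log_2 n \cdot E[1/I_S]$; the reciprocal moment is
accumulated in double precision from the exact rationals, a relative
error around $10^{-15}$, three orders of magnitude below anything
compared against it. The first-order approximation replaces the harmonic
mean by the arithmetic mean, using the closed forms
$E_Y[I_S] = 2n(H_n - 1)$ and
$E_U[I_S] = n\!\left((2n-2)!!/(2n-3)!! - 1\right)$; the double-factorial
ratio is accumulated as $\prod (2i)/(2i-1)$, whose factors are near 1,
so it cannot overflow (a log-gamma form takes over past $n = 10^5$).
The error of the first-order approximation is the Jensen gap
$J(n) = E[J_1] - n\log_2 n/E[I_S] \ge 0$. The second-order form adds
$n \log_2 n\, V[I_S]/E[I_S]^3$; at small $n$ it can slightly overshoot
the exact value but it stays within the gap bound and always improves on
first order, which is what the tests assert. The asymptotic Yule value
is $1/(2\ln 2) \approx 0.72$.

Problem sizes: exact enumeration runs to $n = 11$ (Yule, 207 shapes) and
$n = 10$ (uniform), where the gap maxima occur at the top of the range;
the enumeration caps (16 for bifurcating shapes, 12 for the
series-reduced catalogue) keep a full run within a couple of minutes on
one CPU, with the gap computations themselves taking seconds.

## Samplers

`sample_yule()` implements the growth process with an $O(1)$ flat leaf
array; `sample_uniform()` uses Rémy-style node insertion, which is
equivalent in distribution to the random bracket-sequence construction.
Hot loops are compiled, but all randomness is drawn from R's RNG
(Mersenne-Twister), so a single `set.seed()` — or the `seed` argument of
the batch functions — determines every stream identically across
platforms. We use one stream per run rather than per-replicate
substreams: replicates are consumed in a fixed order, so the determinism
contract (same seed, same output, tested byte-for-byte) holds without
jump-ahead machinery. Default replicate count is $10^5$, which places
Monte Carlo standard errors well below the scales compared against
(closed forms and exact enumerations agree within 3 SE in the tests);
larger runs are a parameter away.

What the samplers emulate — and what they do not: both models generate
*topologies only*. Real phylogenies and clone trees carry branch
lengths, non-uniform node sizes, and outdegree-1 chains from sampling
artifacts; passing the null-model tests says nothing about robustness to
those features (robustness of $J_1$ itself to size perturbations is a
property of the index, not of these tests).

## Minimal balance and broom trees

Among bifurcating leafy trees with equal leaves the caterpillar
minimizes $J_1$ (it maximizes $I_S$, and the identity does the rest —
asserted over the full catalogue). Once larger outdegrees are allowed
the minimizer is a *broom*: a bifurcating handle ending in a star head
of $k$ leaves of relative size $p$. The closed form

$$J_1^B(n,k,p) = \frac{2\,[kp + (kp+n-k)\log_2(kp+n-k) -
  kp\log_2 kp]}{(2kp+n-k)(n-k+1)}$$

is re-derived by telescoping the handle contributions of the defining
weighted mean; the printed source formula is typographically flattened,
so the reading implemented here is pinned down by two independent
checks: it reduces at $p = 1$ to
$2(n\log_2 n - k\log_2 k + k)/((n+k)(n-k+1))$, and it matches
`j_one(build_fixture("broom", n, k, p))` to $10^{-10}$ over random
$(n, k, p)$. The same disambiguation-by-oracle approach fixes
$\theta(k,p) = 2/(kp) + k(1-p)$, whose sign against $n$ gives the
monotonicity of $J_1^B$ in $p$ (checked by finite differences on both
sides).

`kstar()` scans $k = 2, \dots, n-1$: the star $k = n$ has
$J_1^B = 1$, the maximum, so admitting it would never change the argmin
and only muddy the region classification. The exhaustive search
`min_balance_search()` (series-reduced shapes, $n \le 12$, 21 965 shapes
at the cap) confirms that the global minimizer is always a broom in this
range and agrees with the closed-form scan at $p = 1$.

The caterpillar/broom crossover — the continuous root of
$J_1^B(n,2,1) = J_1^B(n,3,1)$ — is located by bisection at
$n^* = 4.1858\ldots$; the unique integer $n > 3$ below it is 4, which is
why the caterpillar is the global minimizer exactly for $n \le 4$.
Region boundaries in $(n, p)$ space are located by bisection in
$\log p$ on the integer switch of $k^*$, to relative tolerance
$10^{-6}$; the asymptotes $p = 2/n^2$ and $p = n^2\log_2 n/3$ are
order-of-magnitude guides at small $n$ (at $n = 7$ the upper switch sits
near $p \approx 22$, well below the asymptote's 45.9) and tighten to
within tens of percent by $n \approx 50$. For the large-head regime
($p > 1/2$) the convergence of $\min_k J_1^B$ to $\log_2(n)/(np)$
carries slowly vanishing corrections of order $1/\sqrt{\log_2 n}$; the
package therefore reports empirical ratios and decay factors rather than
asserting a sharp constant, and the tests check monotone decay toward 1
together with the $(1-r^*)\sqrt{\log_2 n}$ plateau. The fixed-$n$
extreme-$p$ limits are sharp and are asserted at 1%:
$J_1^B(n,k^*,p)(n-1) \to 1$ as $p \to \infty$ and
$J_1^B(n,k^*,p)/(p(1-n)\log_2 p) \to 1$ as $p \to 0$.

Over $p$ the minimal broom balance is maximized exactly where
$n = \theta(2,p)$, i.e. at the positive root of
$2p^2 + (n-2)p - 1 = 0$; `max_min_over_p()` returns that root and the
value $\min_k J_1^B(n,k,p^*)$, verified as a maximum by grid scan.

## Numerical choices and degenerate inputs

* Logarithms to base $d^+(i)$ are computed as `log(x)/log(d)`;
  double-precision comparisons in tests use $10^{-10}$ tolerances
  ($10^{-12}$ where the quantity is a short exact sum).
* Zero-magnitude children contribute zero entropy terms; nodes with
  $S_i^* = 0$ are excluded from $\tilde V$, and asking for their balance
  score is an error rather than a silent `NaN`.
* A tree whose every internal node has zero descendant magnitude (or a
  single node) has no defined $J_1$; `j_one()` refuses it.
* Ties in `kstar()` and `min_balance_search()` are broken toward the
  smallest $k$ / lexicographically smallest canonical key, and all ties
  are reported.
* Newick sizes ride in NHX-style comments (`[&&NHX:size=x]`) so they
  cannot collide with the branch-length colon field; branch lengths are
  parsed and discarded, since the index is a function of topology and
  sizes only. Sizes are stored as doubles; decimal annotations
  round-trip exactly through the writer's repr-style formatting.
* The canonical shape key sorts child encodings in the C locale
  (`method = "radix"`), making it a deterministic total order; equality
  of keys coincides with brute-force rooted isomorphism on the full
  catalogue up to 7 leaves (tested).

## Limitations

Branch lengths, unrooted trees, and phylogenetic networks are out of
scope, as are other members of the index family with different
importance factors. Exact enumeration is capped as above; beyond the
caps the closed forms and samplers are the available tools. The
asymptotic-distribution approximation for the uniform model and the
$m$-ary Yule generalization are not implemented.
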