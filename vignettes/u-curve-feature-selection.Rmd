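---
title: "Partitioned U-curve search for feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned U-curve search for feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucurve)
```

## The problem and the model

Feature selection for classifier design asks for a subset $X$ of a feature
set $S$ minimizing a cost function $c : \mathcal{P}(S) \to \mathbb{R}_{\ge 0}$
over the Boolean lattice $(\mathcal{P}(S), \subseteq)$ of all $2^{|S|}$
subsets. Because adding features first adds information and then — once the
sample size can no longer populate the larger feature space — adds estimation
error, the costs along any chain
$\emptyset \subseteq \{s_1\} \subseteq \dots \subseteq S$ typically dip and
then rise. A cost function is *decomposable in U-shaped curves* when every
chain triple $X_1 \subseteq X_2 \subseteq X_3$ satisfies
$c(X_2) \le \max\{c(X_1), c(X_3)\}$. Minimizing such a cost is the U-curve
problem; it is NP-hard (the subset-sum problem reduces to it), so all exact
algorithms are worst-case exponential and the practical question is how much
of the lattice a search can prune and how well the work parallelizes.

This package implements a partitioned search. Choose a *fixed set*
$S' \subseteq S$; its complement is the *free set*. The subsets of $S'$ form
the **outer** Boolean lattice, and every outer element $X$ anchors an
**inner** Boolean lattice $\{X \cup Y : Y \subseteq \bar{S'}\}$, isomorphic
to $\mathcal{P}(\bar{S'})$. The $2^{|S'|}$ inner lattices are pairwise
disjoint and cover $\mathcal{P}(S)$. Costs inside an inner lattice are
evaluated through the wrapper $c_X(Y) = c(X \cup Y)$.

Two facts license pruning during a walk on the outer lattice, for adjacent
outer elements $X \subseteq Y$:

* if $c(X) < c(Y)$, no element of $[Y, S]$ can beat $c(X)$ (costs above a
  strict increase stay above it on a U-decomposable cost), so the whole
  interval is discarded;
* dually, if $c(X \cup \bar{S'}) > c(Y \cup \bar{S'})$, the interval
  $[\emptyset, X \cup \bar{S'}]$ is discarded.

The search therefore proceeds in two phases: a coordinator walks the outer
lattice, popping random start elements from the store of unexplored outer
elements, probing each visited element's *floor* $c(X)$ and *ceiling*
$c(X \cup \bar{S'})$, testing the two rules on every adjacent pair (in the
pseudocode's strict branch order — ceiling test before floor test on the
upward side, floor before ceiling on the downward side), and removing the
licensed intervals from the search space; then the inner lattices anchored
at the surviving explored elements are solved independently — recursively by
the same procedure down to a depth limit, and at the leaves by a pluggable
base algorithm. Independence of the inner problems is what makes the
algorithm parallel: workers receive whole inner lattices and return their
evaluation ledgers, which are merged.

## Cost functions

**Subset-sum costs.** For weights $w$ and a target $t$,
$c(X) = |t - \sum_{x \in X} w_x|$. Every such cost is U-decomposable, and a
subset hits cost 0 exactly when it solves the subset-sum instance — these
are the "hard but well-behaved" synthetic benchmarks, generated by
`gen_subset_sum_instance()` (weights uniform on $\{0, \dots, 10n\}$, target
uniform on $\{0, \dots, \sum w\}$; the distribution of the random integers
is the package's choice — it keeps optima away from both lattice ends).

**Penalized mean conditional entropy.** For discrete labelled samples the
criterion is the estimated expectation of the conditional Shannon entropy
of the label given the realization of the selected features,

$$\hat{c}(X) = \frac{N}{t} + \sum_{x\,:\,\hat{P}(x) > 1/t}
  \hat{H}(Y \mid \mathbf{X} = x)\, \hat{P}(x),$$

where $t$ is the sample count and $N$ the number of samples whose projected
realization occurs exactly once: realizations seen once carry no usable
label distribution, so they are charged the maximal entropy 1, as if their
label were uniform. Two numerical conventions matter:

* the entropy logarithm is taken in base $|L|$, the number of classes, so
  the uniform distribution has entropy exactly 1 and each singleton
  realization contributes exactly $1/t$ — with a base-2 logarithm and more
  than two classes the stated "maximal entropy" charge would be understated;
* "$\hat{P}(x) > 1/t$" is read strictly: counts are integers, so
  realizations observed once are penalized and realizations observed at
  least twice enter the entropy sum; ties are impossible.

Features must be discrete; continuous inputs are discretized upstream, and
the package deliberately takes no position on the discretization scheme.

### What the estimator does and does not reward

The singleton penalty is the estimator's only guard against overfitting.
Realizations observed two or more times still contribute a *plug-in*
entropy estimate, which is biased downward in small cells. Consequences,
measured with this package's own exhaustive searches on planted synthetic
tables: with clean or nearly clean labels the planted subset scores at or
near 0 and adding noise features raises the criterion, but once label noise
pushes the true conditional entropy up (≈ 0.1 flip probability and beyond),
splitting cells lowers the *estimated* entropy faster than the penalty
grows, and the minimizer becomes a strict superset of the planted features.
The planted features themselves are always selected (with a parity label no
proper subset carries signal); what cannot be guaranteed at realistic
sample sizes is that nothing else is selected. The tests assert exactly
these two regimes and nothing stronger.

## The synthetic-data generator

`gen_mce_dataset()` emulates classifier-design training data of the
windowed-image kind: feature vectors are uniform random bits, the label is
a fixed Boolean function (parity by default — fully multivariate, the case
correlation-based criteria miss; majority as the alternative) of `k`
planted features, and the label is flipped with probability `noise_rate`
(default 0.3, matching the salt-and-pepper corruption regime the criterion
was designed for). What it does not emulate: spatial correlation between
window positions, non-uniform feature marginals, and feature-side noise —
so a passing test says the search and the estimator behave as specified on
well-posed tables, not that the criterion ranks real image windows the
same way.

## Parameters

* `p` — proportion of features fixed; the fixed-set size is
  $\lceil p\,n \rceil$. Small instances (≤ 25 features) default to
  `p = 0.5`; big instances to `p = 10/n`, capping the outer lattice at
  1024 elements. Finer partitions visit more subsets (better solutions
  with a suboptimal base, more time), coarser ones parallelize less.
* `l` — maximum recursion depth, default 1: inner lattices go straight to
  the base algorithm. Recursion re-derives the fixed-set size from the
  current free set and bottoms out at `l` or when a free set has at most
  one element.
* `base` — the leaf solver: `ubb` (optimal on U-decomposable costs) for
  small instances, `sfs` for big ones; `es` and `sffs` (with its `delta`
  margin, default 3) are also available.
* `seed` — drives every random choice (which features are fixed, walk
  start elements, adjacency order) through a private RNG stream; the
  global RNG state is never touched. The minima are invariant to
  `workers`.
* `workers` — processes used to solve surviving inner lattices; ledgers
  are merged afterwards, and the reported call count is the size of the
  merged ledger (memo hits are never counted twice).

## Design choices where the design was open

* **Which features become fixed points** is not prescribed beyond "choose
  a fixed set": the package draws them uniformly at random with the run's
  seed, consistent with the random-choice policy used for walk starts and
  adjacency order, and accepts an explicit override (`fixed =`).
* **The UBB base algorithm** is specified here only by its contract
  (simple, optimal under the U-curve property). The implementation
  enumerates the power set as a spanning tree (children append features
  above the parent's highest index, so each subset is generated once) and
  prunes a child's subtree whenever the cost strictly increases into the
  child — sound for the same reason the walk's upset rule is sound. Its
  call counts are therefore implementation-specific, and no parity with
  any published count is claimed.
* **SFS stopping and ties**: stop when no single addition strictly
  improves the best cost seen; ties break toward the lowest feature
  index, making all sequential searches deterministic.
* **Store realization**: the unexplored outer-lattice family is held in a
  reduced ordered binary decision diagram; the initial full family costs
  O(1), interval removal is a conjunction with a negated cube, membership
  is a root-to-terminal walk, and pops draw uniformly via model counting.
  Any structure with explicit-set semantics would be conforming — the
  behavioural test suite, not the data structure, is the contract.
* **Per-worker ledgers** merged after the inner solves (rather than a
  shared concurrent memo): merging preserves correctness because costs
  are deterministic, keeps the distinct-call count well defined, and
  needs no cross-worker synchronization.

## Numerical conventions and degenerate inputs

Pruning tests use strict inequalities, so cost comparisons must not flip
on floating-point noise: integer-valued costs compare exactly and
real-valued costs with a $10^{-12}$ relative tolerance. `p = 1` (outer
lattice = whole lattice, singleton inner lattices) and single-feature
ground sets run through the same code paths. On costs that are *not*
U-decomposable the pruning rules can discard true minima — the returned
best cost is always the minimum over everything actually evaluated, and
never below the true optimum's cost by construction; only plain
exhaustive search is oscillation-proof. The *oscillation count* — ordered
consecutive-cardinality triples with $c(X_2) > \max\{c(X_1), c(X_3)\}$,
reported per lattice element as count$/2^n$ — quantifies how far a given
instance departs from the assumption.

## Problem sizes used in the tests

The suite verifies optimality of the partitioned search against the
exhaustive oracle on 200 random subset-sum instances with 4–12 features,
pruning soundness against full enumeration on the same pool, store
behaviour against an explicit-set oracle on 1000 random operation
histories up to dimension 10, call accounting at $2^7$ and $2^{17}$, and
the suboptimal-regime ordering (partitioned SFS versus plain SFS) on 50
instances with 30 features. These sizes exercise every code path —
partitioning, pruning, recursion, parallel merge — while each individual
check stays well under a minute; the 30-feature batch, the largest, runs
the big-instance defaults end to end.

## Known limitations

* Optimality is conditional on the U-curve property; real-data criteria
  oscillate, and robustness there is empirical, not guaranteed.
* The penalized MCE estimator's superset bias (above) is a property of
  the printed formula; stronger penalties (e.g. charging all
  small-count cells) would change the selected subsets and are out of
  scope.
* The BDD store is single-threaded and owned by the coordinator; only
  inner-lattice solving is parallel. Concurrent multi-walk exploration is
  not implemented.
* Wall-clock comparisons across algorithms are reported by the benchmark
  harness but are hardware-bound; distinct cost-function calls are the
  portable work measure.
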