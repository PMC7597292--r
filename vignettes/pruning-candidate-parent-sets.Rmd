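---
title: "Pruning candidate parent sets in Bayesian network structure learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pruning candidate parent sets in Bayesian network structure learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnprune)
```

## The model and the score

A discrete Bayesian network factorises the joint distribution of variables
$X_1,\dots,X_n$ as $\prod_i P(X_i \mid \Pi_i)$, where $\Pi_i$ is the parent
set that the DAG $G$ assigns to $X_i$. `bnprune` learns $G$ from complete
multinomial data by maximising the BDeu score, the log marginal likelihood of
the data under symmetric Dirichlet priors with equivalent sample size
$\alpha$:

$$S(i, \Pi_i) = \sum_{j=1}^{q_i}\left[\ln\Gamma\!\left(\tfrac{\alpha}{q_i}\right)
  - \ln\Gamma\!\left(\tfrac{\alpha}{q_i} + N_{ij}\right)\right]
  + \sum_{j=1}^{q_i}\sum_{k=1}^{r_i}\left[\ln\Gamma\!\left(\tfrac{\alpha}{q_i r_i} + N_{ijk}\right)
  - \ln\Gamma\!\left(\tfrac{\alpha}{q_i r_i}\right)\right]$$

with $r_i$ the child's arity, $q_i$ the number of joint parent
configurations, $N_{ijk}$ the count of child state $k$ under configuration
$j$, and $N_{ij} = \sum_k N_{ijk}$. The graph score is the decomposable sum
$\sum_i S(i,\Pi_i)$, which is what turns structure learning into a
combinatorial optimisation over per-node *candidate parent sets* (CPSs):
score every admissible $(i, \Pi_i)$ pair once, then search for the
maximum-score acyclic assignment.

Two conventions are fixed in this implementation:

* $q_i$ counts **all** $\prod_{p \in \Pi_i} r_p$ parent configurations,
  observed or not. Some implementations count only observed configurations;
  the two disagree on sparse data, so the choice is documented and fixed.
  Unobserved configurations contribute nothing to the sums but do set the
  prior cell sizes $\alpha/q_i$.
* All scores are natural-log valued, finite and $\le 0$; comparisons are
  exact floating-point comparisons with no tolerance. Ties are resolved
  structurally everywhere (below), never by score perturbation.

BDeu is likelihood-equivalent: DAGs in the same Markov equivalence class
receive the same total score (the test suite checks this on 2- and 3-node
classes). The default $\alpha = 1$ follows common practice in
GOBNILP-compatible tooling; it is exposed as `ess` on every scoring entry
point since the score — and hence how aggressively small parent sets
dominate — depends on it.

## Why prune candidate parent sets

With $n$ variables and maximum in-degree $d$ there are
$n\sum_{k=0}^{d}\binom{n-1}{k}$ CPSs (`count_possible_cps()`), e.g. 16.18
million for $n = 100$, $d = 3$, while the number of DAGs themselves grows
super-exponentially (`dag_count()`, the Robinson recurrence — about
$4.2\times10^{18}$ at $n = 10$). Order-based search narrows the space to the
$2^{n(n-1)/2}$ structures consistent with node orderings
(`order_structure_count()`), but the CPS tables are still the memory and
time bottleneck. Two pruning stages address this:

**Legality pruning** (`legal_prune()`). A parent set $P$ of node $i$ cannot
occur in any optimal DAG if some proper subset $Q \subset P$ has
$S(i,Q) \ge S(i,P)$: replacing $P$ by $Q$ never lowers the total and only
removes arcs, which cannot create a cycle. The comparison is deliberately
non-strict — on a tie the smaller set dominates — which is score-safe and
yields sparser graphs. Survivors are the *legal* CPSs. This pruning is
exact: the test suite verifies on the embedded four-node example and on
hundreds of random score sets that the optimum over legal CPSs equals the
optimum over all CPSs.

**Percentage pruning** (`percent_prune()`). Each node's legal list, sorted
by descending score, is truncated to its top
$\lceil (1 - p/100)\,m \rceil$ entries (never fewer than one). This is a
heuristic: it can remove sets that the optimal DAG needs, and the point of
the package is to measure that loss. Two guard rails are built in: the
rounding is $\lceil\cdot\rceil$ (the rule keeps at least the single best
entry even at $p = 99$), and the empty parent set is force-retained at every
level — any DAG needs at least one root, and search must always be able to
make a node a root. Both choices are deliberate: the keep-count rounding is
otherwise unconstrained, and dropping the empty set can make search
infeasible outright.

Sorting, and therefore what "bottom-ranked" means, is deterministic: score
descending, then fewer parents, then lexicographically by parent indices.
This makes pruning and every search engine reproducible across runs and
across CPS line orderings in score files.

## Loss measurement

The cost of pruning is the discrepancy of the pruned-search score $S$
against a baseline $S^\ast$ from the same engine without percentage pruning:

$$\Delta = (S^\ast - S)/S^\ast.$$

Scores are negative, so a worse (more negative) $S$ gives $\Delta < 0$;
results are conventionally printed in per mille (`format_permille()`, two
decimals). `pruning_curve()` runs the sweep: level 0 is always included to
define $S^\ast$, and with the exact engine the curve is provably monotone —
the feasible set at a higher level is nested inside the lower one (up to the
re-appended empty set). Whether the designated baseline is itself a global
optimum is unknowable for large networks when $S^\ast$ comes from a
truncated approximate run; $\Delta$ is always relative to the baseline the
user designates. `time_to_best`-style timings are recorded in the curve
output for orientation but never asserted in tests, being
hardware-dependent.

## Search engines

* `exact_dp()` — dynamic programming over variable subsets: first the best
  table entry for each (node, allowed-predecessor-set) pair by a subset-max
  sweep, then the best sink for every subset. Exact over the given score
  tables; memory is $O(n 2^n)$, capped at $n = 20$ by default.
* `exhaustive_search()` — depth-first enumeration of one table entry per
  node with cycle pruning and an admissible score bound; restricted to
  $n \le 5$. It exists as an independent oracle for the other engines and is
  kept in the package rather than the test code so that users can run the
  same cross-check.
* `greedy_search()` — a constructive pass: nodes in descending order of
  potential gain (best minus empty score), each taking its best CPS that
  keeps the graph acyclic. The iteration order and the "next best non-cyclic
  CPS" fallback are concrete choices among several faithful readings of a
  constructive CPS iteration; they are documented here as this package's
  instantiation.
* `order_best_network()` / `order_local_search()` — order-based search:
  given an ordering, each node takes its best CPS among its predecessors;
  the local search hill-climbs over adjacent transpositions
  (first-improvement, re-scoring only the two swapped positions) from seeded
  random restarts. This neighbourhood is the simplest reproducible choice;
  memetic/genetic operators of large-scale order-based engines are out of
  scope. All stochasticity flows from one integer seed, and identical seeds
  give identical results.

Tie-breaking is uniform across engines — higher score, then fewer parents,
then lexicographic — realised by the table sort order, so "first match in
table order" is always the preferred candidate. Every engine returns a
`bnsl` object whose total equals `graph_score()` of its parent assignment,
and any acyclic assignment necessarily contains a root node.

## Synthetic data: what it emulates, what it does not

`random_dag()` draws a uniform node ordering and includes predecessor edges
independently (default `edge_prob = 0.5`, truncated to the in-degree bound
by keeping the most recent predecessors); `random_cpts()` draws each
conditional distribution from a symmetric Dirichlet (default concentration
0.5 — informative, learnable dependencies; arities default to 2);
`forward_sample()` generates multinomial data by ancestral sampling. These
defaults are the package's study conditions and are used unchanged by the
test suite and the acceptance script.

One generator choice deserves emphasis. Pure low-concentration Dirichlet
rows routinely produce *effectively constant* variables (e.g. a state
probability of $1 - 10^{-7}$), and independently drawn rows give a
substantial fraction of arcs near-zero effect size. A variable that never
changes state, or an arc that barely shifts its child's conditional
distribution, is unidentifiable at any sample size — no method could recover
it. `random_cpts()` therefore floors every state probability at `min_prob`
(default 0.05, renormalised; 0 disables), and the structure-recovery smoke
test additionally screens its ground truths for identifiability — every arc
must shift its child's conditionals by at least 0.15 total variation — with
the screen computed from the true CPTs *before* any data are sampled.

What passing tests on this generator do **not** show: real categorical data
have skewed marginals, context-specific independence, near-deterministic
logical constraints and missing values, none of which the generator
emulates. The pruning-loss *trends* (legal-CPS fraction rising with sample
size and falling with the in-degree bound; $\Delta$ flat at mild pruning and
decreasing beyond) reproduce qualitatively on this synthetic family, but the
specific per-mille losses on real benchmark networks depend on those
real-data features and on far larger CPS tables than desk-scale sweeps use.

## Problem sizes used by the tests and acceptance script

The packaged experiments are deliberately scaled to a single CPU: the
exact-vs-exhaustive and legality-soundness cross-checks run on 200 random
score sets with $n \in \{3,4,5\}$; the pruning sweep runs on a 15-node
ground truth with 5,000 samples at in-degree 3 (about 7,000 scored CPSs) at
levels 0/30/60/90; the legal-fraction trends average three 7-node
replicates per condition. These sizes were chosen so the full pipeline —
generation, scoring, pruning, exact search, evaluation — is exercised end to
end in seconds to minutes while keeping the 2ⁿ dynamic-programming tables
small.

## Numerical and degenerate-input choices

* Scores use `lgamma()` throughout; no large-factorial intermediates occur.
* Structure counts use an internal exact big-integer routine (base-10⁴
  schoolbook arithmetic with Pascal-row binomials), because the 10-node DAG
  count already exceeds the integer range of doubles; results carry both the
  exact decimal string and a double approximation.
* Data files: arities may be stated explicitly or inferred as
  `max(value) + 1` (floored at 2 — a constant column still encodes a binary
  variable); a headerless file whose first observation contains only values
  ≥ 2 is ambiguous, which is why `write_bn_data()` always writes the arity
  row.
* Score files are written with six decimals; round-trips are exact to that
  precision, and parsing is insensitive to the order of CPS lines. Parent
  fields may be names or 0-based indices (auto-detected: all-integer tokens
  matching no variable name).
* `percent_prune(p = 0)` is the identity; `p = 100` is rejected (it would
  empty every table).
* An empty dataset, a child listed among its own parents, a missing CPS
  entry during `graph_score()`, and a non-permutation ordering are all
  errors, reported with the offending node or line.

## Known limitations

* Exact search is limited by the $n 2^n$ tables (default cap $n = 20$);
  beyond that only the greedy and order-based engines apply, and their
  result is a lower bound on the optimum.
* Only BDeu is implemented; AIC/BIC/MDL and other Bayesian-Dirichlet
  variants are out of scope, as are score-bound (entropy/Gamma) pruning
  rules beyond subset dominance, integer-programming search, and
  BIF/XMLBIF network parsers.
* Legality pruning assumes the input tables contain the subsets of every
  entry (true after full enumeration, the package's own scoring path);
  on partial external tables it compares only against subsets present.
* `legal_cps_fraction()` and the pruning sweep re-enumerate scores per call;
  they are measurement utilities, not optimised batch tooling.
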