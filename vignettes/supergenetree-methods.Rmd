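---
title: "Supergenetrees: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supergenetrees: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgtree)
```

## The problem

Gene trees for a large family are often estimated piecewise: clusters of
orthologs or inparalogs are aligned and resolved separately, leaving several
rooted binary trees $G_1,\dots,G_k$ on overlapping subsets
$\Gamma_1,\dots,\Gamma_k$ of the gene family $\Gamma$. A *supergenetree* is a
single binary tree on $\Gamma$ that **displays** every input: restricting it
to $\Gamma_i$ (dropping other leaves and contracting degree-2 nodes) gives
back $G_i$ exactly. Compatibility alone rarely pins down one tree, so when a
species tree $S$ is known we rank the candidates by their reconciliation
against $S$ and ask for a displaying supertree of minimum **duplication**
cost, or of minimum **mutation** cost (duplications plus losses).

`sgtree` implements this program end to end: compatibility testing,
an exact solver, a greedy heuristic, reconciliation, a simulator with known
ground truth, and a graph-coloring reduction used as a correctness fixture.
Both optimization problems are NP-hard (minimizing duplications is even hard
to approximate), so the exact solver is exponential by necessity and the
heuristic makes no approximation promise; the package's value is that the two
can be played against each other, and against a brute-force oracle, on
instances small enough to certify.

## Reconciliation

With a total map $s:\Gamma\to\Sigma$ from genes to species, every internal
node $x$ of a gene tree receives the LCA mapping
$s(x)=\mathrm{lca}_S\{s(g): g \in L(T_x)\}$. Node $x$ is a **speciation**
when the images of its two children are *separated* in $S$ (neither is an
ancestor-or-equal of the other), otherwise a **duplication**; a duplication
mapped to the root of $S$ is a **pre-speciation duplication**. Losses use the
standard linear-time depth-difference count: writing $e(x,c)$ for the number
of $S$-edges between $s(x)$ and $s(c)$,

$$\ell(x) = \begin{cases}
(e(x,x_l)-1) + (e(x,x_r)-1) & x \text{ a speciation},\\
e(x,x_l) + e(x,x_r) & x \text{ a duplication},
\end{cases}$$

summed over internal nodes. The test suite checks this closed form against an
independent dynamic program that minimizes losses over *all* valid
reconciliation maps (not just the LCA map) on random trees with up to six
leaves — the LCA map attains that minimum, so the two must agree.

## Compatibility: triplets and BUILD

A binary tree is determined by its rooted triplets, and a set of binary trees
is compatible iff the union of their triplets $tr(\mathcal G)$ is. The
triplet graph on a gene set $V$ joins $x$ and $y$ whenever some triplet
$xy|z$ has all three genes inside $V$; BUILD recurses on connected
components, failing exactly when a level stays connected with three or more
genes. Components are always ordered by their smallest gene label, so BUILD
output, polytomy child order, and everything downstream is deterministic.
Graph plumbing uses `igraph`; the exact solver re-derives components
internally over bitmasks for speed, and the two paths are pinned together by
the oracle-equivalence tests.

## The exact solver

For a subset $P\subseteq\Gamma$ let $R(P)$ be the minimum cost of a binary
tree on $P$ displaying every restricted input. Any feasible root split of $P$
must keep each component of the triplet graph on $P$ intact, so with
components $\mathcal C$ the recurrence minimizes over unordered proper
bipartitions $(C,\bar C)$ of $\mathcal C$:

$$R(P) = \min_{C} \; R(V(C)) + R(V(\bar C)) + d\!\left(V(C),V(\bar C)\right),$$

where $d$ is 0 if $s(V(C))$ and $s(V(\bar C))$ are separated in $S$ and 1
otherwise. Because the recurrence creates exactly the nodes of the output
tree, it explores precisely the set of displaying binary trees, which is why
it matches the enumeration oracle case for case.

Implementation notes:

* **Subset LCA.** $s(X)$ is precomputed for every nonempty subset in
  increasing order via $s(X)=\mathrm{lca}_S(s(X\setminus\{x\}), s(x))$, one
  pairwise query each, $O(2^n)$ total. The separation test then reduces to
  "does $\mathrm{lca}(s(A),s(B))$ differ from both".
* **Mutation cost.** The recurrence carries over with the per-node term
  $d + \ell(x)$, computing $\ell$ from $s(P)$, $s(V(C))$, $s(V(\bar C))$ with
  the same depth-difference formula; the DP total therefore equals the
  reconciliation cost of the tree it returns, which the tests assert.
* **Determinism.** Unordered bipartitions are enumerated once ($2^{m-1}-1$ of
  them); among equal-cost splits the one minimizing the smaller side's
  bitmask wins, so returned trees are bit-reproducible.
* **Caps.** The DP refuses families above 22 genes (≈4M subsets) and the
  enumeration oracle above 8 ($(2n-3)!!$ topologies); both caps are
  arguments, and the greedy solver is the intended fallback.

`solve_constrained_root()` scores one prescribed root bipartition: infeasible
(cost $\infty$) when the split severs a triplet-graph component, otherwise
$R(A)+R(B)+d(A,B)$.

## The greedy heuristic

A triplet $xy|z$ whose root reconciles to a duplication at $r(S)$ is a
**required duplication**: every displaying supertree contains it. The
heuristic builds, at each level, the graph whose vertices are the
triplet-graph components, with an edge of weight $w$ when $w$ distinct
required-duplication triplets have their cherry in one component and their
outgroup in the other. Choosing the root bipartition that *merges* the most
required duplications into the single new root node is a weighted Max-Cut;
the heuristic takes a maximum cut and recurses into both sides, pushing
unresolved duplications downward.

Design choices the problem statement leaves open:

* **Below the first level.** "Required duplication" is only defined against
  $r(S)$. At a recursive subset $P$ the package uses the natural
  generalization: a triplet counts when its root maps, as a duplication, to
  $s(P)$ — the species node where $P$'s first speciation can happen. This is
  a documented package choice, not forced by the problem.
* **Edgeless component graphs.** When no required duplication crosses
  components, the bipartition minimizing the duplication flag is taken, most
  balanced first, then smallest canonical encoding — consistent with the
  heuristic's intent of deferring duplications.
* **Max-Cut itself.** Up to 25 components the cut is exact by enumeration;
  beyond that a seeded multi-restart single-flip local search is used. An SDP
  rounding step was deliberately avoided: the recursion stacks cut errors
  anyway, so no approximation factor is promised — only the invariant
  `greedy cost >= exact cost`, which the suite checks on every instance where
  both run, along with seeded bit-reproducibility.

## The simulator and what it does (not) show

`simulate_instance()` grows a full gene tree $T^\*$ down a random species
tree — at each gene-tree node the lineage duplicates in place with
probability `dup_prob`, and each species-tree edge is lost with probability
`loss_prob` — then cuts the inputs as restrictions of $T^\*$ to sampled leaf
subsets. Consequently every simulated instance is consistent, and $T^\*$'s
cost upper-bounds the optimum; both facts are asserted as properties. The
stored "true" counts are $T^\*$'s LCA-reconciliation counts: raw generative
event counts are unobservable once extinct lineages are pruned. Defaults
(8 species, `dup_prob = 0.2`, `loss_prob = 0.1`, `k = 3`, subset sizes 3–6,
uniform species-tree shape) describe a moderately duplicating family whose
subsets resemble ortholog clusters.

With `speciation_only = TRUE` the subsets are the maximal duplication-free
subtrees of $T^\*$ (split further at random when more parts are requested):
restrictions of speciation trees remain speciation trees, so the inputs are
valid independent-speciation instances — disjoint, speciation-only — and a
speciation-preserving supertree always exists (join the inputs under any
binary scaffold), which the constrained oracle verifies on small instances.

What the simulator does **not** emulate: sequence-level estimation error
(inputs are always correct restrictions, never misleading), branch lengths
or rates, transfers, incomplete lineage sorting, and non-binary species
trees. Passing tests therefore certify the combinatorial machinery, not
robustness to misestimated input trees.

## The coloring reduction as a fixture

From a simple graph $H$ the package builds two genes $v_1,v_2$ per vertex,
four triplet trees $v_1v_2|w_1$, $v_1v_2|w_2$, $w_1w_2|v_1$, $w_1w_2|v_2$
per edge, and a species tree joining a caterpillar over the `_1` species
with one over the `_2` species, so each pair $(v_1,v_2)$ meets only at the
species root. The minimum duplication cost of the instance is exactly
$\chi(H)-1$. Caterpillar shapes over lexicographically sorted species were
fixed for reproducibility (any binary shapes would do). Because $\chi$ of
small graphs is computable by brute force, this gives analytically known
optima: the suite sweeps *all* labeled simple graphs on up to four vertices
against the enumeration oracle, and pins $K_3 \to 2$, $K_4 \to 3$, and the
5-cycle (10 genes, via the DP) $\to 2$. Vertices without incident edges are
dropped — they would contribute genes appearing in no input tree, and they
cannot change $\chi$ once an edge exists.

## Problem sizes used in the checks

The package's own verification runs at desk scale, chosen so each suite is a
few tens of seconds: oracle-equivalence on 200 simulated instances with
4–7 genes (both costs, exact agreement required), the coloring sweep over
all ≤4-vertex graphs (up to 8 genes per oracle run, 135135 topologies),
greedy-versus-exact dominance on 60 instances, and loss-count agreement with
the embedding dynamic program on trees with up to six leaves. The worked
six-gene example — three triplet inputs over a two-clade species tree —
is recomputed by `scripts/acceptance.R`.

## Known limitations

* All inputs must be binary and rooted; polytomies are rejected rather than
  resolved, and unrooted trees are out of scope.
* Inconsistent input sets yield a verdict, not a repair: no tree correction
  or maximal-compatible-subset search is attempted.
* The exact solver's $O(4^n)$ worst case makes ~22 genes a hard practical
  ceiling; the greedy heuristic carries no quality guarantee beyond never
  beating the optimum.
* Transfers and other non-duplication-loss events are ignored throughout.
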