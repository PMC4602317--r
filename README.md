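# sgtree — supertrees for gene families, guided by a species tree

Large gene families are usually resolved piecewise: clusters of orthologs or
inparalogs are built (OrthoMCL-style), aligned, and turned into small rooted
gene trees on overlapping subsets of the family. `sgtree` amalgamates such
partial trees into one binary **supergenetree** that *displays* every input
(restricting the supertree to an input's leaves returns that input exactly),
and uses a known species tree *S* to pick, among all displaying supertrees,
one of minimum reconciliation cost.

For a gene tree *T* and species map *s*, LCA reconciliation maps each
internal node *x* to *s(x) = lca_S{s(g) : g below x}*; *x* is a *speciation*
when its children's images are separated in *S*, otherwise a *duplication*,
and the implied losses follow the standard depth-difference count. The two
objectives are

* **dup** — number of duplication nodes, and
* **mutation** — duplications + losses,

minimized over all binary supertrees displaying the inputs. Both problems are
NP-hard (the duplication version even hard to approximate), so the package
provides, behind one instance type:

* `is_consistent()` / `build_supertree()` — BUILD compatibility test over
  rooted triplets, with the triplet graph exposed (`extract_triplets()`,
  `triplet_graph()`, `triplet_components()`);
* `solve_exact()` — exact dynamic program over gene subsets, recursing on
  bipartitions of triplet-graph components (≤ 22 genes);
  `solve_constrained_root()` scores a prescribed root split;
* `solve_greedy()` — the pre-speciation-duplication heuristic: a weighted
  Max-Cut on the component graph of required duplications, applied
  recursively (`component_graph()`, `max_cut()`);
* `oracle_enumerate()` — brute force over all (2n−3)!! topologies (≤ 8
  genes), the ground truth the solvers are tested against;
* `reconcile()`, `reconciliation_cost()`, `count_losses()`,
  `required_duplication()`, `preserves_speciations()` — reconciliation
  toolkit, including the independent-speciation (orthogroup) setting;
* `simulate_instance()` and `coloring_reduction()` — synthetic instances
  with known ground truth, and a graph-coloring reduction with analytically
  known optima (χ(H) − 1).

See `vignettes/supergenetree-methods.Rmd` for the model, the recurrences and
every design decision.

## Worked example

Six species, one gene each, and three triplet inputs whose roots are all
duplications forced at the species root:

```r
library(sgtree)
inst <- load_instance(
  system.file("extdata/maxcut_example/species.nwk",   package = "sgtree"),
  system.file("extdata/maxcut_example/genetrees.nwk", package = "sgtree"),
  system.file("extdata/maxcut_example/map.tsv",       package = "sgtree"))
inst
#> Supergenetree instance: 6 genes, 6 species, 3 input tree(s)

component_graph(inst)
#> Component graph: 3 component(s), 2 weighted edge(s)
#>   C1 = {a1,b1,d1}
#>   C2 = {c1,e1}
#>   C3 = {f1}
#>   C1 -- C2  weight 2
#>   C2 -- C3  weight 1

max_cut(component_graph(inst), "exact")
#> Max-Cut weight 3: ({a1,b1,d1,f1}, {c1,e1})

solve_exact(inst, "dup")
#> Supergenetree (dp, dup cost = 1)
#> (((a1,b1),(d1,f1)),(c1,e1));

solve_greedy(inst)
#> Supergenetree (greedy, dup cost = 1)
#> (((a1,b1),(d1,f1)),(c1,e1));

solve_constrained_root(inst, c("a1", "b1", "d1"))
#> Supergenetree (dp_constrained, dup cost = 2)
#> (((a1,b1),d1),((c1,e1),f1));
```

Reading: the triplet graph splits the genes into three components; two
required-duplication triplets connect `{a1,b1,d1}` to `{c1,e1}` (weight 2)
and one connects `{c1,e1}` to `{f1}` (weight 1). The maximum cut (weight 3)
puts `{a1,b1,d1,f1}` against `{c1,e1}`, merging all three forced
duplications into the single root duplication — the optimal supertree has
duplication cost 1. The alternative root split `{a1,b1,d1} | {c1,e1,f1}`
defers one required duplication and costs 2.

A thin command-line wrapper ships at `inst/cli/sgt.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/sgt.R", package="sgtree"))')" \
  solve -s species.nwk -g genetrees.nwk -m map.tsv --method dp --cost dup
```

Subcommands: `check`, `solve`, `reconcile`, `simulate`, `reduce-coloring`;
exit codes 0 (success/consistent), 1 (inconsistent/infeasible), 2 (usage).

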