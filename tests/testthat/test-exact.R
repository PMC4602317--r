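test_that("the subset-LCA table composes pairwise LCAs over all subsets", {
  inst <- worked_example()
  L <- subset_lca_table(inst)
  genes <- attr(L, "genes")
  expect_equal(genes, inst$genes)
  bit <- setNames(bitwShiftL(1L, seq_along(genes) - 1L), genes)
  # singletons map to their species leaf
  expect_equal(L[bit[["a1"]]], match("a", inst$species$tip.label))
  # {a1, d1} spans both sides: the species root
  expect_equal(L[bit[["a1"]] + bit[["d1"]]], 7L)
  # {a1, b1} maps to the left child of the root
  expect_equal(L[bit[["a1"]] + bit[["b1"]]], tree_lca(inst$species, c("a", "b")))
  # s(X) = lca(s(X \ x), s(x)) spot-checked on random subsets
  withr::with_seed(5, for (i in 1:20) {
    xs <- sample(genes, sample(2:6, 1))
    m <- sum(bit[xs])
    expect_equal(L[m], tree_lca(inst$species, unname(inst$map[xs])))
  })
  expect_error(subset_lca_table(inst, cap = 4L), "solve_greedy")
})

test_that("the duplication flag encodes separation in the species tree", {
  inst <- worked_example()
  expect_equal(dup_flag(inst, "a1", "b1"), 0L)
  expect_equal(dup_flag(inst, c("a1", "b1", "d1"), c("c1", "e1", "f1")), 1L)
  expect_equal(dup_flag(inst, c("a1", "b1"), c("d1", "f1")), 0L)
  # equal images are never separated
  same <- sgt_instance(read_newick("(a,b);", "species"),
                       read_newick("(a_1,a_2);", "gene"),
                       c(a_1 = "a", a_2 = "a"))
  expect_equal(dup_flag(same, "a_1", "a_2"), 1L)
  expect_error(dup_flag(inst, c("a1", "b1"), c("b1", "c1")), "disjoint")
})

test_that("exact solver reproduces hand-verified optima", {
  inst <- worked_example()
  sol <- solve_exact(inst, "dup")
  expect_equal(sol$cost, 1)
  for (g in inst$gene_trees) expect_true(displays(sol$tree, g))
  expect_equal(reconciliation_cost(sol$tree, inst, cost = "dup"), 1L)
  # constrained root splits
  sub <- solve_constrained_root(inst, c("a1", "b1", "d1"), "dup")
  expect_equal(sub$cost, 2)
  expect_equal(reconciliation_cost(sub$tree, inst, cost = "dup"), 2L)
  opt <- solve_constrained_root(inst, c("a1", "b1", "d1", "f1"), "dup")
  expect_equal(opt$cost, 1)
  # a split breaking a triplet-graph component is infeasible
  bad <- solve_constrained_root(inst, c("a1", "c1"), "dup")
  expect_false(bad$feasible)
  expect_equal(bad$cost, Inf)
  # inconsistent inputs yield a verdict, not a tree
  contra <- sgt_instance(read_newick(cat_newick(c("a", "b", "c")), "species"),
                         list(read_newick("((a,b),c);", "gene"),
                              read_newick("((b,c),a);", "gene")),
                         setNames(c("a", "b", "c"), c("a", "b", "c")))
  expect_false(solve_exact(contra)$consistent)
  expect_error(solve_exact(worked_example(), cap = 4L), "solve_greedy")
})

test_that("the enumeration oracle counts topologies and agrees with the DP", {
  inst3 <- sgt_instance(read_newick(cat_newick(c("a", "b", "c")), "species"),
                        read_newick("((a,b),c);", "gene"),
                        setNames(c("a", "b", "c"), c("a", "b", "c")))
  o3 <- oracle_enumerate(inst3, "dup")
  expect_equal(o3$n_enumerated, 3L)
  expect_equal(o3$n_feasible, 1L)
  expect_equal(count_rooted_trees(5), 105)
  inst <- worked_example()
  o <- oracle_enumerate(inst, "dup")
  expect_equal(o$n_enumerated, count_rooted_trees(6))
  expect_equal(o$cost, solve_exact(inst, "dup")$cost)
})

test_that("DP equals the enumeration oracle on random consistent instances", {
  for (seed in 1:30) {
    inst <- random_small_instance(seed)
    if (is.null(inst)) next
    for (cst in c("dup", "mutation")) {
      sol <- solve_exact(inst, cst)
      orc <- oracle_enumerate(inst, cst)
      expect_equal(sol$cost, orc$cost,
                   info = sprintf("seed %d cost %s", seed, cst))
      # the DP value is realized by its own returned tree
      expect_equal(sol$cost,
                   reconciliation_cost(sol$tree, inst, cost = cst))
      for (g in inst$gene_trees) expect_true(displays(sol$tree, g))
    }
    # the true tree is feasible: its cost upper-bounds the optimum
    expect_lte(solve_exact(inst, "dup")$cost, inst$truth$duplication_count)
  }
})

test_that("the optimum never decreases when a compatible tree is added", {
  for (seed in 1:8) {
    inst <- random_small_instance(seed)
    if (is.null(inst) || length(inst$genes) < 4) next
    base <- solve_exact(inst, "dup")$cost
    extra <- restrict_tree(inst$truth$tree, sample(inst$genes, 3))
    bigger <- sgt_instance(inst$species, c(inst$gene_trees, list(extra)),
                           inst$map)
    expect_gte(solve_exact(bigger, "dup")$cost, base)
  }
})

test_that("coloring reductions solve to the chromatic number minus one", {
  k3 <- coloring_reduction(rbind(c("u", "v"), c("v", "w"), c("u", "w")))
  expect_equal(solve_exact(k3, "dup")$cost, 2)
  e1 <- coloring_reduction(rbind(c("u", "v")))
  expect_equal(solve_exact(e1, "dup")$cost, 1)
  k4 <- coloring_reduction(t(combn(letters[1:4], 2)))
  expect_equal(solve_exact(k4, "dup")$cost, 3)
})
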