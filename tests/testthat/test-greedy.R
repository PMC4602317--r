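test_that("component-graph edges count distinct required-duplication triplets", {
  inst <- worked_example()
  cg <- component_graph(inst)
  expect_equal(cg$components,
               list(c("a1", "b1", "d1"), c("c1", "e1"), "f1"))
  e <- cg$edges[order(cg$edges$i, cg$edges$j), ]
  expect_equal(e$i, c(1L, 2L))
  expect_equal(e$j, c(2L, 3L))
  expect_equal(e$weight, c(2L, 1L))
  # a triplet present in two input trees still contributes weight 1
  dup_inst <- sgt_instance(inst$species,
                           c(inst$gene_trees,
                             list(read_newick("((a1,d1),c1);", "gene"))),
                           inst$map)
  e2 <- component_graph(dup_inst)$edges
  expect_equal(sort(e2$weight), c(1L, 2L))
  # no required duplications: edgeless component graph
  calm <- sgt_instance(read_newick("((a,b),(c,d));", "species"),
                       read_newick("((ga,gb),gc);", "gene"),
                       c(ga = "a", gb = "b", gc = "c"))
  expect_equal(nrow(component_graph(calm)$edges), 0L)
})

test_that("exact Max-Cut maximizes merged duplications", {
  inst <- worked_example()
  cut <- max_cut(component_graph(inst), "exact")
  expect_equal(cut$weight, 3L)
  expect_equal(cut$genes1, c("a1", "b1", "d1", "f1"))
  expect_equal(cut$genes2, c("c1", "e1"))
  # unit triangle: best cut weight 2
  tri <- structure(list(
    components = list("a", "b", "c"),
    edges = data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                       weight = c(1L, 1L, 1L)),
    level_node = NA, genes = c("a", "b", "c")),
    class = "sgt_component_graph")
  expect_equal(max_cut(tri, "exact")$weight, 2L)
  expect_equal(max_cut(tri, "local_search", seed = 4L)$weight, 2L)
  # edgeless graph: weight 0, deterministic tie-break
  el <- structure(list(components = list("a", "b"),
                       edges = data.frame(i = integer(), j = integer(),
                                          weight = integer()),
                       level_node = NA, genes = c("a", "b")),
                  class = "sgt_component_graph")
  expect_equal(max_cut(el, "exact")$weight, 0L)
  expect_error(max_cut(structure(list(components = list("a"),
                                      edges = el$edges),
                                 class = "sgt_component_graph")), "at least 2")
})

test_that("local-search Max-Cut is seeded-deterministic and near-exact", {
  withr::with_seed(31, {
    for (i in 1:10) {
      m <- sample(3:7, 1)
      pairs <- t(combn(m, 2))
      keep <- runif(nrow(pairs)) < 0.6
      if (!any(keep)) keep[1] <- TRUE
      g <- structure(list(components = as.list(letters[1:m]),
                          edges = data.frame(i = pairs[keep, 1],
                                             j = pairs[keep, 2],
                                             weight = sample(1:3, sum(keep),
                                                             replace = TRUE)),
                          level_node = NA, genes = letters[1:m]),
                     class = "sgt_component_graph")
      ex <- max_cut(g, "exact")
      l1 <- max_cut(g, "local_search", seed = 99L)
      l2 <- max_cut(g, "local_search", seed = 99L)
      expect_identical(l1, l2)
      expect_lte(l1$weight, ex$weight)
      expect_gte(l1$weight, ceiling(ex$weight / 2))  # any local optimum
    }
  })
})

test_that("greedy solver attains the optimum on the worked example", {
  inst <- worked_example()
  sol <- solve_greedy(inst)
  expect_equal(sol$cost, 1L)
  for (g in inst$gene_trees) expect_true(displays(sol$tree, g))
  # root split merges all three required duplications
  left <- restrict_tree(sol$tree, c("a1", "b1", "d1", "f1"))
  expect_true(displays(sol$tree, left))
  expect_identical(canonical_newick(sol$tree),
                   canonical_newick(solve_exact(inst, "dup")$tree))
})

test_that("greedy never beats the exact optimum and is reproducible", {
  for (seed in 1:12) {
    inst <- random_small_instance(seed)
    if (is.null(inst)) next
    g1 <- solve_greedy(inst, seed = 7L)
    g2 <- solve_greedy(inst, seed = 7L)
    expect_identical(write_newick(g1$tree), write_newick(g2$tree))
    expect_gte(g1$cost, solve_exact(inst, "dup")$cost)
    for (g in inst$gene_trees) expect_true(displays(g1$tree, g))
  }
  # a speciation-only single input solves at zero cost
  clean <- simulate_instance(n_species = 6, dup_prob = 0, loss_prob = 0,
                             k = 1, size_range = c(2, 6), seed = 42)
  expect_equal(solve_greedy(clean)$cost, 0L)
  # heuristic upper-bounds the DP on the hardness fixture
  k3 <- coloring_reduction(rbind(c("u", "v"), c("v", "w"), c("u", "w")))
  expect_gte(solve_greedy(k3)$cost, 2L)
  # inconsistent inputs give a verdict
  contra <- sgt_instance(read_newick(cat_newick(c("a", "b", "c")), "species"),
                         list(read_newick("((a,b),c);", "gene"),
                              read_newick("((b,c),a);", "gene")),
                         setNames(c("a", "b", "c"), c("a", "b", "c")))
  expect_false(solve_greedy(contra)$consistent)
})
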