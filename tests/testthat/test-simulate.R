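test_that("event-free simulation reproduces the species tree exactly", {
  inst <- simulate_instance(n_species = 6, dup_prob = 0, loss_prob = 0,
                            k = 2, size_range = c(3, 6), seed = 11)
  expect_equal(inst$truth$duplication_count, 0L)
  expect_equal(inst$truth$loss_count, 0L)
  expect_equal(length(inst$genes), 6L)       # one gene per species
  expect_equal(solve_exact(inst, "dup")$cost, 0)
  expect_equal(solve_exact(inst, "mutation")$cost, 0)
})

test_that("simulated instances are always consistent and seed-reproducible", {
  for (seed in c(3, 14, 77)) {
    a <- simulate_instance(n_species = 5, dup_prob = 0.3, loss_prob = 0.2,
                           k = 3, size_range = c(2, 5), seed = seed)
    b <- simulate_instance(n_species = 5, dup_prob = 0.3, loss_prob = 0.2,
                           k = 3, size_range = c(2, 5), seed = seed)
    expect_identical(write_newick(a$truth$tree), write_newick(b$truth$tree))
    expect_true(is_consistent(a))
    for (g in a$gene_trees) expect_true(displays(a$truth$tree, g))
  }
  expect_error(simulate_instance(n_species = 5, seed = 1, dup_prob = 2), "dup_prob")
})

test_that("speciation-only instances are disjoint speciation trees with a feasible join", {
  inst <- simulate_instance(n_species = 6, dup_prob = 0.35, loss_prob = 0.1,
                            k = 2, size_range = c(2, 6),
                            speciation_only = TRUE, seed = 29)
  expect_false(inst$overlapping)
  for (g in inst$gene_trees) {
    if (length(g$tip.label) < 2) next
    expect_equal(reconcile(g, inst)$duplication_count, 0L)
  }
  # a speciation-preserving supertree always exists for such inputs
  if (length(inst$genes) <= 8) {
    o <- oracle_enumerate(inst, "dup", constraint = "preserve_speciations")
    expect_true(o$feasible)
    expect_true(preserves_speciations(o$tree, inst))
    # and is never cheaper than the unconstrained optimum
    expect_gte(o$cost, oracle_enumerate(inst, "dup")$cost)
  }
})

test_that("instances round-trip through the on-disk format", {
  inst <- simulate_instance(n_species = 5, dup_prob = 0.3, loss_prob = 0.1,
                            k = 2, size_range = c(2, 5), seed = 8)
  d1 <- file.path(tempdir(), "sgt_rt1")
  d2 <- file.path(tempdir(), "sgt_rt2")
  write_instance(inst, d1)
  back <- read_instance(d1)
  expect_equal(back$genes, inst$genes)
  expect_equal(back$map, inst$map)
  expect_identical(canonical_newick(back$species), canonical_newick(inst$species))
  for (i in seq_along(inst$gene_trees))
    expect_identical(canonical_newick(back$gene_trees[[i]]),
                     canonical_newick(inst$gene_trees[[i]]))
  expect_equal(back$truth$duplication_count, inst$truth$duplication_count)
  # identical bytes from an identical seed
  write_instance(simulate_instance(n_species = 5, dup_prob = 0.3,
                                   loss_prob = 0.1, k = 2,
                                   size_range = c(2, 5), seed = 8), d2)
  for (f in c("species.nwk", "genetrees.nwk", "map.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("the coloring reduction emits four triplets per edge", {
  e1 <- coloring_reduction(rbind(c("u", "v")))
  expect_length(e1$gene_trees, 4L)
  expect_length(e1$genes, 4L)
  expect_equal(oracle_enumerate(e1, "dup")$cost, 1)   # chi(K2) - 1
  expect_error(coloring_reduction(rbind(c("u", "u"))), "self-loop")
  expect_error(coloring_reduction(matrix(character(), 0, 2)), "at least one")
  # duplicate edges collapse
  e2 <- coloring_reduction(rbind(c("u", "v"), c("v", "u")))
  expect_length(e2$gene_trees, 4L)
})

test_that("reduced instances of 3-vertex graphs solve to chi minus one", {
  for (edges in all_small_graphs(max_v = 3L)) {
    inst <- coloring_reduction(edges)
    chi <- chromatic_number(edges)
    o <- oracle_enumerate(inst, "dup")
    expect_equal(o$cost, chi - 1, info = paste(edges, collapse = ","))
    # every feasible tree pairs the two gene copies of each edge vertex
    for (r in seq_len(nrow(edges))) {
      v <- edges[r, 1]; w <- edges[r, 2]
      quartet <- read_newick(sprintf("((%s_1,%s_2),(%s_1,%s_2));", v, v, w, w),
                             "gene")
      expect_true(displays(o$tree, quartet))
    }
  }
})
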