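# Shared fixtures and independent oracles used across the suite.

# six-gene worked example: two-clade species tree, one gene per species,
# three triplet inputs whose roots are all forced duplications
worked_example <- function() {
  species <- read_newick("((a,(b,c)),(d,(e,f)));", "species")
  trees <- lapply(c("((a1,d1),c1);", "((d1,b1),e1);", "((c1,e1),f1);"),
                  read_newick, kind = "gene")
  map <- setNames(c("a", "b", "c", "d", "e", "f"),
                  c("a1", "b1", "c1", "d1", "e1", "f1"))
  sgt_instance(species, trees, map)
}

cat_newick <- function(labels)
  paste0(Reduce(function(a, b) sprintf("(%s,%s)", a, b), labels), ";")

# random topology on given labels, via ape
random_tree_on <- function(labels) {
  t <- ape::rtree(length(labels), rooted = TRUE)
  t$tip.label <- sample(labels)
  t$edge.length <- NULL
  t
}

# simulated (hence consistent) instance with a bounded gene-family size
random_small_instance <- function(seed, n_min = 4, n_max = 7) {
  for (t in 1:80) {
    cand <- try(simulate_instance(n_species = 4L + (seed + t) %% 3L,
                                  dup_prob = 0.3, loss_prob = 0.15,
                                  k = 2L + (seed + t) %% 2L,
                                  size_range = c(2L, 5L),
                                  seed = seed * 1000L + t),
                silent = TRUE)
    if (!inherits(cand, "try-error") &&
        length(cand$genes) >= n_min && length(cand$genes) <= n_max)
      return(cand)
  }
  NULL
}

# arbitrary (possibly inconsistent) set of random gene trees on overlapping
# subsets, with a bijective gene-species map over a caterpillar species tree
random_treeset_instance <- function(seed) {
  withr::with_seed(seed, {
    genes <- paste0("g", seq_len(sample(4:6, 1)))
    k <- sample(2:3, 1)
    trees <- lapply(seq_len(k), function(i)
      random_tree_on(sample(genes, sample(3:length(genes), 1))))
    species <- read_newick(cat_newick(genes), "species")
    sgt_instance(species, trees, setNames(genes, genes))
  })
}

# ---- naive tree helpers, independent of the package internals ----

tt_parents <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  p <- integer(n)
  p[phy$edge[, 2]] <- phy$edge[, 1]
  p
}

tt_path_to_root <- function(p, v) {
  out <- v
  while (p[v] != 0L) { v <- p[v]; out <- c(out, v) }
  out
}

# path-walking LCA of two nodes
tt_naive_lca <- function(phy, u, v) {
  p <- tt_parents(phy)
  pu <- tt_path_to_root(p, u)
  pv <- tt_path_to_root(p, v)
  pu[pu %in% pv][1L]
}

tt_depths <- function(phy) {
  p <- tt_parents(phy)
  n <- length(p)
  vapply(seq_len(n), function(v) length(tt_path_to_root(p, v)) - 1L, 0L)
}

# minimum losses over all reconciliation maps m (m(x) ancestral-or-equal to
# the images of x's children): tree dynamic program over explicit
# embeddings, independent of the closed-form depth-difference count
min_losses_embedding <- function(tree, species, map) {
  ns <- length(species$tip.label) + species$Nnode
  sd <- tt_depths(species)
  SM <- outer(seq_len(ns), seq_len(ns),
              Vectorize(function(u, v) tt_naive_lca(species, u, v)))
  anc_eq <- function(a, b) SM[a, b] == a
  nt <- length(tree$tip.label)
  ntot <- nt + tree$Nnode
  kids <- vector("list", ntot)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  spid <- match(map[tree$tip.label], species$tip.label)
  f <- matrix(Inf, ntot, ns)
  for (v in seq_len(nt)) f[v, spid[v]] <- 0
  rec <- function(v) {
    if (v <= nt) return(invisible(NULL))
    l <- kids[[v]][1L]; r <- kids[[v]][2L]
    rec(l); rec(r)
    for (a in seq_len(ns)) {
      best <- Inf
      for (a1 in which(is.finite(f[l, ]))) {
        if (!anc_eq(a, a1)) next
        for (a2 in which(is.finite(f[r, ]))) {
          if (!anc_eq(a, a2)) next
          sep <- !anc_eq(a1, a2) && !anc_eq(a2, a1)
          ev_cost <- if (sep && SM[a1, a2] == a)
            (sd[a1] - sd[a] - 1L) + (sd[a2] - sd[a] - 1L)   # speciation
          else
            (sd[a1] - sd[a]) + (sd[a2] - sd[a])             # duplication
          best <- min(best, f[l, a1] + f[r, a2] + ev_cost)
        }
      }
      f[v, a] <<- best
    }
  }
  rec(nt + 1L)
  min(f[nt + 1L, ])
}

# ---- small-graph utilities for the coloring reduction ----

# all labeled simple graphs with >= 1 edge on 2..max_v vertices
all_small_graphs <- function(max_v = 4L) {
  out <- list()
  for (nv in 2:max_v) {
    pairs <- t(combn(letters[seq_len(nv)], 2))
    np <- nrow(pairs)
    for (s in seq_len(2^np - 1)) {
      sel <- bitwAnd(bitwShiftR(s, seq_len(np) - 1L), 1L) == 1L
      out[[length(out) + 1L]] <- pairs[sel, , drop = FALSE]
    }
  }
  out
}

# brute-force chromatic number of the subgraph induced by incident vertices
chromatic_number <- function(edges) {
  verts <- sort(unique(as.vector(edges)))
  for (k in seq_along(verts)) {
    grid <- expand.grid(rep(list(seq_len(k)), length(verts)))
    for (r in seq_len(nrow(grid))) {
      asg <- setNames(as.integer(grid[r, ]), verts)
      if (all(asg[edges[, 1]] != asg[edges[, 2]])) return(k)
    }
  }
  length(verts)
}
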