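# Synthetic instances with known ground truth, and the graph-coloring
# reduction used as a hardness-derived correctness fixture.

.nested_to_newick <- function(tr, labels) {
  rec <- function(x) {
    if (!is.list(x)) return(labels[x])
    sprintf("(%s,%s)", rec(x[[1L]]), rec(x[[2L]]))
  }
  paste0(rec(tr), ";")
}

# insert leaf `lf` above the node at preorder position `pos`
.insert_leaf_at <- function(tr, lf, pos) {
  cnt <- 0L
  done <- FALSE
  rec <- function(x) {
    cnt <<- cnt + 1L
    if (cnt == pos) { done <<- TRUE; return(list(x, lf)) }
    if (!is.list(x) || done) return(x)
    l <- rec(x[[1L]])
    if (done) return(list(l, x[[2L]]))
    list(l, rec(x[[2L]]))
  }
  rec(tr)
}

.count_positions <- function(tr) if (!is.list(tr)) 1L else
  1L + .count_positions(tr[[1L]]) + .count_positions(tr[[2L]])

#' Random rooted binary species tree
#'
#' `"uniform"` draws uniformly over labeled topologies (sequential leaf
#' insertion at a uniform node position); `"yule"` splits a uniformly chosen
#' pendant lineage at each step.
#'
#' @param n number of species (`>= 2`).
#' @param model `"uniform"` or `"yule"`.
#' @param labels species labels (default `s01`, `s02`, ...).
#' @return a `phylo`.
#' @export
random_species_tree <- function(n, model = c("uniform", "yule"), labels = NULL) {
  model <- match.arg(model)
  if (n < 2L) stop("need at least 2 species", call. = FALSE)
  if (is.null(labels)) labels <- sprintf("s%02d", seq_len(n))
  stopifnot(length(labels) == n)
  tr <- list(1L, 2L)
  if (n > 2L) for (k in 3:n) {
    if (model == "uniform") {
      tr <- .insert_leaf_at(tr, k, sample.int(.count_positions(tr), 1L))
    } else {
      # replace a uniformly chosen leaf by a cherry
      leaf_no <- sample.int(k - 1L, 1L)
      cnt <- 0L
      rec <- function(x) {
        if (!is.list(x)) {
          cnt <<- cnt + 1L
          if (cnt == leaf_no) return(list(x, k)) else return(x)
        }
        list(rec(x[[1L]]), rec(x[[2L]]))
      }
      tr <- rec(tr)
    }
  }
  read_newick(.nested_to_newick(tr, labels), "species")
}

# grow one gene lineage down the species tree; duplication in place with
# probability dup_prob at each gene-tree node, loss with probability
# loss_prob on each species-tree edge; returns a Newick fragment or NULL
.evolve_genes <- function(species, dup_prob, loss_prob, max_genes = 1000L) {
  kids <- .children_list(species)
  nt <- .n_tip(species)
  counter <- new.env(parent = emptyenv())
  counter$per_species <- integer(nt)
  counter$total <- 0L
  counter$map <- character(0)
  new_gene <- function(v) {
    counter$per_species[v] <- counter$per_species[v] + 1L
    counter$total <- counter$total + 1L
    if (counter$total > max_genes) stop("gene family blew up", call. = FALSE)
    g <- sprintf("%s_%d", species$tip.label[v], counter$per_species[v])
    counter$map[g] <- species$tip.label[v]
    g
  }
  evolve <- function(v) {
    if (runif(1) < dup_prob) {
      l <- evolve(v); r <- evolve(v)
      if (is.null(l)) return(r)
      if (is.null(r)) return(l)
      return(sprintf("(%s,%s)", l, r))
    }
    if (v <= nt) return(new_gene(v))
    l <- if (runif(1) < loss_prob) NULL else evolve(kids[[v]][1L])
    r <- if (runif(1) < loss_prob) NULL else evolve(kids[[v]][2L])
    if (is.null(l)) return(r)
    if (is.null(r)) return(l)
    sprintf("(%s,%s)", l, r)
  }
  frag <- evolve(.root_id(species))
  list(newick = frag, map = counter$map)
}

# maximal duplication-free subtrees of a reconciled gene tree: their leaf
# sets partition the gene family, and each restriction is a speciation tree
.speciation_groups <- function(tree, species, map) {
  r <- reconcile(tree, species, map)
  nt <- .n_tip(tree)
  kids <- .children_list(tree)
  has_dup <- rep(FALSE, .n_node(tree))
  for (v in .postorder_internal(tree))
    has_dup[v] <- identical(r$label[v], "duplication") ||
      any(has_dup[kids[[v]]])
  parents <- .parents(tree)
  groups <- list()
  collect <- function(v) {
    if (v <= nt) return(tree$tip.label[v])
    unlist(lapply(kids[[v]], collect))
  }
  for (v in seq_len(.n_node(tree))) {
    maximal <- !has_dup[v] && (parents[v] == 0L || has_dup[parents[v]])
    if (maximal) groups[[length(groups) + 1L]] <- sort(collect(v))
  }
  groups[order(vapply(groups, `[[`, "", 1L))]
}

#' Simulate a supergenetree instance with known ground truth
#'
#' Grows a full gene tree T* along a random species tree (per-node
#' duplication probability, per-edge loss probability), then cuts input
#' trees as restrictions of T* to sampled leaf subsets — so the input set is
#' consistent by construction and the cost of T* upper-bounds the optimum.
#' The stored "true" duplication and loss counts are T*'s LCA-reconciliation
#' (parsimony) counts.
#'
#' @param n_species number of species.
#' @param dup_prob per-gene-tree-node duplication probability in `[0, 0.8]`.
#' @param loss_prob per-species-edge loss probability in `[0, 0.9]`.
#' @param k number of input trees.
#' @param size_range integer 2-vector: inclusive range of input leaf-set
#'   sizes (minimum 2).
#' @param speciation_only input leaf sets are taken from the maximal
#'   duplication-free subtrees of T*, so every input is a speciation tree
#'   (leaf sets then come out disjoint; more than `k` inputs are produced
#'   when T* decomposes into more duplication-free groups, so that their
#'   union still covers the gene family).
#' @param disjoint sample pairwise disjoint leaf sets (a partition of the
#'   gene family; `size_range` is then honored loosely).
#' @param tree_model species-tree shape, `"uniform"` or `"yule"`.
#' @param seed mandatory integer seed; the simulation is a pure function of
#'   its arguments.
#' @return an `sgt_instance` whose `$truth` holds the true tree and its
#'   duplication/loss counts.
#' @export
simulate_instance <- function(n_species = 8L, dup_prob = 0.2, loss_prob = 0.1,
                              k = 3L, size_range = c(3L, 6L),
                              speciation_only = FALSE, disjoint = FALSE,
                              tree_model = c("uniform", "yule"), seed) {
  tree_model <- match.arg(tree_model)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(dup_prob >= 0, dup_prob <= 0.8, loss_prob >= 0, loss_prob <= 0.9,
            k >= 1L, length(size_range) == 2L, size_range[1] >= 2L,
            size_range[1] <= size_range[2], n_species >= 2L)
  withr::with_seed(as.integer(seed), {
    species <- random_species_tree(n_species, tree_model)
    sim <- NULL
    for (try in seq_len(100L)) {
      cand <- tryCatch(.evolve_genes(species, dup_prob, loss_prob),
                       error = function(e) NULL)
      if (!is.null(cand) && !is.null(cand$newick) &&
          length(cand$map) >= max(2L, size_range[1])) { sim <- cand; break }
    }
    if (is.null(sim))
      stop("simulation failed to produce a usable gene family ",
           "(all lineages lost or family blew up); adjust probabilities",
           call. = FALSE)
    tstar <- read_newick(paste0(sim$newick, ";"), "gene")
    map <- sim$map
    genes <- sort(tstar$tip.label)
    ng <- length(genes)
    sizes <- function() sample(seq(size_range[1], min(size_range[2], ng)), k,
                               replace = TRUE)
    if (speciation_only) {
      groups <- .speciation_groups(tstar, species, map)
      while (length(groups) < k) {
        ls <- lengths(groups)
        big <- which(ls >= 4L)
        if (!length(big)) break
        pick <- big[which.max(ls[big])]
        g <- sample(groups[[pick]])
        half <- floor(length(g) / 2)
        groups[[pick]] <- sort(g[seq_len(half)])
        groups[[length(groups) + 1L]] <- sort(g[-seq_len(half)])
      }
      subsets <- groups
    } else if (disjoint) {
      # random partition into near-even chunks of size >= 2
      perm <- sample(genes)
      kk <- max(1L, min(k, floor(ng / 2)))
      cuts <- round(seq(0, ng, length.out = kk + 1))
      subsets <- lapply(seq_len(kk), function(i)
        sort(perm[(cuts[i] + 1):cuts[i + 1]]))
    } else {
      subsets <- lapply(sizes(), function(s) sort(sample(genes, s)))
      left <- setdiff(genes, unlist(subsets))
      for (g in left) {
        i <- sample.int(length(subsets), 1L)
        subsets[[i]] <- sort(c(subsets[[i]], g))
      }
    }
    subsets <- subsets[lengths(subsets) >= 1L]
    gene_trees <- lapply(subsets, function(s) restrict_tree(tstar, s))
    inst <- sgt_instance(species, gene_trees, map,
                         require_disjoint = disjoint || speciation_only)
    rt <- reconcile(tstar, species, map)
    inst$truth <- list(tree = tstar,
                       duplication_count = rt$duplication_count,
                       loss_count = rt$loss_count)
    class(inst) <- c("sgt_sim_instance", class(inst))
    inst
  })
}

.caterpillar <- function(labels)
  Reduce(function(a, b) sprintf("(%s,%s)", a, b), labels)

#' Graph-coloring reduction to a supergenetree instance
#'
#' For each vertex v of a simple graph H, two genes v_1, v_2 (one species
#' each); for each edge vw, the four triplet trees `v1v2|w1`, `v1v2|w2`,
#' `w1w2|v1`, `w1w2|v2`. The species tree joins a left-leaning caterpillar
#' over all `_1` species with one over all `_2` species, so every pair
#' (v_1, v_2) is separated only by the species root. The minimum duplication
#' cost of the resulting instance equals `chi(H) - 1`.
#'
#' Vertices incident to no edge contribute no input tree and are dropped
#' (they do not affect the chromatic number of a graph with at least one
#' edge).
#'
#' @param edges 2-column matrix or data frame of vertex names (one edge per
#'   row); self-loops are rejected, duplicate edges collapsed.
#' @return an `sgt_instance` (the triplet
#'   trees of an edge reuse genes).
#' @export
coloring_reduction <- function(edges) {
  edges <- as.matrix(edges)
  if (!nrow(edges) || ncol(edges) != 2L)
    stop("edges must be a 2-column matrix with at least one row", call. = FALSE)
  mode(edges) <- "character"
  if (any(edges[, 1] == edges[, 2])) stop("self-loop in edge list", call. = FALSE)
  key <- apply(edges, 1, function(e) paste(sort(e), collapse = "\r"))
  edges <- edges[!duplicated(key), , drop = FALSE]
  verts <- sort(unique(as.vector(edges)))
  g1 <- paste0(verts, "_1"); g2 <- paste0(verts, "_2")
  s_nwk <- sprintf("(%s,%s);", .caterpillar(g1), .caterpillar(g2))
  species <- read_newick(s_nwk, "species")
  trees <- list()
  for (r in seq_len(nrow(edges))) {
    v <- edges[r, 1]; w <- edges[r, 2]
    trees <- c(trees, lapply(
      c(sprintf("((%s_1,%s_2),%s_1);", v, v, w),
        sprintf("((%s_1,%s_2),%s_2);", v, v, w),
        sprintf("((%s_1,%s_2),%s_1);", w, w, v),
        sprintf("((%s_1,%s_2),%s_2);", w, w, v)),
      read_newick, kind = "gene"))
  }
  map <- setNames(c(g1, g2), c(g1, g2))
  sgt_instance(species, trees, map)
}
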