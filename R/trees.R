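# Rooted-tree substrate: Newick I/O, LCA queries, restriction, display tests.
# Trees are ape "phylo" objects; tips are 1..n, the root is n+1, all trees are
# rooted and (for parsed input) strictly binary.

.n_tip <- function(phy) length(phy$tip.label)
.root_id <- function(phy) .n_tip(phy) + 1L
.n_node <- function(phy) .n_tip(phy) + phy$Nnode

.check_binary <- function(phy, what = "tree") {
  if (.n_tip(phy) < 2L)
    stop(what, " must have at least 2 leaves", call. = FALSE)
  deg <- tabulate(phy$edge[, 1], nbins = .n_node(phy))
  bad <- which(deg != 0L & deg != 2L)
  if (length(bad))
    stop(what, " is not binary: internal node(s) with ",
         paste(unique(deg[bad]), collapse = "/"), " children", call. = FALSE)
  invisible(phy)
}

#' Read a rooted binary tree from Newick
#'
#' Parses a single rooted tree in strict Newick. Branch lengths and internal
#' node labels are parsed and discarded; polytomies are rejected, since both
#' the species tree and the input gene trees are required to be binary.
#'
#' @param x a Newick string, or the path of a file containing one tree.
#' @param kind `"gene"` or `"species"`; only affects error messages and the
#'   uniqueness check wording (labels must be unique in either case).
#' @return an object of class `phylo`, rooted, without branch lengths.
#' @examples
#' read_newick("((a,b),c);", "species")
#' @export
read_newick <- function(x, kind = c("gene", "species")) {
  kind <- match.arg(kind)
  is_file <- length(x) == 1L && !grepl("(", x, fixed = TRUE) && file.exists(x)
  txt <- if (is_file) paste(readLines(x, warn = FALSE), collapse = "\n") else x
  phy <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(phy)) stop("malformed Newick string: ", substr(txt, 1, 60), call. = FALSE)
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L) stop("expected a single tree, got ", length(phy), call. = FALSE)
    phy <- phy[[1L]]
  }
  if (anyDuplicated(phy$tip.label))
    stop("duplicate ", if (kind == "species") "species" else "gene",
         " labels in tree", call. = FALSE)
  .check_binary(phy, kind)
  phy$edge.length <- NULL
  phy$node.label <- NULL
  phy
}

#' Read gene trees, one Newick per line
#'
#' @param path file with one rooted binary Newick tree per non-empty line.
#' @return a list of `phylo` objects.
#' @export
read_gene_trees <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln)]
  if (!length(ln)) stop("no gene trees found in ", path, call. = FALSE)
  lapply(ln, read_newick, kind = "gene")
}

#' Serialize a tree to Newick
#' @param phy a `phylo` object.
#' @return a Newick string ending in `";"`.
#' @export
write_newick <- function(phy) ape::write.tree(phy)

# parent id of each node (0 for the root)
.parents <- function(phy) {
  p <- integer(.n_node(phy))
  p[phy$edge[, 2]] <- phy$edge[, 1]
  p
}

# children ids, one integer vector per node (empty for tips)
.children_list <- function(phy) {
  ch <- vector("list", .n_node(phy))
  for (i in seq_len(nrow(phy$edge)))
    ch[[phy$edge[i, 1]]] <- c(ch[[phy$edge[i, 1]]], phy$edge[i, 2])
  ch
}

# edge count from the root, per node
.node_depths <- function(phy) {
  d <- integer(.n_node(phy))
  pe <- ape::reorder.phylo(phy, "cladewise")$edge  # parents before children
  for (i in seq_len(nrow(pe))) d[pe[i, 2]] <- d[pe[i, 1]] + 1L
  d
}

# internal nodes, children before parents
.postorder_internal <- function(phy) {
  kids <- .children_list(phy)
  out <- integer(0)
  rec <- function(v) {
    if (v <= .n_tip(phy)) return(invisible(NULL))
    for (c in kids[[v]]) rec(c)
    out[[length(out) + 1L]] <<- v
  }
  rec(.root_id(phy))
  out
}

# full node-by-node LCA lookup table; O(1) amortized per pairwise query after
# an O(N^2 depth) precomputation (N small: trees here have <= ~64 leaves)
.lca_table <- function(phy) {
  N <- .n_node(phy)
  p <- .parents(phy)
  d <- .node_depths(phy)
  anc <- vector("list", N)
  for (v in seq_len(N)) {
    path <- v
    u <- v
    while (p[u] != 0L) { u <- p[u]; path <- c(path, u) }
    anc[[v]] <- path
  }
  M <- matrix(0L, N, N)
  for (u in seq_len(N)) for (v in u:N) {
    common <- intersect(anc[[u]], anc[[v]])
    w <- common[which.max(d[common])]
    M[u, v] <- M[v, u] <- w
  }
  M
}

.resolve_nodes <- function(phy, nodes) {
  ids <- if (is.character(nodes)) match(nodes, phy$tip.label) else as.integer(nodes)
  if (any(is.na(ids)) || any(ids < 1L | ids > .n_node(phy)))
    stop("unknown node(s): ",
         paste(nodes[is.na(ids) | ids < 1 | ids > .n_node(phy)], collapse = ", "),
         call. = FALSE)
  ids
}

#' Lowest common ancestor of a set of nodes
#'
#' @param phy a `phylo` object.
#' @param nodes tip labels (character) or node ids (integer); nonempty.
#' @return the node id of the LCA (a tip id for a singleton input).
#' @export
tree_lca <- function(phy, nodes) {
  if (!length(nodes)) stop("empty node set", call. = FALSE)
  ids <- .resolve_nodes(phy, nodes)
  M <- .lca_table(phy)
  Reduce(function(a, b) M[a, b], ids)
}

# 1-tip pseudo-phylo used for degenerate restrictions
.leaf_phylo <- function(label) {
  structure(list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = label, Nnode = 1L),
            class = "phylo")
}

#' Restrict a tree to a subset of its leaves
#'
#' Keeps only the leaves in `leaves`, contracts the resulting degree-2 nodes,
#' and roots the result at the LCA of the kept leaves.
#'
#' @param phy a `phylo` object.
#' @param leaves nonempty character vector of tip labels, a subset of
#'   `phy$tip.label`.
#' @return the restricted `phylo` (a 1-tip stub when `length(leaves) == 1`).
#' @export
restrict_tree <- function(phy, leaves) {
  leaves <- unique(as.character(leaves))
  if (!length(leaves)) stop("empty leaf set", call. = FALSE)
  miss <- setdiff(leaves, phy$tip.label)
  if (length(miss))
    stop("leaves not in tree: ", paste(miss, collapse = ", "), call. = FALSE)
  if (length(leaves) == 1L) return(.leaf_phylo(leaves))
  if (length(leaves) == .n_tip(phy)) return(phy)
  ape::keep.tip(phy, leaves)
}

# canonical form of a rooted leaf-labeled tree: children ordered by
# (smallest leaf label, subtree string); isomorphism == string equality
.canon_node <- function(v, kids, labs, ntip) {
  if (v <= ntip) return(list(str = labs[v], min = labs[v]))
  sub <- lapply(kids[[v]], .canon_node, kids = kids, labs = labs, ntip = ntip)
  o <- order(vapply(sub, `[[`, "", "min"), vapply(sub, `[[`, "", "str"))
  sub <- sub[o]
  list(str = paste0("(", paste(vapply(sub, `[[`, "", "str"), collapse = ","), ")"),
       min = vapply(sub, `[[`, "", "min")[1L])
}

#' Canonical Newick form of a rooted tree
#'
#' Deterministic string representation: two rooted leaf-labeled trees are
#' isomorphic iff their canonical forms are equal.
#'
#' @param phy a `phylo` object.
#' @return a Newick string.
#' @export
canonical_newick <- function(phy) {
  if (.n_tip(phy) == 1L) return(paste0(phy$tip.label, ";"))
  kids <- .children_list(phy)
  paste0(.canon_node(.root_id(phy), kids, phy$tip.label, .n_tip(phy))$str, ";")
}

#' Does a tree display another tree?
#'
#' `tree` displays `subtree` iff restricting `tree` to the leaves of
#' `subtree` yields a tree isomorphic to `subtree`.
#'
#' @param tree,subtree `phylo` objects with `subtree`'s leaves contained in
#'   `tree`'s.
#' @return logical.
#' @export
displays <- function(tree, subtree) {
  labs <- subtree$tip.label
  miss <- setdiff(labs, tree$tip.label)
  if (length(miss))
    stop("subtree leaves absent from tree: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(labs) <= 1L) return(TRUE)
  identical(canonical_newick(restrict_tree(tree, labs)), canonical_newick(subtree))
}
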