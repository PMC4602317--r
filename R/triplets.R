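# Rooted triplets, the triplet graph, and the BUILD compatibility algorithm.
#
# tr(G) = { xy|z : some input tree restricted to {x,y,z} equals xy|z }.
# The triplet graph on a gene set V has an edge xy whenever a triplet xy|z
# has all three genes inside V. BUILD recursively decomposes the graph into
# connected components; a connected graph on >= 3 genes means the input
# trees are inconsistent.

#' Extract the rooted triplets of a set of gene trees
#'
#' Enumerates every 3-leaf restriction of every input tree and deduplicates
#' (`xy|z` with `x < y` lexicographically).
#'
#' @param trees a list of `phylo` gene trees, a single `phylo`, or an
#'   `sgt_instance`.
#' @return a data frame of class `sgt_triplets` with columns `x`, `y`, `z`.
#' @export
extract_triplets <- function(trees) {
  if (inherits(trees, "sgt_instance")) trees <- trees$gene_trees
  if (inherits(trees, "phylo")) trees <- list(trees)
  rows <- list()
  for (tr in trees) {
    nt <- .n_tip(tr)
    if (nt < 3L) next
    M <- .lca_table(tr)
    d <- .node_depths(tr)
    labs <- tr$tip.label
    idx <- combn(nt, 3L)
    for (j in seq_len(ncol(idx))) {
      u <- idx[1L, j]; v <- idx[2L, j]; w <- idx[3L, j]
      duv <- d[M[u, v]]; duw <- d[M[u, w]]; dvw <- d[M[v, w]]
      top <- min(duv, duw, dvw)
      # exactly one pairwise lca lies strictly below the triple's lca
      if (duv > top)      { a <- labs[u]; b <- labs[v]; z <- labs[w] }
      else if (duw > top) { a <- labs[u]; b <- labs[w]; z <- labs[v] }
      else                { a <- labs[v]; b <- labs[w]; z <- labs[u] }
      if (a > b) { t <- a; a <- b; b <- t }
      rows[[length(rows) + 1L]] <- c(a, b, z)
    }
  }
  if (!length(rows)) {
    out <- data.frame(x = character(), y = character(), z = character())
  } else {
    m <- do.call(rbind, rows)
    m <- m[!duplicated(paste(m[, 1], m[, 2], m[, 3], sep = "\r")), , drop = FALSE]
    out <- data.frame(x = m[, 1], y = m[, 2], z = m[, 3])
  }
  class(out) <- c("sgt_triplets", class(out))
  out
}

#' Triplet graph on a gene set
#'
#' Vertices are the genes of `genes`; an edge joins `x` and `y` whenever a
#' triplet `xy|z` has all three of `x`, `y`, `z` inside `genes`.
#'
#' @param triplets an `sgt_triplets` data frame.
#' @param genes character vector of genes (the vertex set).
#' @return an undirected `igraph` graph with vertex names.
#' @export
triplet_graph <- function(triplets, genes) {
  genes <- sort(unique(as.character(genes)))
  keep <- triplets$x %in% genes & triplets$y %in% genes & triplets$z %in% genes
  ep <- unique(data.frame(from = triplets$x[keep], to = triplets$y[keep]))
  g <- igraph::graph_from_data_frame(ep, directed = FALSE,
                                     vertices = data.frame(name = genes))
  igraph::simplify(g)
}

#' Connected components of a triplet graph
#'
#' @param graph an `igraph` graph with named vertices.
#' @return a list of character vectors (each sorted), ordered by their
#'   smallest gene label — the deterministic component order used throughout.
#' @export
triplet_components <- function(graph) {
  memb <- igraph::components(graph)$membership
  comps <- lapply(split(names(memb), memb), sort)
  comps <- comps[order(vapply(comps, `[[`, "", 1L))]
  unname(comps)
}

#' BUILD: test triplet compatibility and construct a supertree
#'
#' Recursive component decomposition of the triplet graph. Returns a
#' (possibly non-binary) tree displaying every triplet, or an inconsistency
#' verdict when some recursion level yields a connected graph on three or
#' more genes. A 2-gene level returns the cherry of the two genes.
#'
#' @param triplets an `sgt_triplets` data frame.
#' @param genes the full gene set to build over.
#' @return an object of class `sgt_build`: `consistent` (logical) and, when
#'   consistent, `tree` (`phylo`, possibly polytomous) and `newick`.
#' @export
build_supertree <- function(triplets, genes) {
  genes <- sort(unique(as.character(genes)))
  inconsistent <- FALSE
  rec <- function(gs) {
    if (inconsistent) return(NA_character_)
    if (length(gs) == 1L) return(gs)
    if (length(gs) == 2L) return(sprintf("(%s,%s)", gs[1L], gs[2L]))
    comps <- triplet_components(triplet_graph(triplets, gs))
    if (length(comps) == 1L) { inconsistent <<- TRUE; return(NA_character_) }
    ch <- vapply(comps, rec, "")
    if (inconsistent) return(NA_character_)
    sprintf("(%s)", paste(ch, collapse = ","))
  }
  nwk <- rec(genes)
  if (inconsistent)
    return(structure(list(consistent = FALSE, tree = NULL, newick = NULL),
                     class = "sgt_build"))
  nwk <- paste0(nwk, ";")
  structure(list(consistent = TRUE,
                 tree = ape::read.tree(text = nwk), newick = nwk),
            class = "sgt_build")
}

#' @export
print.sgt_build <- function(x, ...) {
  if (x$consistent) cat("CONSISTENT:", x$newick, "\n") else cat("INCONSISTENT\n")
  invisible(x)
}

#' Are the input gene trees consistent?
#'
#' Consistency means some supertree displays every input tree; decided by
#' running BUILD on the extracted triplet set.
#'
#' @param x an `sgt_instance`, or an `sgt_triplets` data frame (then `genes`
#'   must be given).
#' @param genes gene set, defaulting to the instance's gene family.
#' @return logical.
#' @export
is_consistent <- function(x, genes = NULL) {
  if (inherits(x, "sgt_instance")) {
    genes <- x$genes
    x <- extract_triplets(x)
  }
  if (is.null(genes)) stop("genes must be supplied with a triplet set", call. = FALSE)
  build_supertree(x, genes)$consistent
}
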