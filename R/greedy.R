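# Greedy heuristic for the duplication cost: at each level, group the
# triplet-graph components into the two sides of the root so that as many
# required duplications as possible merge into the single duplication
# created at that root — a weighted Max-Cut on the component graph — then
# recurse into both sides, pushing the remaining duplications downward.

.set_lca <- function(instance, genes) {
  idx <- instance$spidx
  ids <- unname(idx$leafid[instance$map[genes]])
  Reduce(function(a, b) idx$lcaM[a, b], ids)
}

# component graph relative to the species node `level`: an edge C1-C2 of
# weight d means d distinct triplets xy|z with {x,y} in one component and z
# in the other whose root is a duplication mapped to `level`
.component_graph_at <- function(comps, triplets, genes, instance, level) {
  idx <- instance$spidx
  memb <- setNames(rep(seq_along(comps), lengths(comps)), unlist(comps))
  keep <- triplets$x %in% genes & triplets$y %in% genes & triplets$z %in% genes
  tt <- triplets[keep, , drop = FALSE]
  ew <- new.env(parent = emptyenv())
  if (nrow(tt)) {
    spid <- function(g) unname(idx$leafid[instance$map[g]])
    for (r in seq_len(nrow(tt))) {
      cx <- memb[[tt$x[r]]]; cz <- memb[[tt$z[r]]]
      if (cx == cz) next                        # edge genes share a component
      sxy <- idx$lcaM[spid(tt$x[r]), spid(tt$y[r])]
      sz <- spid(tt$z[r])
      root <- idx$lcaM[sxy, sz]
      if (root != level) next
      if (root != sxy && root != sz) next       # separated: speciation root
      key <- paste(min(cx, cz), max(cx, cz))
      ew[[key]] <- (if (is.null(ew[[key]])) 0L else ew[[key]]) + 1L
    }
  }
  keys <- sort(names(as.list(ew)))
  edges <- if (length(keys)) {
    ij <- do.call(rbind, strsplit(keys, " "))
    data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
               weight = vapply(keys, function(k) ew[[k]], 0L),
               row.names = NULL)
  } else data.frame(i = integer(), j = integer(), weight = integer())
  structure(list(components = comps, edges = edges, level_node = level,
                 genes = sort(genes)),
            class = "sgt_component_graph")
}

#' Weighted component graph of required duplications
#'
#' Vertices are the connected components of the triplet graph on `genes`;
#' an edge of weight d joins two components when d distinct triplets
#' `xy|z` — `x`, `y` in one component, `z` in the other — have their root
#' mapped, as a duplication, to the LCA in the species tree of the species
#' of `genes` (the species-tree root when `genes` spans the full family).
#'
#' @param instance an `sgt_instance`.
#' @param genes gene subset (default: the full gene family).
#' @param triplets precomputed triplet set (default: extracted from the
#'   instance).
#' @return an object of class `sgt_component_graph` with fields
#'   `components` (list of gene sets, ordered by smallest label), `edges`
#'   (data frame `i`, `j`, `weight` over component indices), `level_node`.
#' @export
component_graph <- function(instance, genes = NULL, triplets = NULL) {
  if (is.null(genes)) genes <- instance$genes
  if (is.null(triplets)) triplets <- extract_triplets(instance)
  comps <- triplet_components(triplet_graph(triplets, genes))
  if (length(comps) < 2L)
    stop("triplet graph on the given genes has fewer than 2 components",
         call. = FALSE)
  .component_graph_at(comps, triplets, genes, instance, .set_lca(instance, genes))
}

#' @export
print.sgt_component_graph <- function(x, ...) {
  cat("Component graph:", length(x$components), "component(s),",
      nrow(x$edges), "weighted edge(s)\n")
  for (k in seq_along(x$components))
    cat(sprintf("  C%d = {%s}\n", k, paste(x$components[[k]], collapse = ",")))
  if (nrow(x$edges))
    for (r in seq_len(nrow(x$edges)))
      cat(sprintf("  C%d -- C%d  weight %d\n",
                  x$edges$i[r], x$edges$j[r], x$edges$weight[r]))
  invisible(x)
}

.cut_weight <- function(edges, in_side1) {
  if (!nrow(edges)) return(0L)
  sum(edges$weight[in_side1[edges$i] != in_side1[edges$j]])
}

#' Maximum cut of a component graph
#'
#' Exact bipartition enumeration for up to 25 vertices, or a seeded
#' multi-restart local search (single-vertex flips to a local optimum) for
#' larger graphs.
#'
#' @param graph an `sgt_component_graph`.
#' @param mode `"exact"` or `"local_search"`.
#' @param seed integer seed for the local search; `NULL` uses the current
#'   RNG state.
#' @param restarts number of local-search restarts.
#' @return an object of class `sgt_cut`: component indices `side1`, `side2`,
#'   gene sets `genes1`, `genes2`, and the cut `weight`.
#' @export
max_cut <- function(graph, mode = c("exact", "local_search"), seed = NULL,
                    restarts = 20L) {
  mode <- match.arg(mode)
  m <- length(graph$components)
  if (m < 2L) stop("Max-Cut needs at least 2 vertices", call. = FALSE)
  edges <- graph$edges
  finish <- function(in1, w) {
    s1 <- which(in1); s2 <- which(!in1)
    structure(list(side1 = s1, side2 = s2,
                   genes1 = sort(unlist(graph$components[s1])),
                   genes2 = sort(unlist(graph$components[s2])),
                   weight = as.integer(w)),
              class = "sgt_cut")
  }
  if (mode == "exact") {
    if (m > 25L)
      stop("too many components for exact Max-Cut; use mode = 'local_search'",
           call. = FALSE)
    best_w <- -1L; best <- NULL
    for (s in seq_len(bitwShiftL(1L, m - 1L) - 1L)) {
      in1 <- c(TRUE, bitwAnd(bitwShiftR(s, seq_len(m - 1L) - 1L), 1L) == 0L)
      w <- .cut_weight(edges, in1)
      if (w > best_w) { best_w <- w; best <- in1 }   # first max: smallest side2
    }
    return(finish(best, best_w))
  }
  run <- function() {
    best_w <- -1L; best <- NULL
    for (r in seq_len(restarts)) {
      in1 <- sample(c(TRUE, FALSE), m, replace = TRUE)
      if (all(in1)) in1[sample.int(m, 1L)] <- FALSE
      if (!any(in1)) in1[sample.int(m, 1L)] <- TRUE
      w <- .cut_weight(edges, in1)
      repeat {
        improved <- FALSE
        for (v in seq_len(m)) {
          cand <- in1; cand[v] <- !cand[v]
          if (!any(cand) || all(cand)) next
          cw <- .cut_weight(edges, cand)
          if (cw > w) { in1 <- cand; w <- cw; improved <- TRUE }
        }
        if (!improved) break
      }
      if (w > best_w) { best_w <- w; best <- in1 }
    }
    finish(best, best_w)
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), run()) else run()
}

#' @export
print.sgt_cut <- function(x, ...) {
  cat(sprintf("Max-Cut weight %d: ({%s}, {%s})\n", x$weight,
              paste(x$genes1, collapse = ","), paste(x$genes2, collapse = ",")))
  invisible(x)
}

# edgeless fallback: bipartition of the components minimizing the
# duplication flag, then imbalance, then the canonical encoding
.cheapest_bipartition <- function(comps, instance) {
  m <- length(comps)
  if (m > 20L) return(list(A = comps[[1L]], B = unlist(comps[-1L])))
  best <- NULL
  for (s in seq_len(bitwShiftL(1L, m - 1L) - 1L)) {
    pick <- c(FALSE, bitwAnd(bitwShiftR(s, seq_len(m - 1L) - 1L), 1L) == 1L)
    B <- unlist(comps[pick]); A <- unlist(comps[!pick])
    key <- c(dup_flag(instance, A, B), abs(length(A) - length(B)), s)
    if (is.null(best) || key[1] < best$key[1] ||
        (key[1] == best$key[1] && key[2] < best$key[2]))
      best <- list(A = A, B = B, key = key)
  }
  best
}

#' Greedy Max-Cut supergenetree heuristic
#'
#' Top-down construction: at each gene subset, build the component graph of
#' required duplications relative to that subset's species LCA, split the
#' components by a maximum cut (merging as many required duplications as
#' possible into the one duplication created at this node), and recurse.
#' When no required duplication crosses components, the bipartition with the
#' cheapest duplication flag (ties: most balanced) is taken instead.
#'
#' @param instance an `sgt_instance`.
#' @param maxcut Max-Cut mode, `"exact"` or `"local_search"`.
#' @param seed integer seed controlling all randomness (local search).
#' @return an `sgt_solution` with `method = "greedy"` and the duplication
#'   cost of the returned tree (computed by reconciliation).
#' @export
solve_greedy <- function(instance, maxcut = c("exact", "local_search"),
                         seed = 1L) {
  maxcut <- match.arg(maxcut)
  triplets <- extract_triplets(instance)
  if (!is_consistent(triplets, instance$genes))
    return(.sgt_solution(consistent = FALSE, tree = NULL, cost = Inf,
                         cost_type = "dup", method = "greedy"))
  rec <- function(gs) {
    if (length(gs) == 1L) return(gs)
    if (length(gs) == 2L) return(sprintf("(%s,%s)", gs[1L], gs[2L]))
    comps <- triplet_components(triplet_graph(triplets, gs))
    if (length(comps) == 1L)
      stop("internal error: connected triplet graph on a consistent instance")
    cg <- .component_graph_at(comps, triplets, gs, instance,
                              .set_lca(instance, gs))
    if (nrow(cg$edges)) {
      cut <- max_cut(cg, mode = maxcut, seed = NULL)
      A <- cut$genes1; B <- cut$genes2
    } else {
      bp <- .cheapest_bipartition(comps, instance)
      A <- bp$A; B <- bp$B
    }
    if (min(B) < min(A)) { tmp <- A; A <- B; B <- tmp }
    sprintf("(%s,%s)", rec(sort(A)), rec(sort(B)))
  }
  nwk <- withr::with_seed(as.integer(seed), rec(instance$genes))
  tree <- read_newick(paste0(nwk, ";"), "gene")
  .sgt_solution(consistent = TRUE, feasible = TRUE, tree = tree,
                cost = reconcile(tree, instance)$duplication_count,
                cost_type = "dup", method = "greedy",
                seed = as.integer(seed), maxcut = maxcut)
}
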