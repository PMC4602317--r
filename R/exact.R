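# Exact minimum-duplication / minimum-mutation supergenetree.
#
# Memoized recurrence over gene subsets P (bitmasks over the lexicographic
# gene order): R(P) is the optimal cost of a binary tree on P displaying all
# restricted inputs. At each subset the triplet graph on P is decomposed
# into connected components; every unordered bipartition (C, C-bar) of the
# component set is a candidate root split, contributing
#   R(V(C)) + R(V(C-bar)) + d(V(C), V(C-bar))
# where d is 0 when s(V(C)) and s(V(C-bar)) are separated in S (speciation)
# and 1 otherwise (duplication). For the mutation cost the node term is
# d plus the node's depth-difference losses. A connected graph on >= 3 genes
# scores Inf (no displaying tree exists on that subset).

# triplets encoded as bitmasks over the instance's sorted gene order
.encode_instance <- function(instance) {
  genes <- instance$genes
  n <- length(genes)
  bitv <- bitwShiftL(1L, seq_len(n) - 1L)
  tr <- extract_triplets(instance)
  xi <- match(tr$x, genes); yi <- match(tr$y, genes); zi <- match(tr$z, genes)
  pm <- bitv[xi] + bitv[yi]
  tm <- pm + bitv[zi]
  leafsp <- unname(instance$spidx$leafid[instance$map[genes]])
  list(genes = genes, n = n, bitv = bitv, xi = xi, yi = yi, zi = zi,
       pm = as.integer(pm), tm = as.integer(tm), leafsp = leafsp,
       lcaM = instance$spidx$lcaM, depth = instance$spidx$depth,
       root = instance$spidx$root)
}

#' Subset-LCA table
#'
#' For every nonempty subset X of the gene family (bitmask over the sorted
#' gene order), the species-tree node `s(X) = lca_S` of the species of X.
#' Computed in increasing subset order, one pairwise LCA per subset, so the
#' table costs O(2^n) time and memory.
#'
#' @param instance an `sgt_instance`.
#' @param cap refuse gene families larger than this (default 22); the table
#'   has `2^n - 1` entries.
#' @return an integer vector `t` with `t[mask]` the species node id of the
#'   subset encoded by `mask`; attribute `genes` gives the bit order.
#' @export
subset_lca_table <- function(instance, cap = 22L) {
  enc <- .encode_instance(instance)
  n <- enc$n
  if (n > cap)
    stop("gene family too large for the subset-LCA table (n = ", n,
         " > cap = ", cap, "); use solve_greedy() instead", call. = FALSE)
  total <- bitwShiftL(1L, n) - 1L
  L <- integer(total)
  L[enc$bitv] <- enc$leafsp
  lcaM <- enc$lcaM
  if (n > 1L) for (m in seq_len(total)) {
    if (bitwAnd(m, m - 1L) == 0L) next     # singleton, already set
    low <- bitwAnd(m, -m)
    L[m] <- lcaM[L[m - low], L[low]]
  }
  attr(L, "genes") <- enc$genes
  L
}

#' Duplication flag of a candidate bipartition
#'
#' 0 when `s(left)` and `s(right)` are separated in the species tree (the
#' split is a speciation node), 1 otherwise (a duplication node).
#'
#' @param instance an `sgt_instance`.
#' @param left,right disjoint nonempty gene sets (character vectors).
#' @return integer 0 or 1.
#' @export
dup_flag <- function(instance, left, right) {
  if (!length(left) || !length(right) || length(intersect(left, right)))
    stop("left and right must be disjoint and nonempty", call. = FALSE)
  idx <- instance$spidx
  sp_of <- function(gs) {
    ids <- unname(idx$leafid[instance$map[gs]])
    if (anyNA(ids)) stop("unknown gene(s)", call. = FALSE)
    Reduce(function(a, b) idx$lcaM[a, b], ids)
  }
  sa <- sp_of(left); sb <- sp_of(right)
  l <- idx$lcaM[sa, sb]
  if (l != sa && l != sb) 0L else 1L
}

# connected components (as bitmasks) of the triplet graph restricted to mask
.components_of <- function(mask, members, enc) {
  sel <- which(bitwAnd(enc$tm, mask) == enc$tm)
  uf <- seq_len(enc$n)
  find <- function(a) {
    while (uf[a] != a) { uf[a] <<- uf[uf[a]]; a <- uf[a] }
    a
  }
  for (t in sel) {
    ra <- find(enc$xi[t]); rb <- find(enc$yi[t])
    if (ra != rb) uf[rb] <- ra
  }
  roots <- vapply(members, find, 0L)
  # components ordered by smallest member index (members is ascending)
  out <- lapply(split(enc$bitv[members], factor(roots, levels = unique(roots))),
                function(b) as.integer(sum(b)))
  unname(out)
}

# shared DP machinery for solve_exact / solve_constrained_root
.dp_context <- function(instance, cost, cap) {
  enc <- .encode_instance(instance)
  n <- enc$n
  if (n > cap)
    stop("gene family too large for the exact solver (n = ", n,
         " > cap = ", cap, "); use solve_greedy() instead", call. = FALSE)
  L <- subset_lca_table(instance, cap = cap)
  lcaM <- enc$lcaM; depth <- enc$depth
  mutation <- identical(cost, "mutation")
  total <- bitwShiftL(1L, n) - 1L
  costv <- rep(NA_real_, total)
  choice <- rep(NA_integer_, total)

  node_cost <- function(ma, mb) {
    sa <- L[ma]; sb <- L[mb]
    l <- lcaM[sa, sb]
    if (l != sa && l != sb) {
      if (!mutation) return(0)
      (depth[sa] - depth[l] - 1L) + (depth[sb] - depth[l] - 1L)
    } else {
      if (!mutation) return(1)
      1 + (depth[sa] - depth[l]) + (depth[sb] - depth[l])
    }
  }

  dp <- function(mask) {
    v <- costv[mask]
    if (!is.na(v)) return(v)
    members <- which(bitwAnd(mask, enc$bitv) != 0L)
    if (length(members) <= 1L) { costv[mask] <<- 0; return(0) }
    comps <- .components_of(mask, members, enc)
    m <- length(comps)
    if (m == 1L) { costv[mask] <<- Inf; return(Inf) }   # connected, >= 3 genes
    best <- Inf; best_tie <- Inf; best_mb <- NA_integer_
    rest <- comps[-1L]
    for (s in seq_len(bitwShiftL(1L, m - 1L) - 1L)) {
      mb <- 0L; ss <- s; i <- 1L
      while (ss > 0L) {
        if (bitwAnd(ss, 1L) == 1L) mb <- mb + rest[[i]]
        ss <- bitwShiftR(ss, 1L); i <- i + 1L
      }
      ma <- bitwXor(mask, mb)
      tot <- dp(ma) + dp(mb) + node_cost(ma, mb)
      tie <- min(ma, mb)
      if (tot < best || (tot == best && tie < best_tie)) {
        best <- tot; best_tie <- tie; best_mb <- mb
      }
    }
    costv[mask] <<- best
    choice[mask] <<- best_mb
    best
  }

  rebuild <- function(mask) {
    members <- which(bitwAnd(mask, enc$bitv) != 0L)
    if (length(members) == 1L) return(enc$genes[members])
    mb <- choice[mask]
    ma <- bitwXor(mask, mb)
    sprintf("(%s,%s)", rebuild(ma), rebuild(mb))
  }

  mask_of <- function(gs) as.integer(sum(enc$bitv[match(gs, enc$genes)]))

  list(enc = enc, dp = dp, rebuild = rebuild, node_cost = node_cost,
       mask_of = mask_of, total = total,
       components_full = function() {
         members <- seq_len(n)
         .components_of(total, members, enc)
       })
}

.sgt_solution <- function(..., class = character()) {
  structure(list(...), class = c(class, "sgt_solution"))
}

#' @export
print.sgt_solution <- function(x, ...) {
  if (!isTRUE(x$consistent)) {
    cat("INCONSISTENT: no supertree displays all input trees\n")
    return(invisible(x))
  }
  if (!is.null(x$feasible) && !x$feasible) {
    cat("INFEASIBLE under the given constraint\n")
    return(invisible(x))
  }
  cat(sprintf("Supergenetree (%s, %s cost = %s)\n%s\n",
              x$method, x$cost_type, format(x$cost), write_newick(x$tree)))
  invisible(x)
}

#' Exact minimum-cost supergenetree
#'
#' Dynamic program over gene subsets; returns a binary supertree displaying
#' every input tree with minimum duplication (or mutation) cost.
#'
#' @param instance an `sgt_instance`.
#' @param cost `"dup"` or `"mutation"`.
#' @param cap refuse gene families larger than this (default 22: about 4M
#'   subsets).
#' @return an `sgt_solution`: `consistent`, `tree` (`phylo`), `cost`,
#'   `cost_type`, `method = "dp"`.
#' @export
solve_exact <- function(instance, cost = c("dup", "mutation"), cap = 22L) {
  cost <- match.arg(cost)
  if (!is_consistent(instance))
    return(.sgt_solution(consistent = FALSE, tree = NULL, cost = Inf,
                         cost_type = cost, method = "dp"))
  ctx <- .dp_context(instance, cost, cap)
  val <- ctx$dp(ctx$total)
  tree <- read_newick(paste0(ctx$rebuild(ctx$total), ";"), "gene")
  .sgt_solution(consistent = TRUE, feasible = TRUE, tree = tree, cost = val,
                cost_type = cost, method = "dp")
}

#' Optimal supergenetree under a fixed root bipartition
#'
#' Minimum cost over supertrees whose root splits the gene family exactly
#' into `left` versus its complement; `Inf` (infeasible) when no displaying
#' supertree has that root split.
#'
#' @param instance an `sgt_instance`.
#' @param left character vector: the genes on one side of the root.
#' @inheritParams solve_exact
#' @return an `sgt_solution` with `feasible` flag; `cost = Inf` and
#'   `tree = NULL` when the split is incompatible.
#' @export
solve_constrained_root <- function(instance, left, cost = c("dup", "mutation"),
                                   cap = 22L) {
  cost <- match.arg(cost)
  left <- unique(as.character(left))
  right <- setdiff(instance$genes, left)
  if (!length(left) || !length(right) || !all(left %in% instance$genes))
    stop("left must be a nonempty proper subset of the gene family", call. = FALSE)
  if (!is_consistent(instance))
    return(.sgt_solution(consistent = FALSE, tree = NULL, cost = Inf,
                         cost_type = cost, method = "dp_constrained"))
  ctx <- .dp_context(instance, cost, cap)
  ma <- ctx$mask_of(left)
  mb <- bitwXor(ctx$total, ma)
  # a feasible root split cannot break a triplet-graph component
  straddles <- any(vapply(ctx$components_full(), function(cm)
    bitwAnd(cm, ma) != 0L && bitwAnd(cm, mb) != 0L, NA))
  if (straddles)
    return(.sgt_solution(consistent = TRUE, feasible = FALSE, tree = NULL,
                         cost = Inf, cost_type = cost, method = "dp_constrained",
                         root_split = list(left = sort(left), right = sort(right))))
  val <- ctx$dp(ma) + ctx$dp(mb) + ctx$node_cost(ma, mb)
  if (!is.finite(val))
    return(.sgt_solution(consistent = TRUE, feasible = FALSE, tree = NULL,
                         cost = Inf, cost_type = cost, method = "dp_constrained",
                         root_split = list(left = sort(left), right = sort(right))))
  nwk <- sprintf("(%s,%s);", ctx$rebuild(ma), ctx$rebuild(mb))
  .sgt_solution(consistent = TRUE, feasible = TRUE,
                tree = read_newick(nwk, "gene"), cost = val, cost_type = cost,
                method = "dp_constrained",
                root_split = list(left = sort(left), right = sort(right)))
}
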