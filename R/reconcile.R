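# LCA-mapping reconciliation of a gene tree against the species tree.
#
# Every internal gene-tree node x is mapped to s(x) = lca_S of the species of
# the genes below x. x is a speciation node when its children's images are
# separated in S (neither ancestral-or-equal to the other), otherwise a
# duplication. Losses follow the standard depth-difference count: with
# e(x,c) the number of S-edges between s(x) and s(c),
#   speciation x:  (e(x,x_l) - 1) + (e(x,x_r) - 1)
#   duplication x:  e(x,x_l) + e(x,x_r)
# summed over internal nodes. The mutation (reconciliation) cost is
# duplications + losses.

.as_species_ctx <- function(species, map) {
  if (inherits(species, "sgt_instance"))
    list(species = species$species, map = species$map, idx = species$spidx)
  else
    list(species = species, map = map, idx = .sp_index(species))
}

#' Reconcile a gene tree with a species tree
#'
#' Computes the LCA node mapping, speciation/duplication labels, and the
#' duplication, loss and mutation costs.
#'
#' @param tree gene tree (`phylo`).
#' @param species species tree (`phylo`) or an `sgt_instance` (in which case
#'   `map` is taken from the instance).
#' @param map named character vector `gene -> species`.
#' @return an object of class `sgt_reconciliation`: fields `node_map`
#'   (species node id per gene-tree node), `label` (`"speciation"` /
#'   `"duplication"` per node, `NA` for leaves), `pre_speciation` (logical
#'   per node: duplication mapped to the species root), `node_losses`,
#'   `duplication_count`, `loss_count`, `mutation_cost`.
#' @examples
#' S <- read_newick("((a,b),(c,d));", "species")
#' g <- read_newick("(ga,gc);", "gene")
#' reconcile(g, S, c(ga = "a", gc = "c"))
#' @export
reconcile <- function(tree, species, map = NULL) {
  ctx <- .as_species_ctx(species, map)
  nt <- .n_tip(tree)
  N <- .n_node(tree)
  smap <- integer(N)
  sp_labels <- ctx$map[tree$tip.label]
  if (anyNA(sp_labels))
    stop("unmapped gene(s): ",
         paste(tree$tip.label[is.na(sp_labels)], collapse = ", "), call. = FALSE)
  leaf_ids <- ctx$idx$leafid[sp_labels]
  if (anyNA(leaf_ids))
    stop("species absent from species tree: ",
         paste(unique(sp_labels[is.na(leaf_ids)]), collapse = ", "), call. = FALSE)
  smap[seq_len(nt)] <- leaf_ids
  label <- rep(NA_character_, N)
  node_losses <- rep(NA_integer_, N)
  pre_spec <- rep(FALSE, N)
  lcaM <- ctx$idx$lcaM
  depth <- ctx$idx$depth
  if (nt >= 2L) {
    kids <- .children_list(tree)
    for (v in .postorder_internal(tree)) {
      l <- kids[[v]][1L]; r <- kids[[v]][2L]
      sl <- smap[l]; sr <- smap[r]
      sv <- lcaM[sl, sr]
      smap[v] <- sv
      el <- depth[sl] - depth[sv]
      er <- depth[sr] - depth[sv]
      if (sv == sl || sv == sr) {       # one image ancestral to the other
        label[v] <- "duplication"
        node_losses[v] <- el + er
        pre_spec[v] <- sv == ctx$idx$root
      } else {
        label[v] <- "speciation"
        node_losses[v] <- (el - 1L) + (er - 1L)
      }
    }
  }
  dup <- sum(label == "duplication", na.rm = TRUE)
  loss <- sum(node_losses, na.rm = TRUE)
  structure(list(tree = tree, node_map = smap, label = label,
                 pre_speciation = pre_spec, node_losses = node_losses,
                 duplication_count = dup, loss_count = loss,
                 mutation_cost = dup + loss),
            class = "sgt_reconciliation")
}

#' @export
print.sgt_reconciliation <- function(x, ...) {
  cat("LCA reconciliation:", x$duplication_count, "duplication(s),",
      x$loss_count, "loss(es), mutation cost", x$mutation_cost, "\n")
  invisible(x)
}

#' Reconciliation cost of a gene tree
#'
#' @inheritParams reconcile
#' @param cost `"dup"` (duplications only) or `"mutation"`
#'   (duplications + losses).
#' @return an integer cost.
#' @export
reconciliation_cost <- function(tree, species, map = NULL,
                                cost = c("dup", "mutation")) {
  cost <- match.arg(cost)
  r <- reconcile(tree, species, map)
  if (cost == "dup") r$duplication_count else r$mutation_cost
}

#' Minimum number of losses under LCA reconciliation
#' @inheritParams reconcile
#' @return an integer `>= 0`.
#' @export
count_losses <- function(tree, species, map = NULL)
  reconcile(tree, species, map)$loss_count

#' Gene tree annotated with reconciliation labels
#'
#' Returns the input tree with internal node labels `"D"` (duplication) or
#' `"S"` (speciation), suitable for Newick output.
#'
#' @inheritParams reconcile
#' @return a `phylo` with `node.label` set.
#' @export
annotate_tree <- function(tree, species, map = NULL) {
  r <- reconcile(tree, species, map)
  nt <- .n_tip(tree)
  lab <- r$label[(nt + 1L):.n_node(tree)]
  tree$node.label <- ifelse(lab == "duplication", "D", "S")
  tree
}

#' Is a triplet's root a required duplication at the species root?
#'
#' A triplet `xy|z` found in the input trees forces a duplication in every
#' compatible supertree when its root, under LCA reconciliation, is a
#' duplication mapped to the species-tree root.
#'
#' @param triplet a 3-leaf binary gene tree (`phylo`).
#' @inheritParams reconcile
#' @return logical.
#' @export
required_duplication <- function(triplet, species, map = NULL) {
  if (.n_tip(triplet) != 3L) stop("expected a 3-leaf triplet tree", call. = FALSE)
  ctx <- .as_species_ctx(species, map)
  r <- reconcile(triplet, ctx$species, ctx$map)
  root <- .root_id(triplet)
  identical(r$label[root], "duplication") && r$node_map[root] == ctx$idx$root
}

#' Does a supertree preserve the speciations of the input trees?
#'
#' For independent speciation trees (pairwise disjoint leaf sets), checks
#' that the restriction of `tree` to each input leaf set is displayed and
#' contains only speciation nodes.
#'
#' @param tree candidate supertree (`phylo`) over the instance's gene family.
#' @param instance an `sgt_instance` with pairwise disjoint input leaf sets.
#' @return logical.
#' @export
preserves_speciations <- function(tree, instance) {
  if (instance$overlapping)
    stop("input leaf sets overlap: speciation preservation requires disjoint inputs",
         call. = FALSE)
  for (g in instance$gene_trees) {
    labs <- g$tip.label
    if (!displays(tree, g)) return(FALSE)
    if (length(labs) < 2L) next
    r <- reconcile(restrict_tree(tree, labs), instance)
    if (r$duplication_count > 0L) return(FALSE)
  }
  TRUE
}
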