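# Problem instances: a binary species tree S over species set Sigma, a gene
# family Gamma with a total mapping s: Gamma -> Sigma, and k rooted binary
# gene trees on possibly overlapping subsets of Gamma.

#' Read a gene-to-species mapping table
#'
#' Two-column tab-separated file with header `gene<TAB>species`.
#'
#' @param path file path.
#' @return a named character vector mapping gene ids to species labels.
#' @export
read_gene_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (!all(c("gene", "species") %in% names(tab)))
    stop("mapping file must have columns 'gene' and 'species'", call. = FALSE)
  if (anyDuplicated(tab$gene))
    stop("duplicate gene ids in mapping file", call. = FALSE)
  setNames(tab$species, tab$gene)
}

#' Derive a gene-to-species mapping from leaf labels
#'
#' Fallback convention for labels of the form `species_gene`: the species is
#' everything before the first separator.
#'
#' @param genes character vector of gene ids.
#' @param sep separator character (default `"_"`).
#' @return a named character vector mapping each gene to a species.
#' @export
map_from_prefix <- function(genes, sep = "_") {
  sp <- sub(paste0(sep, ".*$"), "", genes)
  if (any(sp == genes))
    stop("gene id(s) without a '", sep, "' separator: ",
         paste(genes[sp == genes], collapse = ", "), call. = FALSE)
  setNames(sp, genes)
}

# species-tree lookup index carried by each instance
.sp_index <- function(species) {
  list(depth  = .node_depths(species),
       lcaM   = .lca_table(species),
       leafid = setNames(seq_len(.n_tip(species)), species$tip.label),
       root   = .root_id(species))
}

#' Construct a supergenetree problem instance
#'
#' Validates and bundles a species tree, a list of gene trees, and a
#' gene-to-species mapping. The gene family Gamma is the union of the gene
#' trees' leaf sets; leaf sets may overlap (the usual supertree setting).
#' The independent-speciation mode instead requires pairwise disjoint leaf
#' sets: set `require_disjoint = TRUE` to enforce that at load time.
#'
#' @param species species tree (`phylo`, binary, unique leaf labels).
#' @param gene_trees list of gene trees (`phylo`); a single `phylo` is
#'   accepted and wrapped.
#' @param map named character vector `gene -> species` covering every leaf of
#'   every gene tree; targets must be leaves of `species`.
#' @param require_disjoint reject instances whose input trees share genes.
#' @return an object of class `sgt_instance` with fields `species`,
#'   `gene_trees`, `map`, `genes` (sorted Gamma) and `overlapping`.
#' @export
sgt_instance <- function(species, gene_trees, map, require_disjoint = FALSE) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  if (!length(gene_trees)) stop("empty gene-tree list", call. = FALSE)
  .check_binary(species, "species tree")
  if (anyDuplicated(species$tip.label))
    stop("duplicate species labels", call. = FALSE)
  for (g in gene_trees) {
    if (.n_tip(g) >= 2L) .check_binary(g, "gene tree")
    if (anyDuplicated(g$tip.label))
      stop("duplicate gene ids within a gene tree", call. = FALSE)
  }
  leafsets <- lapply(gene_trees, `[[`, "tip.label")
  all_genes <- unlist(leafsets)
  overlapping <- anyDuplicated(all_genes) > 0L
  if (overlapping && require_disjoint)
    stop("gene id(s) occur in more than one input tree, but disjoint ",
         "leaf sets were required", call. = FALSE)
  genes <- sort(unique(all_genes))
  unmapped <- setdiff(genes, names(map))
  if (length(unmapped))
    stop("unmapped gene(s): ", paste(unmapped, collapse = ", "), call. = FALSE)
  bad_sp <- setdiff(unique(map[genes]), species$tip.label)
  if (length(bad_sp))
    stop("mapped species absent from species tree: ",
         paste(bad_sp, collapse = ", "), call. = FALSE)
  structure(list(species = species, gene_trees = gene_trees,
                 map = map[genes], genes = genes, overlapping = overlapping,
                 spidx = .sp_index(species), truth = NULL),
            class = "sgt_instance")
}

#' @export
print.sgt_instance <- function(x, ...) {
  cat("Supergenetree instance:", length(x$genes), "genes,",
      .n_tip(x$species), "species,", length(x$gene_trees), "input tree(s)\n")
  if (!is.null(x$truth))
    cat("Simulated; true tree has", x$truth$duplication_count, "duplication(s) and",
        x$truth$loss_count, "loss(es)\n")
  invisible(x)
}

#' Load an instance from files or objects
#'
#' @param species species tree: `phylo`, Newick string or file path.
#' @param gene_trees list of `phylo`, or a file with one Newick per line.
#' @param map named character vector or path of a `gene<TAB>species` table;
#'   ignored when `use_prefix_map = TRUE`.
#' @param use_prefix_map derive the mapping from `species_gene` leaf labels.
#' @param require_disjoint see [sgt_instance()].
#' @return an `sgt_instance`.
#' @export
load_instance <- function(species, gene_trees, map = NULL,
                          use_prefix_map = FALSE,
                          require_disjoint = FALSE) {
  if (!inherits(species, "phylo")) species <- read_newick(species, "species")
  if (is.character(gene_trees)) gene_trees <- read_gene_trees(gene_trees)
  genes <- sort(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  if (use_prefix_map) {
    map <- map_from_prefix(genes)
  } else if (is.character(map) && is.null(names(map))) {
    map <- read_gene_map(map)
  }
  if (is.null(map)) stop("a gene-to-species mapping is required", call. = FALSE)
  sgt_instance(species, gene_trees, map, require_disjoint)
}

#' Write an instance to a directory
#'
#' Emits `species.nwk`, `genetrees.nwk` (one Newick per line), `map.tsv`
#' (header `gene<TAB>species`) and, for simulated instances, `truth.json`
#' with the true tree and its duplication/loss counts.
#'
#' @param instance an `sgt_instance`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_instance <- function(instance, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("species.nwk", "genetrees.nwk", "map.tsv"))
  writeLines(write_newick(instance$species), paths[1])
  writeLines(vapply(instance$gene_trees, write_newick, ""), paths[2])
  tab <- data.frame(gene = names(instance$map), species = unname(instance$map))
  utils::write.table(tab, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(instance$truth)) {
    tp <- file.path(dir, "truth.json")
    jsonlite::write_json(list(tree = write_newick(instance$truth$tree),
                              duplication_count = instance$truth$duplication_count,
                              loss_count = instance$truth$loss_count),
                         tp, auto_unbox = TRUE)
    paths <- c(paths, tp)
  }
  invisible(paths)
}

#' Read an instance written by [write_instance()]
#'
#' @param dir directory containing `species.nwk`, `genetrees.nwk`, `map.tsv`
#'   and optionally `truth.json`.
#' @param require_disjoint see [sgt_instance()].
#' @return an `sgt_instance` (with `$truth` restored when present).
#' @export
read_instance <- function(dir, require_disjoint = FALSE) {
  inst <- load_instance(file.path(dir, "species.nwk"),
                        file.path(dir, "genetrees.nwk"),
                        file.path(dir, "map.tsv"),
                        require_disjoint = require_disjoint)
  tp <- file.path(dir, "truth.json")
  if (file.exists(tp)) {
    tr <- jsonlite::read_json(tp)
    inst$truth <- list(tree = read_newick(tr$tree, "gene"),
                       duplication_count = as.integer(tr$duplication_count),
                       loss_count = as.integer(tr$loss_count))
  }
  inst
}
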