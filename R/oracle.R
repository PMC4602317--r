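# Brute-force ground truth: enumerate every rooted binary leaf-labeled tree
# on the gene family ((2n-3)!! of them), keep those displaying all inputs,
# and minimize the reconciliation cost directly. Independent of the dynamic
# program: feasibility is decided from clusters (a triplet xy|z is displayed
# iff some cluster contains x and y but not z), costs from per-node LCA maps.
#
# Tree shapes for a given n are enumerated once and cached: each shape is a
# pair of integer vectors L, R of length n-1 listing the children of the
# internal nodes in postorder (ids 1..n are leaves, n+i is internal node i;
# the root is 2n-1).

.enum_shapes <- function(n) {
  key <- paste0("shapes", n)
  if (!is.null(.sgt_cache[[key]])) return(.sgt_cache[[key]])
  stopifnot(n >= 2L)
  ins <- function(tr, lf) {
    out <- list(list(tr, lf))
    if (is.list(tr)) {
      out <- c(out,
               lapply(ins(tr[[1L]], lf), function(x) list(x, tr[[2L]])),
               lapply(ins(tr[[2L]], lf), function(x) list(tr[[1L]], x)))
    }
    out
  }
  trees <- list(list(1L, 2L))
  if (n > 2L) for (k in 3:n)
    trees <- unlist(lapply(trees, ins, lf = k), recursive = FALSE)
  nt <- length(trees)
  Lm <- matrix(0L, nt, n - 1L)
  Rm <- matrix(0L, nt, n - 1L)
  for (t in seq_len(nt)) {
    i <- 0L
    Lv <- integer(n - 1L); Rv <- integer(n - 1L)
    rec <- function(tr) {
      if (!is.list(tr)) return(tr)
      l <- rec(tr[[1L]]); r <- rec(tr[[2L]])
      i <<- i + 1L
      Lv[i] <<- l; Rv[i] <<- r
      n + i
    }
    rec(trees[[t]])
    Lm[t, ] <- Lv; Rm[t, ] <- Rv
  }
  res <- list(L = Lm, R = Rm, n = n)
  .sgt_cache[[key]] <- res
  res
}

.shape_newick <- function(sh, row, genes) {
  n <- sh$n
  rec <- function(id) {
    if (id <= n) return(genes[id])
    sprintf("(%s,%s)", rec(sh$L[row, id - n]), rec(sh$R[row, id - n]))
  }
  paste0(rec(2L * n - 1L), ";")
}

#' Number of rooted binary leaf-labeled trees
#'
#' The double factorial `(2n-3)!!`.
#'
#' @param n number of leaves (`>= 2`).
#' @return a number.
#' @export
count_rooted_trees <- function(n) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  prod(seq(1, 2 * n - 3, by = 2))
}

#' Enumeration oracle for the supergenetree problem
#'
#' Enumerates all rooted binary trees on the gene family, keeps those
#' displaying every input tree (and, optionally, preserving all input
#' speciations), and returns a minimum-cost tree. Exponential; intended as
#' ground truth on small instances.
#'
#' @param instance an `sgt_instance`.
#' @param cost `"dup"` or `"mutation"`.
#' @param constraint `"none"`, or `"preserve_speciations"` (requires
#'   pairwise disjoint input leaf sets).
#' @param cap refuse gene families larger than this (default 8; `(2n-3)!!`
#'   trees are enumerated).
#' @return an `sgt_solution` with `method = "oracle"` and extra fields
#'   `n_enumerated` and `n_feasible`; `feasible = FALSE` when no tree
#'   satisfies the constraint.
#' @export
oracle_enumerate <- function(instance, cost = c("dup", "mutation"),
                             constraint = c("none", "preserve_speciations"),
                             cap = 8L) {
  cost <- match.arg(cost)
  constraint <- match.arg(constraint)
  enc <- .encode_instance(instance)
  n <- enc$n
  if (n > cap)
    stop("gene family too large for the enumeration oracle (n = ", n,
         " > cap = ", cap, ")", call. = FALSE)
  if (n < 2L) stop("need at least 2 genes", call. = FALSE)
  if (constraint == "preserve_speciations" && instance$overlapping)
    stop("speciation preservation requires disjoint input leaf sets", call. = FALSE)
  sh <- .enum_shapes(n)
  nt <- nrow(sh$L)
  seqt <- seq_len(nt)
  lcaM <- enc$lcaM; depth <- enc$depth
  Nn <- 2L * n - 1L
  spm <- matrix(0L, nt, Nn)
  msk <- matrix(0L, nt, Nn)
  for (j in seq_len(n)) { spm[, j] <- enc$leafsp[j]; msk[, j] <- enc$bitv[j] }
  ML <- matrix(0L, nt, n - 1L); MR <- matrix(0L, nt, n - 1L)
  dupm <- matrix(FALSE, nt, n - 1L)
  lossm <- matrix(0L, nt, n - 1L)
  for (i in seq_len(n - 1L)) {
    l <- sh$L[, i]; r <- sh$R[, i]
    sl <- spm[cbind(seqt, l)]; sr <- spm[cbind(seqt, r)]
    ll <- lcaM[cbind(sl, sr)]
    spm[, n + i] <- ll
    ml <- msk[cbind(seqt, l)]; mr <- msk[cbind(seqt, r)]
    msk[, n + i] <- ml + mr
    ML[, i] <- ml; MR[, i] <- mr
    isd <- ll == sl | ll == sr
    dupm[, i] <- isd
    e <- (depth[sl] - depth[ll]) + (depth[sr] - depth[ll])
    lossm[, i] <- ifelse(isd, e, e - 2L)
  }
  # a tree displays all inputs iff it displays every extracted triplet
  feas <- rep(TRUE, nt)
  for (t in seq_along(enc$pm)) {
    pmv <- enc$pm[t]; zb <- enc$bitv[enc$zi[t]]
    ok <- rep(FALSE, nt)
    for (i in seq_len(n - 1L)) {
      mi <- msk[, n + i]
      ok <- ok | (bitwAnd(mi, pmv) == pmv & bitwAnd(mi, zb) == 0L)
    }
    feas <- feas & ok
  }
  n_feasible <- sum(feas)
  sel <- feas
  if (constraint == "preserve_speciations") {
    tabL <- subset_lca_table(instance, cap = cap)
    for (g in instance$gene_trees) {
      gm <- as.integer(sum(enc$bitv[match(g$tip.label, enc$genes)]))
      for (i in seq_len(n - 1L)) {
        al <- bitwAnd(ML[, i], gm); ar <- bitwAnd(MR[, i], gm)
        act <- al != 0L & ar != 0L
        if (!any(act)) next
        sa <- tabL[al[act]]; sb <- tabL[ar[act]]
        l2 <- lcaM[cbind(sa, sb)]
        bad <- l2 == sa | l2 == sb     # not separated: a duplication survives
        idx <- which(act)[bad]
        sel[idx] <- FALSE
      }
    }
  }
  if (!any(sel))
    return(.sgt_solution(consistent = n_feasible > 0L, feasible = FALSE,
                         tree = NULL, cost = Inf, cost_type = cost,
                         method = "oracle", constraint = constraint,
                         n_enumerated = nt, n_feasible = n_feasible))
  dupc <- rowSums(dupm)
  val <- if (cost == "dup") dupc else dupc + rowSums(lossm)
  val[!sel] <- Inf
  best <- which.min(val)   # first minimum: deterministic under the fixed order
  .sgt_solution(consistent = TRUE, feasible = TRUE,
                tree = read_newick(.shape_newick(sh, best, enc$genes), "gene"),
                cost = val[best], cost_type = cost, method = "oracle",
                constraint = constraint,
                n_enumerated = nt, n_feasible = n_feasible)
}
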