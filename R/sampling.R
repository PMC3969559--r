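## Representative sampling of LECA clades: least-squares rooting of the clade
## tree followed by iterative pruning of the deepest leaves, keeping k
## representatives of the clade's sequence diversity.

#' Root a tree by the least-squares (minimal depth variance) criterion
#'
#' Places the root at the point, on any edge, minimising the sum of squared
#' deviations of root-to-leaf path lengths from their mean. On each edge the
#' optimum is solved in closed form (the objective is quadratic in the
#' position along the edge); the global optimum is found by scanning all
#' edges. On a perfectly clock-like tree this recovers the point from which
#' the tree is ultrametric, with criterion 0.
#'
#' @param tree A `phylo` with branch lengths and at least 2 leaves. Rooted
#'   input is treated as unrooted.
#' @return A list of class `ls_rooted` with elements `tree` (rooted
#'   `phylo`), `score` (the minimised criterion), `edge` (the two node
#'   numbers of the winning edge of the unrooted tree) and `position`
#'   (distance of the root from the parent end of that edge).
#' @export
least_squares_root <- function(tree) {
  if (ape::Ntip(tree) < 2L) stop("need at least 2 leaves to root")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; using 1.0 throughout", call. = FALSE)
    tree$edge.length <- rep(1, nrow(tree$edge))
  }

  if (ape::Ntip(tree) == 2L) { # midpoint of the single path
    labs <- sort(tree$tip.label)
    h <- sum(tree$edge.length) / 2
    out <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);",
                                         labs[1L], h, labs[2L], h))
    return(structure(list(tree = out, score = 0,
                          edge = c(NA_integer_, NA_integer_), position = h),
                     class = "ls_rooted"))
  }

  tree <- .as_unrooted(tree)
  n <- ape::Ntip(tree)
  M <- clan_matrix(tree)
  D <- ape::dist.nodes(tree)

  all_zero <- all(tree$edge.length == 0)
  if (all_zero)
    warning("all branch lengths are zero; rooting at the first edge midpoint",
            call. = FALSE)

  best <- list(score = Inf, edge = NA, x = NA)
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1L]; v <- tree$edge[k, 2L]
    L <- tree$edge.length[k]
    on_v <- M[v, ]                       # leaves on the child side
    ## leaf depth as a function of x = distance from u along the edge:
    ## u-side leaves: d(u, leaf) + x;  v-side leaves: d(v, leaf) + (L - x)
    c0 <- ifelse(on_v, D[v, seq_len(n)] + L, D[u, seq_len(n)])
    s <- ifelse(on_v, -1, 1)
    e <- c0 - mean(c0)
    t <- s - mean(s)
    tt <- sum(t * t)
    x <- if (tt > 0) max(0, min(L, -sum(e * t) / tt)) else L / 2
    score <- sum((e + t * x)^2)
    if (score < best$score - 1e-12) best <- list(score = score, edge = k, x = x)
  }
  if (all_zero) best <- list(score = 0, edge = 1L, x = 0)

  u <- tree$edge[best$edge, 1L]; v <- tree$edge[best$edge, 2L]
  L <- tree$edge.length[best$edge]
  ## phytools::reroot places the root at `position` from the parent end
  pos <- min(max(best$x, 0), L)
  rooted <- phytools::reroot(tree, node.number = v, position = pos)
  structure(list(tree = rooted, score = best$score,
                 edge = c(u, v), position = pos),
            class = "ls_rooted")
}

#' @export
print.ls_rooted <- function(x, ...) {
  cat("Least-squares rooted tree:", ape::Ntip(x$tree), "leaves; criterion =",
      format(x$score, digits = 6), "\n")
  invisible(x)
}

## node-count and path-length depths of every tip of a rooted tree
.tip_depths <- function(tree) {
  nt <- ape::Ntip(tree)
  bl <- ape::node.depth.edgelength(tree)[seq_len(nt)]
  unit <- tree
  unit$edge.length <- rep(1, nrow(tree$edge))
  nw <- ape::node.depth.edgelength(unit)[seq_len(nt)]
  list(nodewise = nw, lengthwise = bl, labels = tree$tip.label)
}

#' Prune a rooted clade tree to k representative leaves
#'
#' Iteratively removes the leaf that is deepest node-wise (most edges from
#' the root); among node-wise ties, the leaf with the greatest root-to-leaf
#' path length is removed; residual ties are resolved by removing the
#' lexicographically greatest label. After each removal, unary nodes are
#' suppressed (their branch lengths summed) and depths are recomputed, so the
#' deepest-leaf criterion always refers to the current, reduced tree. The
#' procedure favours short-branched leaves near the root, i.e. it retains
#' sequence diversity while shedding the longest-branched sequences.
#'
#' @param rooted A [least_squares_root()] result or a rooted `phylo`.
#' @param k Number of representatives to keep (default 10).
#' @return Sorted character vector of the retained leaf labels (all leaves
#'   if there are at most `k`).
#' @export
prune_to_k <- function(rooted, k = 10) {
  if (k < 1) stop("k must be >= 1")
  tree <- if (inherits(rooted, "ls_rooted")) rooted$tree else rooted
  if (!inherits(tree, "phylo")) stop("expected a phylo or ls_rooted object")
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))

  while (ape::Ntip(tree) > k) {
    d <- .tip_depths(tree)
    cand <- which(d$nodewise == max(d$nodewise))
    if (length(cand) > 1L)
      cand <- cand[d$lengthwise[cand] == max(d$lengthwise[cand])]
    drop <- d$labels[cand]
    drop <- sort(drop)[length(drop)]     # residual tie: greatest label
    if (ape::Ntip(tree) == 2L)
      return(setdiff(d$labels, drop))
    tree <- ape::drop.tip(tree, drop)
  }
  sort(tree$tip.label)
}

#' Select representative sequences for a LECA clade
#'
#' Extracts the clade's subtree from the gene tree (with branch lengths),
#' roots it by the least-squares criterion and prunes it to `k` leaves.
#'
#' @param tree The gene-family `phylo` containing the clade.
#' @param clade_leaves Leaf labels of the (monophyletic) clade.
#' @param k Number of representatives (default 10).
#' @return Sorted character vector of representative leaf labels.
#' @export
sample_representatives <- function(tree, clade_leaves, k = 10) {
  clade_leaves <- .check_leafset(tree, clade_leaves, "clade")
  if (length(clade_leaves) <= k) return(clade_leaves)
  sub <- ape::keep.tip(.as_unrooted(tree), clade_leaves)
  prune_to_k(least_squares_root(sub), k)
}
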